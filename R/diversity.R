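#' Per-locus genetic diversity statistics
#'
#' Computes, for every locus over a sample subset, the standard codominant
#' diversity statistics from observed allele frequencies among typed
#' samples: observed allele count `Na`, effective allele count
#' `Ne = 1 / sum(p_i^2)`, minor allele frequency (biallelic loci), observed
#' heterozygosity `Ho`, expected heterozygosity `He = 1 - sum(p_i^2)`,
#' unbiased `uHe = (2n / (2n - 1)) He`, Shannon information index
#' `I = -sum(p_i log p_i)` (natural log), fixation index `F = 1 - Ho / He`,
#' polymorphic information content
#' `PIC = 1 - sum(p_i^2) - sum_{i<j} 2 p_i^2 p_j^2` and the
#' Chakraborty-style null-allele frequency estimate
#' `Fnull = (He - Ho) / (He + Ho)`. Biallelic loci also get an exact
#' Hardy-Weinberg test p-value ([hwe_exact_test()]). `F` and `Fnull` are
#' `NA` at monomorphic loci; a locus with zero typed samples has all
#' statistics `NA`.
#'
#' Works both on a biallelic [genotype_matrix()] and on a `genotype_calls`
#' character matrix of `"A/B"` pairs (multi-allelic, e.g. SSR-style data).
#'
#' @param x a [genotype_matrix()] or a character matrix of `"A/B"` calls
#'   (`NA` = missing)
#' @param subset optional vector of sample ids (or indices) to restrict to
#' @return data.frame of class `locus_stats`, one row per locus, with
#'   attribute `sample_ids` recording the subset used
#' @export
locus_statistics <- function(x, subset = NULL) UseMethod("locus_statistics")

#' @export
locus_statistics.genotype_matrix <- function(x, subset = NULL) {
  d <- x$dosage
  if (!is.null(subset)) d <- d[subset, , drop = FALSE]
  if (nrow(d) == 0) stop("empty sample subset")
  n_typed <- colSums(!is.na(d))
  p_alt <- ifelse(n_typed > 0, colSums(d, na.rm = TRUE) / (2 * n_typed), NA)
  ho <- ifelse(n_typed > 0, colSums(d == 1L, na.rm = TRUE) / n_typed, NA)
  nAA <- colSums(d == 0L, na.rm = TRUE)
  nAB <- colSums(d == 1L, na.rm = TRUE)
  nBB <- colSums(d == 2L, na.rm = TRUE)
  res <- locus_stats_from_freqs(
    lapply(seq_along(p_alt), function(j) {
      p <- p_alt[j]
      if (is.na(p)) return(numeric(0))
      f <- c(1 - p, p); f[f > 0]
    }),
    n_typed, ho)
  res$MAF <- pmin(p_alt, 1 - p_alt)
  res$hwe_p <- vapply(seq_along(p_alt), function(j) {
    if (n_typed[j] == 0) return(NA_real_)
    hwe_exact_test(nAA[j], nAB[j], nBB[j])
  }, 0)
  finish_locus_stats(res, colnames(d), rownames(d))
}

#' @export
locus_statistics.default <- function(x, subset = NULL) {
  if (!is.matrix(x) || !is.character(x))
    stop("x must be a genotype_matrix or a character call matrix")
  if (!is.null(subset)) x <- x[subset, , drop = FALSE]
  if (nrow(x) == 0) stop("empty sample subset")
  n_typed <- colSums(!is.na(x))
  split2 <- function(v) strsplit(v, "/", fixed = TRUE)
  ho <- numeric(ncol(x)); freqs <- vector("list", ncol(x))
  for (j in seq_len(ncol(x))) {
    calls <- x[!is.na(x[, j]), j]
    if (!length(calls)) { ho[j] <- NA; freqs[[j]] <- numeric(0); next }
    al <- split2(calls)
    ho[j] <- mean(vapply(al, function(a) a[1] != a[2], NA))
    tab <- table(unlist(al))
    freqs[[j]] <- as.numeric(tab) / sum(tab)
  }
  res <- locus_stats_from_freqs(freqs, n_typed, ho)
  res$MAF <- vapply(freqs, function(f)
    if (length(f) == 2) min(f) else NA_real_, 0)
  res$hwe_p <- NA_real_
  finish_locus_stats(res, colnames(x), rownames(x))
}

locus_stats_from_freqs <- function(freqs, n_typed, ho) {
  one <- function(f, n, h) {
    if (!length(f)) return(rep(NA_real_, 8))
    sp2 <- sum(f^2)
    he <- 1 - sp2
    uhe <- if (n > 0 && 2 * n > 1) (2 * n / (2 * n - 1)) * he else NA_real_
    ne <- 1 / sp2
    i <- -sum(f * log(f))
    fx <- if (he > 0) 1 - h / he else NA_real_
    pic <- 1 - sp2 - pic_cross_term(f)
    fn <- if ((he + h) > 0) (he - h) / (he + h) else NA_real_
    c(length(f), ne, he, uhe, i, fx, pic, fn)
  }
  m <- t(mapply(one, freqs, n_typed, ho))
  data.frame(n_typed = n_typed, Na = m[, 1], Ne = m[, 2], Ho = ho,
             He = m[, 3], uHe = m[, 4], I = m[, 5], F = m[, 6],
             PIC = m[, 7], Fnull = m[, 8])
}

pic_cross_term <- function(f) {
  if (length(f) < 2) return(0)
  s <- 0
  for (i in 1:(length(f) - 1))
    s <- s + sum(2 * f[i]^2 * f[(i + 1):length(f)]^2)
  s
}

finish_locus_stats <- function(res, locus_id, sample_ids) {
  out <- cbind(data.frame(locus_id = locus_id, stringsAsFactors = FALSE),
               res[c("n_typed", "Na", "Ne", "MAF", "Ho", "He", "uHe", "I",
                     "F", "PIC", "Fnull", "hwe_p")])
  rownames(out) <- NULL
  attr(out, "sample_ids") <- sample_ids
  class(out) <- c("locus_stats", "data.frame")
  out
}

#' Exact Hardy-Weinberg test for biallelic genotype counts
#'
#' Two-sided exact test conditioning on the allele counts: enumerates all
#' heterozygote counts of the right parity and sums the conditional
#' probabilities not exceeding that of the observed configuration
#' (Wigginton-style enumeration).
#'
#' @param n_AA,n_AB,n_BB non-negative genotype counts
#' @return the exact p-value in (0, 1]
#' @export
hwe_exact_test <- function(n_AA, n_AB, n_BB) {
  if (any(c(n_AA, n_AB, n_BB) < 0)) stop("negative genotype counts")
  n <- n_AA + n_AB + n_BB
  if (n == 0) return(NA_real_)
  nA <- 2 * n_AA + n_AB
  nB <- 2 * n_BB + n_AB
  rare <- min(nA, nB)
  if (rare == 0) return(1)
  hets <- seq(rare %% 2, rare, by = 2)
  # log P(n_AB = h | allele counts), up to a shared constant
  logp <- lgamma(n + 1) - lgamma((nA - hets) / 2 + 1) - lgamma(hets + 1) -
    lgamma((nB - hets) / 2 + 1) + hets * log(2)
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  obs <- prob[match(n_AB, hets)]
  sum(prob[prob <= obs * (1 + 1e-12)])
}

#' Summarize per-locus diversity statistics
#'
#' Unweighted mean, min and max over loci with defined values for each
#' statistic, plus the monomorphic-locus fraction and the band fractions
#' used to describe a marker panel: MAF in \[0.30, 0.50\] (closed
#' endpoints), PIC below 0.1, PIC at or above 0.2.
#'
#' @param stats a [locus_statistics()] table
#' @return data.frame of class `diversity_summary`
#' @export
summarize_diversity <- function(stats) {
  if (!nrow(stats)) stop("no loci")
  cols <- c("Na", "Ne", "MAF", "Ho", "He", "uHe", "I", "F", "PIC", "Fnull")
  rows <- lapply(cols, function(cn) {
    v <- stats[[cn]]; v <- v[!is.na(v)]
    if (!length(v)) return(data.frame(statistic = cn, mean = NA_real_,
                                      min = NA_real_, max = NA_real_))
    data.frame(statistic = cn, mean = mean(v), min = min(v), max = max(v))
  })
  out <- do.call(rbind, rows)
  attr(out, "fraction_monomorphic") <- mean(stats$Na == 1, na.rm = TRUE)
  maf <- stats$MAF
  attr(out, "fraction_maf_30_50") <-
    mean(maf >= 0.30 & maf <= 0.50, na.rm = TRUE)
  attr(out, "fraction_pic_lt_0.1") <- mean(stats$PIC < 0.1, na.rm = TRUE)
  attr(out, "fraction_pic_ge_0.2") <- mean(stats$PIC >= 0.2, na.rm = TRUE)
  class(out) <- c("diversity_summary", "data.frame")
  out
}

#' Compare diversity of two marker sets on one sample subset
#'
#' Side-by-side per-locus means of Navg (observed allele count), Ne, Ho, He
#' and Shannon I for two marker panels genotyped on the same samples, e.g. a
#' biallelic SNP panel against a multi-allelic SSR panel.
#'
#' @param stats_a,stats_b [locus_statistics()] tables computed on the same
#'   sample subset
#' @param labels length-2 character vector naming the two panels
#' @return data.frame with one row per statistic and one column per panel
#' @export
compare_marker_sets <- function(stats_a, stats_b, labels = c("A", "B")) {
  sa <- attr(stats_a, "sample_ids"); sb <- attr(stats_b, "sample_ids")
  if (!is.null(sa) && !is.null(sb) && !length(intersect(sa, sb)))
    stop("marker sets were computed on disjoint sample subsets")
  pick <- c(Navg = "Na", Ne = "Ne", Ho = "Ho", He = "He", I = "I")
  m <- function(s) vapply(pick, function(cn) mean(s[[cn]], na.rm = TRUE), 0)
  out <- data.frame(parameter = names(pick), a = m(stats_a), b = m(stats_b),
                    stringsAsFactors = FALSE)
  names(out)[2:3] <- labels
  rownames(out) <- NULL
  out
}
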