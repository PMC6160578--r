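#' Cohort specification for the synthetic genotype generator
#'
#' Describes a simulated germplasm cohort with the structure the downstream
#' analyses assume: a founder pool of distinct cultivars drawn under
#' Hardy-Weinberg equilibrium, clonal duplicate groups (exact genotype
#' copies), somatic-mutant variants differing from their parent by a small
#' number of single-allele flips, a wild pool differentiated from the
#' cultivated founders (Balding-Nichols model), Mendelian F1 progeny of two
#' founders, and missing calls injected at random.
#'
#' The defaults emulate a large olive collection panel: 1,043 biallelic loci
#' with founder MAF uniform on \[0.06, 0.50\] (the panel's ascertainment
#' floor), 325 cultivated samples comprising 59 clone groups of 164 samples
#' (largest group of 7), 157 singleton cultivars and 4 somatic variants at
#' 1, 2, 9 and 10 allele flips, 89 wild genotypes at a differentiation
#' parameter of 0.39, and 15 progeny of a founder pair.
#'
#' @param n_loci number of biallelic loci (default 1043)
#' @param maf_range founder minor-allele-frequency range, in (0, 0.5]
#' @param n_cultivars number of distinct cultivar founder genotypes
#' @param clone_group_sizes integer sizes of the clonal duplicate groups;
#'   group g is built from founder g, so `length(clone_group_sizes)` must
#'   not exceed `n_cultivars`. Founders not heading a group enter as
#'   singletons.
#' @param mutant_spec list of `c(parent, k)` pairs: an extra sample copied
#'   from founder `parent` with exactly `k` single-allele flips (k in 1..10
#'   by convention, up to `n_loci`)
#' @param n_wild number of wild genotypes
#' @param wild_fst Balding-Nichols differentiation parameter in \[0, 1)
#' @param n_progeny number of F1 progeny of `parent_pair`
#' @param parent_pair indices of the two founder parents of the progeny
#' @param missing_rate per-call missing probability in \[0, 1)
#' @param seed integer seed; all draws derive from it
#' @return list of class `cohort_spec`
#' @export
cohort_spec <- function(n_loci = 1043,
                        maf_range = c(0.06, 0.5),
                        n_cultivars = 216,
                        clone_group_sizes = c(7L, rep(3L, 41), rep(2L, 17)),
                        mutant_spec = list(c(1L, 1L), c(1L, 2L),
                                           c(2L, 9L), c(3L, 10L)),
                        n_wild = 89, wild_fst = 0.39,
                        n_progeny = 15, parent_pair = c(60L, 61L),
                        missing_rate = 0.01, seed = 1L) {
  if (length(maf_range) != 2 || maf_range[1] > maf_range[2] ||
      maf_range[1] <= 0 || maf_range[2] > 0.5)
    stop("maf_range must be [low, high] with 0 < low <= high <= 0.5")
  if (wild_fst < 0 || wild_fst >= 1) stop("wild_fst must be in [0, 1)")
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")
  if (length(clone_group_sizes) > n_cultivars)
    stop("more clone groups than founders")
  if (length(clone_group_sizes) && any(clone_group_sizes < 1))
    stop("clone group sizes must be >= 1")
  for (m in mutant_spec) {
    if (length(m) != 2 || m[1] < 1 || m[1] > n_cultivars)
      stop("mutant_spec entries must be c(parent, k) with a valid parent")
    if (m[2] < 1 || m[2] > n_loci) stop("mutant flip count k must be in [1, n_loci]")
  }
  if (n_progeny > 0 &&
      (length(parent_pair) != 2 || any(parent_pair < 1 | parent_pair > n_cultivars)))
    stop("parent_pair must index two founders")
  structure(list(n_loci = as.integer(n_loci), maf_range = as.numeric(maf_range),
                 n_cultivars = as.integer(n_cultivars),
                 clone_group_sizes = as.integer(clone_group_sizes),
                 mutant_spec = mutant_spec, n_wild = as.integer(n_wild),
                 wild_fst = as.numeric(wild_fst),
                 n_progeny = as.integer(n_progeny),
                 parent_pair = as.integer(parent_pair),
                 missing_rate = as.numeric(missing_rate),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# run code under a derived, restored RNG state; offset keeps the
# per-purpose streams of one cohort independent of each other
with_stream <- function(seed, offset, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((as.numeric(seed) * 48271 + offset * 16807) %% 2147483629)
  force(code)
}

#' Draw founder allele frequencies
#'
#' Per-locus alt-allele frequencies are sampled so that the MAF
#' `min(p, 1 - p)` is uniform on `spec$maf_range`; which allele is minor is
#' decided by a fair coin. Deterministic under the spec seed.
#'
#' @param spec a [cohort_spec()]
#' @return numeric vector of alt-allele frequencies, length `n_loci`
#' @export
draw_founder_frequencies <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_stream(spec$seed, 1, {
    maf <- stats::runif(spec$n_loci, spec$maf_range[1], spec$maf_range[2])
    flip <- stats::runif(spec$n_loci) < 0.5
    ifelse(flip, maf, 1 - maf)
  })
}

hwe_draw <- function(n, p) {
  # n individuals x length(p) loci, HWE dosages
  matrix(stats::rbinom(n * length(p), 2L, rep(p, each = n)), nrow = n)
}

cohort_gm <- function(dos, ids, loci_ids) {
  dimnames(dos) <- list(ids, loci_ids)
  genotype_matrix(dos, ref_allele = "A", alt_allele = "B")
}

#' Simulate the cultivated set
#'
#' Draws `n_cultivars` distinct founder genotypes under HWE from the founder
#' frequencies, expands the first `length(clone_group_sizes)` founders into
#' clonal duplicate groups (exact copies), and appends somatic-mutant
#' variants: copies of their parent with exactly `k` single-allele flips at
#' `k` distinct loci (hom -> het or het -> hom at each). Truth labels
#' (founder index, flip count) are recorded in the metadata.
#'
#' @param spec a [cohort_spec()]
#' @param p founder frequencies from [draw_founder_frequencies()]
#' @return list with `genotypes`, `meta` (extra columns `founder`,
#'   `mutant_k`), and `founders` (the founder dosage matrix)
#' @export
simulate_cultivars <- function(spec, p) {
  stopifnot(length(p) == spec$n_loci)
  loci_ids <- sprintf("L%04d", seq_len(spec$n_loci))
  with_stream(spec$seed, 2, {
    founders <- hwe_draw(spec$n_cultivars, p)
    sizes <- spec$clone_group_sizes
    ng <- length(sizes)
    rows <- integer(); sid <- character(); acc <- character(); fnd <- integer()
    for (g in seq_len(ng)) {
      rows <- c(rows, rep(g, sizes[g]))
      sid <- c(sid, sprintf("CV%03d_%02d", g, seq_len(sizes[g])))
      acc <- c(acc, rep(sprintf("cv%03d", g), sizes[g]))
      fnd <- c(fnd, rep(g, sizes[g]))
    }
    if (spec$n_cultivars > ng) {
      singles <- (ng + 1):spec$n_cultivars
      rows <- c(rows, singles)
      sid <- c(sid, sprintf("CV%03d_01", singles))
      acc <- c(acc, sprintf("cv%03d", singles))
      fnd <- c(fnd, singles)
    }
    dos <- founders[rows, , drop = FALSE]
    mk <- rep(0L, length(rows))
    for (i in seq_along(spec$mutant_spec)) {
      m <- spec$mutant_spec[[i]]
      parent <- m[1]; k <- m[2]
      row <- founders[parent, ]
      at <- sample.int(spec$n_loci, k)
      for (l in at) {
        row[l] <- if (row[l] == 1L) sample(c(0L, 2L), 1L) else 1L
      }
      dos <- rbind(dos, row)
      sid <- c(sid, sprintf("MU%02d_cv%03d_k%02d", i, parent, k))
      acc <- c(acc, sprintf("cv%03d_var%d", parent, i))
      fnd <- c(fnd, parent)
      mk <- c(mk, as.integer(k))
    }
    meta <- sample_meta(sid, accession_name = acc,
                        register_number = sprintf("R%04d", seq_along(sid)),
                        category = "cultivar", group_label = "cultivated")
    meta$founder <- fnd
    meta$mutant_k <- mk
    list(genotypes = cohort_gm(dos, sid, loci_ids), meta = meta,
         founders = founders)
  })
}

#' Simulate a differentiated wild pool
#'
#' Wild allele frequencies are drawn per locus from the Balding-Nichols
#' distribution `Beta(p(1-F)/F, (1-p)(1-F)/F)` around the founder frequency
#' `p` with differentiation parameter `F = wild_fst`; individuals are then
#' drawn under HWE within the wild pool. With `wild_fst = 0` the wild
#' frequencies equal the founder frequencies. Some loci may come out
#' monomorphic in the wild sample, as observed in real wild material.
#'
#' @inheritParams simulate_cultivars
#' @return list with `genotypes`, `meta`, and `wild_freqs`
#' @export
simulate_wild_pool <- function(spec, p) {
  loci_ids <- sprintf("L%04d", seq_len(spec$n_loci))
  with_stream(spec$seed, 3, {
    f <- spec$wild_fst
    pw <- if (f == 0) p else
      stats::rbeta(spec$n_loci, p * (1 - f) / f, (1 - p) * (1 - f) / f)
    if (spec$n_wild == 0) {
      dos <- matrix(integer(), 0, spec$n_loci)
      meta <- sample_meta(character())
      meta$founder <- integer(0); meta$mutant_k <- integer(0)
      return(list(genotypes = cohort_gm(dos, character(), loci_ids),
                  meta = meta, wild_freqs = pw))
    }
    dos <- hwe_draw(spec$n_wild, pw)
    sid <- sprintf("WL%03d", seq_len(spec$n_wild))
    meta <- sample_meta(sid, accession_name = sid,
                        register_number = sprintf("W%04d", seq_len(spec$n_wild)),
                        category = "wild", group_label = "wild")
    meta$founder <- NA_integer_; meta$mutant_k <- NA_integer_
    list(genotypes = cohort_gm(dos, sid, loci_ids), meta = meta,
         wild_freqs = pw)
  })
}

#' Simulate F1 progeny of two parents
#'
#' Each progeny receives, independently at every locus, one uniformly chosen
#' allele from each parent's pair (Mendelian segregation). A missing call in
#' either parent yields a missing progeny call at that locus.
#'
#' @param spec a [cohort_spec()]
#' @param parents 2-row dosage matrix (the two parents)
#' @return list with `genotypes` and `meta`
#' @export
simulate_progeny <- function(spec, parents) {
  stopifnot(nrow(parents) == 2)
  loci_ids <- sprintf("L%04d", seq_len(ncol(parents)))
  with_stream(spec$seed, 4, {
    n <- spec$n_progeny
    L <- ncol(parents)
    gamete <- function(d) {
      # transmitted alt-allele count per (progeny, locus)
      g <- matrix(0L, n, L)
      g[, d == 2L] <- 1L
      het <- which(d == 1L)
      if (length(het))
        g[, het] <- matrix(stats::rbinom(n * length(het), 1L, 0.5), n)
      g[, is.na(d)] <- NA_integer_
      g
    }
    dos <- gamete(parents[1, ]) + gamete(parents[2, ])
    sid <- if (n) sprintf("PR%03d", seq_len(n)) else character()
    meta <- sample_meta(sid, accession_name = sid,
                        register_number = if (n) sprintf("P%04d", seq_len(n)) else character(),
                        category = if (n) "progeny" else character(),
                        group_label = "progeny")
    if (n) { meta$founder <- NA_integer_; meta$mutant_k <- NA_integer_ }
    list(genotypes = cohort_gm(dos, sid, loci_ids), meta = meta)
  })
}

#' Inject missing calls at random
#'
#' Each call is independently set missing with probability `rate`.
#'
#' @param gm a [genotype_matrix()]
#' @param rate per-call missing probability in \[0, 1)
#' @param seed integer seed
#' @return the matrix with missing calls injected
#' @export
inject_missing <- function(gm, rate, seed = 1L) {
  if (rate < 0 || rate >= 1) stop("rate must be in [0, 1)")
  if (rate == 0) return(gm)
  with_stream(seed, 5, {
    d <- gm$dosage
    d[stats::runif(length(d)) < rate] <- NA_integer_
    gm$dosage <- d
    gm
  })
}

#' Simulate a full cohort
#'
#' Convenience wrapper running [draw_founder_frequencies()],
#' [simulate_cultivars()], [simulate_wild_pool()] and [simulate_progeny()],
#' stacking the results and injecting missing calls. The pre-missingness
#' truth matrix is retained for tests.
#'
#' @param spec a [cohort_spec()]
#' @return list with `genotypes` (missingness injected), `truth` (complete
#'   calls), `meta` (with truth labels), `founder_freqs`, `wild_freqs`,
#'   and `spec`
#' @export
simulate_cohort <- function(spec = cohort_spec()) {
  p <- draw_founder_frequencies(spec)
  cult <- simulate_cultivars(spec, p)
  wild <- simulate_wild_pool(spec, p)
  dos <- rbind(cult$genotypes$dosage, wild$genotypes$dosage)
  meta <- rbind(cult$meta, wild$meta)
  if (spec$n_progeny > 0) {
    prog <- simulate_progeny(spec, cult$founders[spec$parent_pair, , drop = FALSE])
    dos <- rbind(dos, prog$genotypes$dosage)
    meta <- rbind(meta, prog$meta)
  }
  truth <- genotype_matrix(dos, "A", "B")
  gm <- inject_missing(truth, spec$missing_rate, seed = spec$seed)
  list(genotypes = gm, truth = truth, meta = meta,
       founder_freqs = p, wild_freqs = wild$wild_freqs, spec = spec)
}
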