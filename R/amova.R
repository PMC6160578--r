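#' One-way analysis of molecular variance (AMOVA)
#'
#' Excoffier-style variance decomposition over squared pairwise distances.
#' With `d2_ij` the squared allele-difference distance between samples i and
#' j, `SS_total = sum_{i<j} d2_ij / N`, `SS_within = sum_g sum_{i<j in g}
#' d2_ij / n_g`, `SS_among = SS_total - SS_within`; mean squares are SS/df
#' with `df_among = K - 1`, `df_within = N - K`. The within variance
#' component is `MS_within`; the among component is
#' `(MS_among - MS_within) / n0` with `n0 = (N - sum(n_g^2) / N) / (K - 1)`,
#' floored at 0. phi-st is the among share of the total variance, and its
#' significance is assessed by random relabeling of samples:
#' `p = (1 + #permuted phi >= observed) / (1 + n_perm)`.
#'
#' @param pairs a [pairwise_distances()] result (raw allele-difference
#'   counts; they are squared here), or a full symmetric distance matrix
#' @param groups group label per sample, named by sample id or ordered as
#'   the distance matrix
#' @param n_perm number of permutations (default 999)
#' @param seed optional integer seed for the permutations
#' @return object of class `amova_result`
#' @export
amova_one_way <- function(pairs, groups, n_perm = 999, seed = NULL) {
  D <- if (inherits(pairs, "pair_distances")) attr(pairs, "diff_matrix") else pairs
  if (!is.matrix(D)) stop("pairs must be a pair_distances object or a matrix")
  N <- nrow(D)
  if (!is.null(names(groups))) {
    if (!all(rownames(D) %in% names(groups)))
      stop("every sample needs a group label")
    groups <- groups[rownames(D)]
  }
  if (length(groups) != N) stop("one group label per sample required")
  if (anyNA(D[upper.tri(D)])) stop("AMOVA requires complete pairwise distances")
  lab <- as.integer(factor(groups))
  K <- max(lab)
  if (K < 2) stop("need at least 2 groups")
  ng <- tabulate(lab, K)
  if (any(ng == 0)) stop("empty group")
  D2 <- D^2
  ss_tot <- sum(D2[upper.tri(D2)]) / N
  within_ss <- function(lab_vec) {
    s <- 0
    for (g in seq_len(K)) {
      idx <- lab_vec == g
      s <- s + sum(D2[idx, idx]) / (2 * ng[g])
    }
    s
  }
  n0 <- (N - sum(ng^2) / N) / (K - 1)
  phi_from_ssw <- function(ssw) {
    ms_w <- ssw / (N - K)
    ms_a <- (ss_tot - ssw) / (K - 1)
    va <- max(0, (ms_a - ms_w) / n0)
    if (va + ms_w <= 0) 0 else va / (va + ms_w)
  }
  ss_w <- within_ss(lab)
  phi <- phi_from_ssw(ss_w)
  perm_p <- NA_real_
  if (n_perm > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
      on.exit({
        if (is.null(old)) rm(".Random.seed", envir = globalenv())
        else assign(".Random.seed", old, envir = globalenv())
      })
      set.seed(seed)
    }
    # all permutations at once: within-group sums via one matrix product
    perm_lab <- vapply(seq_len(n_perm),
                       function(p) lab[sample.int(N)], integer(N))
    ssw_perm <- numeric(n_perm)
    for (g in seq_len(K)) {
      Xg <- perm_lab == g
      storage.mode(Xg) <- "double"
      ssw_perm <- ssw_perm + colSums(Xg * (D2 %*% Xg)) / (2 * ng[g])
    }
    phi_perm <- vapply(ssw_perm, phi_from_ssw, 0)
    perm_p <- (1 + sum(phi_perm >= phi - 1e-12)) / (1 + n_perm)
  }
  ms_w <- ss_w / (N - K)
  ms_a <- (ss_tot - ss_w) / (K - 1)
  va <- max(0, (ms_a - ms_w) / n0)
  vw <- ms_w
  structure(list(df_among = K - 1L, df_within = as.integer(N - K),
                 SS_among = ss_tot - ss_w, SS_within = ss_w, SS_total = ss_tot,
                 MS_among = ms_a, MS_within = ms_w,
                 var_among = va, var_within = vw,
                 phi_st = phi,
                 pct_among = if (va + vw > 0) 100 * va / (va + vw) else 0,
                 pct_within = if (va + vw > 0) 100 * vw / (va + vw) else 100,
                 perm_p = perm_p, n_permutations = as.integer(n_perm),
                 n_groups = K, group_sizes = ng),
            class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  print(variance_partition_report(x), row.names = FALSE)
  cat(sprintf("phi-st = %.4f, permutation p = %s (%d permutations)\n",
              x$phi_st,
              if (is.na(x$perm_p)) "NA" else format(x$perm_p, digits = 4),
              x$n_permutations))
  invisible(x)
}

#' AMOVA variance partition table
#'
#' Formats an [amova_one_way()] result as the usual three-row df/SS/MS table
#' with variance components and their percentages
#' (`pct_within = 100 * var_within / (var_within + var_among)`, the
#' complement of phi-st).
#'
#' @param result an `amova_result`
#' @return data.frame with rows among, within, total
#' @export
variance_partition_report <- function(result) {
  x <- result
  tot <- x$var_among + x$var_within
  x$pct_among <- if (tot > 0) 100 * x$var_among / tot else 0
  x$pct_within <- if (tot > 0) 100 * x$var_within / tot else 100
  data.frame(source = c("among", "within", "total"),
             df = c(x$df_among, x$df_within, x$df_among + x$df_within),
             SS = c(x$SS_among, x$SS_within, x$SS_total),
             MS = c(x$MS_among, x$MS_within, NA),
             variance = c(x$var_among, x$var_within,
                          x$var_among + x$var_within),
             pct = c(x$pct_among, x$pct_within, 100),
             stringsAsFactors = FALSE)
}
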