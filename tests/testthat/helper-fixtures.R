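# shared fixtures and independent oracles

# genotype_matrix from a character matrix of "AA"/"AB"/"BB"/"--" strings
gm_from_strings <- function(strings, samples = NULL, loci = NULL) {
  if (is.null(samples)) samples <- sprintf("s%d", seq_len(nrow(strings)))
  if (is.null(loci)) loci <- sprintf("L%d", seq_len(ncol(strings)))
  map <- c(AA = 0L, AB = 1L, BA = 1L, BB = 2L)
  d <- matrix(map[strings], nrow(strings), ncol(strings),
              dimnames = list(samples, loci))
  genotype_matrix(d, "A", "B")
}

# independent allele-difference oracle: explicit multiset intersection of
# the two diploid genotypes, looped per locus
naive_allele_diff <- function(di, dj) {
  pairs <- list(c("R", "R"), c("R", "A"), c("A", "A"))
  as_pair <- function(d) pairs[[d + 1L]]
  # di, dj: dosage vectors with NA
  tot <- 0L; shared <- 0L
  for (l in seq_along(di)) {
    if (is.na(di[l]) || is.na(dj[l])) next
    shared <- shared + 1L
    a <- sort(as_pair(di[l])); b <- sort(as_pair(dj[l]))
    inter <- 0L; bb <- b
    for (x in a) {
      hit <- match(x, bb)
      if (!is.na(hit)) { inter <- inter + 1L; bb <- bb[-hit] }
    }
    tot <- tot + (2L - inter)
  }
  c(diff = tot, shared = shared)
}

# brute-force conditional HWE enumeration, independent of the package's
# log-space implementation
naive_hwe_p <- function(nAA, nAB, nBB) {
  n <- nAA + nAB + nBB
  nA <- 2 * nAA + nAB
  rare <- min(nA, 2 * n - nA)
  if (rare == 0) return(1)
  hets <- seq(rare %% 2, rare, by = 2)
  prob <- vapply(hets, function(h) {
    naa <- (nA - h) / 2
    nbb <- n - naa - h
    exp(lfactorial(n) - lfactorial(naa) - lfactorial(h) - lfactorial(nbb) +
          h * log(2) + lfactorial(nA) + lfactorial(2 * n - nA) -
          lfactorial(2 * n))
  }, 0)
  obs <- prob[hets == nAB]
  sum(prob[prob <= obs * (1 + 1e-9)])
}

# spreadsheet-style AMOVA arithmetic on an explicit squared-distance matrix
naive_amova <- function(D2, labels) {
  N <- nrow(D2)
  groups <- unique(labels)
  K <- length(groups)
  ss_tot <- 0
  for (i in 1:(N - 1)) for (j in (i + 1):N) ss_tot <- ss_tot + D2[i, j]
  ss_tot <- ss_tot / N
  ss_w <- 0
  for (g in groups) {
    idx <- which(labels == g)
    s <- 0
    if (length(idx) > 1)
      for (a in 1:(length(idx) - 1)) for (b in (a + 1):length(idx))
        s <- s + D2[idx[a], idx[b]]
    ss_w <- ss_w + s / length(idx)
  }
  ng <- table(labels)[groups]
  ms_a <- (ss_tot - ss_w) / (K - 1)
  ms_w <- ss_w / (N - K)
  n0 <- (N - sum(ng^2) / N) / (K - 1)
  va <- max(0, (ms_a - ms_w) / n0)
  list(SS_total = ss_tot, SS_within = ss_w, SS_among = ss_tot - ss_w,
       MS_among = ms_a, MS_within = ms_w,
       phi = if (va + ms_w > 0) va / (va + ms_w) else 0)
}

# small cohort spec used across tests
tiny_spec <- function(seed = 1, ...) {
  args <- list(n_loci = 120, n_cultivars = 8,
               clone_group_sizes = c(3L, 2L),
               mutant_spec = list(c(1L, 2L)),
               n_wild = 5, n_progeny = 3, parent_pair = c(4L, 5L),
               missing_rate = 0.01, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(cohort_spec, args)
}
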