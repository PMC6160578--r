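test_that("pairwise distances equal the per-locus multiset oracle", {
  # fixed single-locus cases from the 3x3 genotype-pair table
  gm <- gm_from_strings(rbind(c("AA"), c("AB"), c("BB"), c("BA")),
                        samples = c("aa", "ab", "bb", "ba"))
  pd <- pairwise_distances(gm)
  d <- attr(pd, "diff_matrix")
  expect_equal(d["aa", "ab"], 1)
  expect_equal(d["aa", "bb"], 2)
  expect_equal(d["ab", "bb"], 1)
  expect_equal(d["ab", "ba"], 0)  # heterozygote order irrelevant

  # random matrices against the independent multiset-intersection oracle
  set.seed(99)
  for (rep in 1:5) {
    d0 <- matrix(sample(c(0:2, NA), 8 * 30, TRUE, prob = c(.3, .3, .3, .1)),
                 8, 30, dimnames = list(sprintf("s%d", 1:8), sprintf("L%d", 1:30)))
    gm <- genotype_matrix(d0, "A", "B")
    pd <- pairwise_distances(gm)
    for (k in seq_len(nrow(pd))) {
      o <- naive_allele_diff(d0[pd$sample_i[k], ], d0[pd$sample_j[k], ])
      expect_equal(pd$n_allele_diff[k], unname(o["diff"]))
      expect_equal(pd$n_loci_compared[k], unname(o["shared"]))
    }
  }
  # pair count is N(N-1)/2 and bounds hold
  expect_equal(nrow(pd), 8 * 7 / 2)
  expect_true(all(pd$n_allele_diff <= 2 * pd$n_loci_compared, na.rm = TRUE))
})

test_that("identical and maximally different genotypes hit the extremes", {
  d <- rbind(a = rep(0L, 1043), b = rep(0L, 1043), c = rep(2L, 1043))
  colnames(d) <- sprintf("L%d", 1:1043)
  pd <- pairwise_distances(genotype_matrix(d, "A", "B"))
  D <- attr(pd, "diff_matrix")
  expect_equal(D["a", "b"], 0)
  expect_equal(D["a", "c"], 2086)  # 2 x 1,043 alleles all different
})

test_that("triangle-like bound holds against brute force", {
  set.seed(7)
  d0 <- matrix(sample(0:2, 6 * 40, TRUE), 6, 40,
               dimnames = list(sprintf("s%d", 1:6), sprintf("L%d", 1:40)))
  D <- attr(pairwise_distances(genotype_matrix(d0, "A", "B")), "diff_matrix")
  for (a in 1:6) for (b in 1:6) for (c in 1:6) {
    if (length(unique(c(a, b, c))) < 3) next
    expect_lte(D[a, c], D[a, b] + D[b, c])
    expect_gte(D[b, c], abs(D[a, c] - D[a, b]))
  }
})

test_that("gap detection finds the intra/inter separation", {
  fake_pairs <- function(dists) {
    n <- length(dists)
    structure(data.frame(sample_i = sprintf("x%d", 1:n),
                         sample_j = sprintf("y%d", 1:n),
                         n_loci_compared = 1000L, n_allele_diff = dists,
                         normalized_diff = dists / 2000),
              class = c("pair_distances", "data.frame"))
  }
  g <- distance_histogram(fake_pairs(c(0:10, 200:680)))
  expect_true(g$is_bimodal)
  expect_equal(g$gap_interval, c(11L, 199L))
  expect_equal(g$intra_threshold, 10L)
  # all at zero: no gap, fallback threshold
  g0 <- distance_histogram(fake_pairs(rep(0L, 10)))
  expect_false(g0$is_bimodal)
  expect_equal(g0$intra_threshold, 10L)
  # longest empty run wins: {0, 5, 300} -> gap [6, 299], threshold 5
  g2 <- distance_histogram(fake_pairs(c(0L, 5L, 300L)), min_gap_width = 50)
  expect_equal(g2$gap_interval, c(6L, 299L))
  expect_equal(g2$intra_threshold, 5L)
  # no observed distance lies strictly inside the gap
  expect_false(any(c(0L, 5L, 300L) > g2$gap_interval[1] - 1 &
                     c(0L, 5L, 300L) < g2$gap_interval[2] + 1))
})

test_that("redundancy groups are connected components with near-match edges", {
  # 7 mutually identical samples -> one group of 7 at distance 0
  d <- matrix(rep(rbinom(60, 2, 0.4), each = 7), 7, 60,
              dimnames = list(sprintf("f%d", 1:7), sprintf("L%d", 1:60)))
  base <- rbinom(60, 2, 0.4)
  d <- rbind(d, other = ifelse(base == 1L, 2L, 1L))  # far-away genotype
  pd <- pairwise_distances(genotype_matrix(d, "A", "B"))
  red <- redundancy_groups(pd, 10)
  expect_length(red$groups, 1)
  expect_length(red$groups[[1]]$members, 7)
  expect_equal(red$groups[[1]]$max_within_distance, 0L)
  expect_equal(red$unique_genotypes, "other")
  expect_equal(nrow(red$near_match_edges), 0)

  # chained somatic variants join one component through the parent
  base <- rep(0L, 100)
  m1 <- m2 <- base
  m1[1] <- 1L            # distance 1 to parent
  m2[2:3] <- 1L          # distance 2 to parent, 3 to m1
  far <- rep(2L, 100)
  d2 <- rbind(parent = base, m1 = m1, m2 = m2, far = far)
  colnames(d2) <- sprintf("L%d", 1:100)
  pd2 <- pairwise_distances(genotype_matrix(d2, "A", "B"))
  red2 <- redundancy_groups(pd2, 2)  # 3-distance pair above threshold
  expect_length(red2$groups, 1)
  expect_setequal(red2$groups[[1]]$members, c("parent", "m1", "m2"))
  expect_equal(red2$groups[[1]]$max_within_distance, 3L)  # via components
  expect_setequal(red2$near_match_edges$n_allele_diff, c(1L, 2L))

  # empty graph: all unique
  red3 <- redundancy_groups(pd2, 0)
  expect_length(red3$groups, 0)
  expect_length(red3$unique_genotypes, 4)
})

test_that("match_report classifies groups and flags homonymy", {
  d <- rbind(a1 = rep(0L, 50), a2 = rep(0L, 50),
             b1 = rep(1L, 50), b2 = rep(1L, 50),
             c1 = c(rep(2L, 10), rep(0L, 40)))
  colnames(d) <- sprintf("L%d", 1:50)
  pd <- pairwise_distances(genotype_matrix(d, "A", "B"))
  red <- redundancy_groups(pd, 5)
  meta <- sample_meta(c("a1", "a2", "b1", "b2", "c1"),
                      accession_name = c("Alpha", "Alpha", "Beta", "Gamma", "Alpha"),
                      register_number = sprintf("R%d", 1:5))
  mr <- match_report(red, meta)
  tab <- mr$group_table
  # same name, different registers, distance 0 -> replicate-confirmation
  a_row <- tab[grepl("a1", tab$members), ]
  expect_equal(a_row$label, "replicate-confirmation")
  expect_false(a_row$mutant_variant)
  # different names in one distance-0 group -> synonymy candidate
  b_row <- tab[grepl("b1", tab$members), ]
  expect_equal(b_row$label, "synonymy-candidate")
  # "Alpha" spans two components (the a-group and the distant unique c1)
  expect_true("Alpha" %in% mr$homonymy$accession_name)
  expect_false("Beta" %in% mr$homonymy$accession_name)
  # missing metadata -> unannotated
  mr2 <- match_report(red, sample_meta("a1"))
  expect_true("unannotated" %in% mr2$group_table$label)
})
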