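test_that("cohort generation is deterministic and truth-labeled", {
  s1 <- simulate_cohort(tiny_spec(seed = 11))
  s2 <- simulate_cohort(tiny_spec(seed = 11))
  s3 <- simulate_cohort(tiny_spec(seed = 12))
  expect_identical(s1$genotypes$dosage, s2$genotypes$dosage)
  expect_identical(s1$meta, s2$meta)
  expect_false(identical(s1$genotypes$dosage, s3$genotypes$dosage))
  # truth labels complete: every sample has a category; every cultivar a founder
  expect_true(all(s1$meta$category %in% c("cultivar", "wild", "progeny")))
  cult <- s1$meta$category == "cultivar"
  expect_true(all(!is.na(s1$meta$founder[cult])))
})

test_that("founder frequencies respect the MAF range", {
  sp <- cohort_spec(n_loci = 500, maf_range = c(0.06, 0.5), seed = 5)
  p <- draw_founder_frequencies(sp)
  maf <- pmin(p, 1 - p)
  expect_true(all(maf >= 0.06 - 1e-12 & maf <= 0.5 + 1e-12))
  # degenerate range
  sp2 <- cohort_spec(n_loci = 50, maf_range = c(0.5, 0.5), seed = 1)
  expect_true(all(draw_founder_frequencies(sp2) == 0.5))
  expect_error(cohort_spec(maf_range = c(0, 0.5)), "maf_range")
})

test_that("clone groups are identical and mutants sit at exactly k flips", {
  sp <- tiny_spec(seed = 3, clone_group_sizes = c(7L, 2L),
                  mutant_spec = list(c(1L, 10L), c(2L, 1L)),
                  missing_rate = 0, n_wild = 0, n_progeny = 0)
  sim <- simulate_cohort(sp)
  d <- sim$truth$dosage
  g1 <- sim$meta$sample_id[sim$meta$founder == 1 & sim$meta$mutant_k == 0]
  expect_length(g1, 7)
  for (a in g1[-1]) expect_identical(d[a, ], d[g1[1], ])  # clone transitivity
  mut <- sim$meta$sample_id[sim$meta$mutant_k == 10]
  expect_equal(sum(abs(d[mut, ] - d[g1[1], ])), 10)
  # each flip changes exactly one allele
  expect_true(all(abs(d[mut, ] - d[g1[1], ]) <= 1))
  mut1 <- sim$meta$sample_id[sim$meta$mutant_k == 1]
  g2 <- sim$meta$sample_id[sim$meta$founder == 2 & sim$meta$mutant_k == 0][1]
  expect_equal(sum(abs(d[mut1, ] - d[g2, ])), 1)
  expect_error(cohort_spec(n_loci = 5, mutant_spec = list(c(1L, 6L))), "flip")
})

test_that("unrelated founder distance matches the 3x3 enumeration closed form", {
  # E[d] per locus by enumerating the genotype-pair table under HWE
  sp <- cohort_spec(n_loci = 1043, n_cultivars = 400,
                    clone_group_sizes = integer(), mutant_spec = list(),
                    n_wild = 0, n_progeny = 0, missing_rate = 0, seed = 17)
  p <- draw_founder_frequencies(sp)
  geno_probs <- rbind((1 - p)^2, 2 * p * (1 - p), p^2)
  ed <- evar <- numeric(length(p))
  for (a in 0:2) for (b in 0:2) {
    w <- geno_probs[a + 1, ] * geno_probs[b + 1, ]
    ed <- ed + w * abs(a - b)
    evar <- evar + w * (a - b)^2
  }
  expected <- sum(ed)
  sd_total <- sqrt(sum(evar - ed^2))
  cult <- simulate_cultivars(sp, p)
  d <- cult$genotypes$dosage
  # 200 independent founder pairs
  dist_pair <- vapply(seq(1, 399, by = 2),
                      function(i) sum(abs(d[i, ] - d[i + 1, ])), 0)
  se <- sd_total / sqrt(length(dist_pair))
  expect_lt(abs(mean(dist_pair) - expected), 3 * se)
  expect_gt(min(dist_pair), 200)  # unrelated pairs stay right of the gap
})

test_that("wild pool follows the Balding-Nichols model", {
  # fst = 0: wild frequencies equal founder frequencies exactly
  sp0 <- tiny_spec(seed = 9, wild_fst = 0, n_wild = 10)
  p <- draw_founder_frequencies(sp0)
  w0 <- simulate_wild_pool(sp0, p)
  expect_identical(w0$wild_freqs, p)
  # fst = 0.3, n = 89: monomorphic wild loci appear with high probability
  sp3 <- cohort_spec(n_loci = 1043, n_cultivars = 5,
                     clone_group_sizes = integer(), mutant_spec = list(),
                     n_wild = 89, wild_fst = 0.3, n_progeny = 0,
                     missing_rate = 0, seed = 21)
  w3 <- simulate_wild_pool(sp3, draw_founder_frequencies(sp3))
  mono <- colSums(w3$genotypes$dosage) %in% c(0L, 2L * 89L)
  expect_gt(sum(mono), 0)
  # degenerate size: empty matrix, no error
  spn <- tiny_spec(n_wild = 0)
  wn <- simulate_wild_pool(spn, draw_founder_frequencies(spn))
  expect_equal(nrow(wn$genotypes$dosage), 0)
  expect_error(cohort_spec(wild_fst = 1), "wild_fst")
})

test_that("progeny segregate by Mendelian rules", {
  # forced: AA x AA -> AA; missing parent -> missing progeny
  parents <- rbind(c(0L, 2L, 1L, NA), c(0L, 2L, 1L, 0L))
  sp <- tiny_spec(n_progeny = 400, n_loci = 4)
  pr <- simulate_progeny(sp, parents)
  d <- pr$genotypes$dosage
  expect_true(all(d[, 1] == 0L))
  expect_true(all(d[, 2] == 2L))
  expect_true(all(is.na(d[, 4])))
  # AB x AB -> 1:2:1 within 3 SE
  n <- nrow(d)
  counts <- tabulate(d[, 3] + 1L, 3)
  for (k in 1:3) {
    pk <- c(0.25, 0.5, 0.25)[k]
    expect_lt(abs(counts[k] - n * pk), 3 * sqrt(n * pk * (1 - pk)))
  }
})

test_that("missing injection is binomial at the requested rate", {
  sp <- cohort_spec(n_loci = 1043, n_cultivars = 325,
                    clone_group_sizes = integer(), mutant_spec = list(),
                    n_wild = 0, n_progeny = 0, missing_rate = 0, seed = 2)
  cult <- simulate_cultivars(sp, draw_founder_frequencies(sp))
  gm0 <- cult$genotypes
  expect_identical(inject_missing(gm0, 0)$dosage, gm0$dosage)  # identity
  expect_error(inject_missing(gm0, 1), "rate")
  gm <- inject_missing(gm0, 0.01, seed = 4)
  n <- length(gm$dosage)
  expect_lt(abs(sum(is.na(gm$dosage)) - 0.01 * n),
            3 * sqrt(n * 0.01 * 0.99))
})
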