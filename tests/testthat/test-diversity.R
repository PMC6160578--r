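test_that("closed-form values at p = 0.5 and degenerate loci", {
  # 25/50/25 gives p exactly 0.5
  d <- cbind(half = rep(c(0L, 1L, 2L), c(25, 50, 25)),
             mono = rep(0L, 100),
             empty = rep(NA_integer_, 100))
  rownames(d) <- sprintf("s%d", 1:100)
  st <- locus_statistics(genotype_matrix(d, "A", "B"))
  h <- st[st$locus_id == "half", ]
  expect_equal(h$He, 0.5)
  expect_equal(h$Ne, 2.0)
  expect_equal(h$I, log(2))
  expect_equal(h$PIC, 0.375)
  expect_equal(h$MAF, 0.5)
  expect_equal(h$Ho, 0.5)
  expect_equal(h$uHe, (200 / 199) * 0.5)
  m <- st[st$locus_id == "mono", ]
  expect_equal(m$He, 0)
  expect_equal(m$I, 0)
  expect_equal(m$PIC, 0)
  expect_equal(m$Ne, 1)
  expect_true(is.na(m$F) && is.na(m$Fnull))  # undefined when monomorphic
  e <- st[st$locus_id == "empty", ]
  expect_true(all(is.na(e[c("Na", "Ne", "He", "Ho", "I", "PIC")])))
})

test_that("fixation and null-allele indices follow their definitions", {
  d <- cbind(L = rep(c(0L, 1L, 2L), c(33, 37, 30)))
  rownames(d) <- sprintf("s%d", 1:100)
  st <- locus_statistics(genotype_matrix(d, "A", "B"))
  p_alt <- (2 * 30 + 37) / 200
  he <- 1 - p_alt^2 - (1 - p_alt)^2
  expect_equal(st$F, 1 - 0.37 / he)
  expect_equal(st$Fnull, (he - 0.37) / (he + 0.37))
  # printed-style rounding: Ho 0.370 / He 0.329 gives F about -0.125
  expect_equal(round(1 - 0.370 / 0.329, 3), -0.125)
})

test_that("biallelic invariants hold across random loci", {
  set.seed(31)
  sp <- cohort_spec(n_loci = 300, n_cultivars = 80,
                    clone_group_sizes = integer(), mutant_spec = list(),
                    n_wild = 0, n_progeny = 0, missing_rate = 0.02, seed = 31)
  sim <- simulate_cohort(sp)
  st <- locus_statistics(sim$genotypes)
  ok <- !is.na(st$He)
  expect_true(all(st$He[ok] <= 0.5 + 1e-12))
  expect_true(all(st$I[ok] <= log(2) + 1e-12))
  expect_true(all(st$PIC[ok] <= 0.375 + 1e-12))
  expect_true(all(st$PIC[ok] <= st$He[ok] + 1e-12))       # PIC <= He
  expect_equal(st$Ne[ok], 1 / (1 - st$He[ok]))            # Ne = 1/(1-He)
  # Jensen: mean Ne >= 1/(1 - mean He)
  expect_gte(mean(st$Ne[ok]), 1 / (1 - mean(st$He[ok])))
})

test_that("exact HWE test matches brute-force enumeration", {
  cases <- list(c(25, 50, 25), c(50, 0, 50), c(0, 0, 40), c(3, 7, 90),
                c(10, 1, 10), c(0, 40, 0), c(12, 40, 48))
  for (cs in cases)
    expect_equal(hwe_exact_test(cs[1], cs[2], cs[3]),
                 naive_hwe_p(cs[1], cs[2], cs[3]), tolerance = 1e-9,
                 label = paste(cs, collapse = "/"))
  expect_equal(hwe_exact_test(25, 50, 25), 1, tolerance = 1e-12)
  expect_lt(hwe_exact_test(50, 0, 50), 1e-20)
  expect_equal(hwe_exact_test(0, 0, 40), 1)
  expect_error(hwe_exact_test(-1, 0, 5), "negative")
})

test_that("summaries report band fractions and extremes", {
  d <- cbind(a = rep(c(0L, 1L, 2L), c(25, 50, 25)), b = rep(0L, 100))
  rownames(d) <- sprintf("s%d", 1:100)
  st <- locus_statistics(genotype_matrix(d, "A", "B"))
  sm <- summarize_diversity(st)
  expect_equal(attr(sm, "fraction_monomorphic"), 0.5)
  expect_equal(attr(sm, "fraction_maf_30_50"), 0.5)
  he <- sm[sm$statistic == "He", ]
  expect_true(he$min <= he$mean && he$mean <= he$max)
  expect_equal(he$max, 0.5)
})

test_that("multi-allelic calls are supported and panels compare", {
  set.seed(5)
  n <- 60
  # 8-allele SSR-style panel
  alleles <- sprintf("a%d", 1:8)
  ssr <- sapply(1:5, function(j) {
    a <- sample(alleles, 2 * n, TRUE)
    paste(pmin(a[1:n], a[(n + 1):(2 * n)]),
          pmax(a[1:n], a[(n + 1):(2 * n)]), sep = "/")
  })
  dimnames(ssr) <- list(sprintf("s%d", 1:n), sprintf("S%d", 1:5))
  st_ssr <- locus_statistics(ssr)
  expect_true(all(st_ssr$Na > 2))
  expect_true(all(st_ssr$PIC <= st_ssr$He + 1e-12))
  # biallelic panel on the same samples
  d <- matrix(rbinom(n * 20, 2, 0.4), n, 20,
              dimnames = list(sprintf("s%d", 1:n), sprintf("B%d", 1:20)))
  st_snp <- locus_statistics(genotype_matrix(d, "A", "B"))
  cmp <- compare_marker_sets(st_ssr, st_snp, labels = c("SSR", "SNP"))
  expect_equal(cmp$parameter, c("Navg", "Ne", "Ho", "He", "I"))
  expect_gt(cmp$SSR[cmp$parameter == "Navg"], cmp$SNP[cmp$parameter == "Navg"])
  # identical input, identical columns
  cmp2 <- compare_marker_sets(st_snp, st_snp)
  expect_equal(cmp2[[2]], cmp2[[3]])
  # disjoint subsets rejected
  d2 <- d; rownames(d2) <- sprintf("t%d", 1:n)
  st_other <- locus_statistics(genotype_matrix(d2, "A", "B"))
  expect_error(compare_marker_sets(st_snp, st_other), "disjoint")
})

test_that("Ne varies little across nested core subsets", {
  sp <- cohort_spec(n_loci = 500, n_cultivars = 68,
                    clone_group_sizes = integer(), mutant_spec = list(),
                    n_wild = 0, n_progeny = 0, missing_rate = 0, seed = 44)
  sim <- simulate_cohort(sp)
  ids <- sample_ids(sim$genotypes)
  ne <- vapply(c(18, 27, 36, 45, 68), function(k) {
    mean(locus_statistics(sim$genotypes, subset = ids[1:k])$Ne, na.rm = TRUE)
  }, 0)
  expect_lt(max(ne) - min(ne), 0.05)
})
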