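test_that("architecture sampling honours the mixture and validates input", {
  spec <- arch_spec(m_snps = 1000, maf_range = c(0.05, 0.5),
                    effect = list(prop = 0, sd = 0),
                    interaction = list(prop = 0, sd = 0), seed = 1)
  truth <- sample_architecture(spec)
  expect_equal(nrow(truth), 1000)
  expect_true(all(truth$beta == 0) && all(truth$delta == 0))
  expect_true(all(truth$maf >= 0.05 & truth$maf <= 0.5))
  expect_true(all(diff(truth$pos) > 0))

  spec2 <- arch_spec(m_snps = 10000, effect = list(prop = 0.01, sd = 0.05),
                     seed = 2)
  truth2 <- sample_architecture(spec2)
  # exact count up to rounding, which sits well inside the binomial
  # (10000, 0.01) 99.9% interval [71, 133]
  expect_equal(sum(truth2$beta != 0), 100)

  # the reference-scale design: 50,335 SNPs
  expect_equal(nrow(sample_architecture(arch_spec(seed = 3))), 50335)

  expect_error(arch_spec(maf_range = c(0, 0.5)), "maf_range")
  expect_error(arch_spec(effect = list(prop = 1.2, sd = 1)), "proportions")
  expect_error(arch_spec(exposure_prevalence = 1), "prevalence")
  expect_error(arch_spec(m_snps = 0), "m_snps")
})

test_that("genotypes follow HWE, respect MAF bounds and are reproducible", {
  truth <- data.frame(snp_id = c("a", "b"), chrom = "1", pos = c(1, 2),
                      ea = "A", oa = "G", maf = c(0, 0.5), beta = 0, delta = 0)
  G <- simulate_genotypes(truth, 1e5, seed = 4)
  expect_true(all(G[, "a"] == 0))
  # sampled allele frequency of a MAF-0.5 SNP: binomial SE = sqrt(pq/2n)
  expect_lt(abs(mean(G[, "b"]) / 2 - 0.5), 0.005)

  G1 <- simulate_genotypes(truth, 50, seed = 9)
  G2 <- simulate_genotypes(truth, 50, seed = 9)
  expect_identical(G1, G2)
})

test_that("null genotype draws pass the module's own HWE test", {
  spec <- arch_spec(m_snps = 2000, maf_range = c(0.05, 0.5),
                    effect = list(prop = 0, sd = 0), seed = 5)
  truth <- sample_architecture(spec)
  G <- simulate_genotypes(truth, 1000, seed = 6)
  n2 <- colSums(G == 2); n1 <- colSums(G == 1); n0 <- colSums(G == 0)
  p <- hwe_test(n0, n1, n2)
  expect_gte(mean(p >= 1e-6), 0.9999)
})

test_that("exposure simulation matches prevalence and supports exact counts", {
  e <- simulate_exposure(50000, 0.3, seed = 7)
  expect_lt(abs(mean(e) - 0.3), 3 * sqrt(0.3 * 0.7 / 50000))
  ex <- simulate_exposure(1000, 0.3, seed = 8, exact = TRUE)
  expect_equal(sum(ex), 300)
  expect_error(simulate_exposure(10, 0), "prevalence")
  expect_error(simulate_exposure(10, 1), "prevalence")
})

test_that("phenotype model composes genetic, exposure and error terms", {
  truth <- data.frame(snp_id = "s1", chrom = "1", pos = 1, ea = "A", oa = "G",
                      maf = 0.4, beta = 1, delta = 0)
  spec <- arch_spec(m_snps = 1, exposure_main_effect = 0,
                    error_model = list(family = "none", sd = 0))
  G <- simulate_genotypes(truth, 200, seed = 10)
  y <- simulate_phenotype(G, truth, rep(0L, 200), spec)
  expect_identical(y, as.vector(G[, 1] * 1))   # identity: Y equals dosage

  expect_error(simulate_phenotype(G, truth, rep(0L, 10), spec), "dimension")

  # a GxE SNP raises phenotypic variance in the exposed stratum: per
  # stratum, Var(Y | E) = 2pq (beta + delta E)^2 + sigma^2
  truth$beta <- 0.3; truth$delta <- 0.8
  spec2 <- arch_spec(m_snps = 1, exposure_main_effect = 0,
                     error_model = list(family = "normal", sd = 1))
  G2 <- simulate_genotypes(truth, 20000, seed = 11)
  E <- simulate_exposure(20000, 0.5, seed = 12)
  y2 <- simulate_phenotype(G2, truth, E, spec2, seed = 13)
  pq2 <- 2 * 0.4 * 0.6
  v_exp <- var(y2[E == 1])   # expect 1 + 2pq (0.3 + 0.8)^2
  v_une <- var(y2[E == 0])   # expect 1 + 2pq 0.09
  expect_gt(v_exp, v_une)
  expect_lt(abs(v_exp - (1 + pq2 * 1.1^2)), 0.1)
  expect_lt(abs(v_une - (1 + pq2 * 0.09)), 0.1)
})

test_that("the skewed error family gives a BMI-like transformed trait", {
  spec <- arch_spec(m_snps = 50, maf_range = c(0.1, 0.5),
                    effect = list(prop = 0.2, sd = 0.05), seed = 14)
  truth <- sample_architecture(spec)
  G <- simulate_genotypes(truth, 2e5, seed = 15)
  E <- simulate_exposure(2e5, 0.3, seed = 16)
  y <- simulate_phenotype(G, truth, E, spec, seed = 17)
  raw <- to_raw_scale(y)
  expect_true(all(raw > 0))
  prep <- prepare_trait(raw)
  sk <- vqscreen:::.skewness(prep$values)
  expect_gt(sk, 0.3)
  expect_lt(sk, 0.8)
})

test_that("cohort splitting is a disjoint partition preserving metadata", {
  tc <- tiny_cohort(n = 100)
  data <- cohort_data(tc$G, tc$truth, tc$y, rep(0L, 100), "all")
  parts <- split_cohorts(data, c(50, 50), seed = 18)
  expect_length(parts, 2)
  expect_equal(sum(sapply(parts, function(p) length(p$phenotype))), 100)
  # disjoint: pooled phenotype values are a permutation of the input
  expect_equal(sort(c(parts[[1]]$phenotype, parts[[2]]$phenotype)),
               sort(tc$y))
  expect_identical(parts[[1]]$snp_meta, parts[[2]]$snp_meta)
  one <- split_cohorts(data, 100, seed = 19)
  expect_equal(sort(one[[1]]$phenotype), sort(tc$y))
  expect_error(split_cohorts(data, c(80, 40)), "exceed")
})

test_that("the full study generator is byte-deterministic under a fixed seed", {
  spec <- arch_spec(m_snps = 40, maf_range = c(0.1, 0.5), seed = NULL)
  s1 <- simulate_cohort_study(spec, 120, c(60, 60), seed = 20)
  s2 <- simulate_cohort_study(spec, 120, c(60, 60), seed = 20)
  expect_identical(serialize(s1, NULL), serialize(s2, NULL))

  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  write_cohort_data(s1$cohorts[[1]], d1)
  write_cohort_data(s2$cohorts[[1]], d2)
  f1 <- list.files(d1, full.names = TRUE)
  f2 <- list.files(d2, full.names = TRUE)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("marginal effects are recovered by the association scan", {
  spec <- arch_spec(m_snps = 400, maf_range = c(0.1, 0.5),
                    effect = list(prop = 0.25, sd = 0.08),
                    exposure_main_effect = 0,
                    error_model = list(family = "normal", sd = 1), seed = 21)
  truth <- sample_architecture(spec)
  G <- simulate_genotypes(truth, 10000, seed = 22)
  y <- simulate_phenotype(G, truth, rep(0L, 10000), spec, seed = 23)
  ms <- marginal_scan(G, y)
  cover <- abs(ms$beta - truth$beta) <= 3 * ms$se
  expect_gte(mean(cover), 0.99)
})
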