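test_that("genotype calling rounds dosages and honours the no-call threshold", {
  expect_equal(call_genotypes(c(1.9, 0.2, 1.4)), c(2L, 0L, 1L))
  expect_true(is.na(call_genotypes(0.5, threshold = 0.4)))
  expect_equal(call_genotypes(c(0, 1, 2)), c(0L, 1L, 2L))
  expect_error(call_genotypes(2.3), "0, 2")
})

test_that("group summaries match direct arithmetic and ignore row order", {
  # 12-individual cohort, hand-checkable
  y <- c(0.5, -1.2, 0.3, 1.8, -0.4, 0.9, -2.0, 0.1, 1.1, -0.6, 0.2, 0.7)
  g <- c(0, 0, 0, 0, 1, 1, 1, 1, 1, 2, 2, 2)
  s <- summarize_groups(g, y, "c1", snp_id = "rs1")
  for (k in 0:2) {
    yk <- y[g == k]
    zk <- abs(yk - mean(yk))
    expect_equal(s[[paste0("n", k)]], length(yk))
    expect_equal(s[[paste0("meanZ", k)]], mean(zk))
    expect_equal(s[[paste0("varZ", k)]], var(zk))
  }
  expect_equal(s$eaf, mean(g) / 2)

  perm <- sample(12)
  s2 <- summarize_groups(g[perm], y[perm], "c1", snp_id = "rs1")
  expect_equal(s, s2)

  # singleton group: variance undefined
  s3 <- summarize_groups(c(0, 0, 0, 1, 1, 2), rnorm(6), "c1")
  expect_equal(s3$n2, 1)
  expect_true(is.na(s3$varZ2))
  expect_false(is.na(s3$meanZ2))
})

test_that("HWE goodness-of-fit matches its closed forms", {
  expect_equal(hwe_test(8100, 1800, 100), 1)       # exact HWE proportions
  # all-heterozygote: chi-square equals n
  for (n in c(30, 100)) {
    expect_equal(hwe_test(0, n, 0), pchisq(n, 1, lower.tail = FALSE))
    expect_lt(hwe_test(0, n, 0), 1e-6)
  }
  expect_equal(hwe_test(0, 0, 50), 1)              # monomorphic convention
})

test_that("QC filters exclude with the documented reason codes", {
  set.seed(30)
  base <- summarize_groups(rbinom(2000, 2, 0.3), rnorm(2000), "c1")
  res <- qc_filter(base)
  expect_equal(nrow(res$retained), 1)

  low_maf <- base; low_maf$eaf <- 0.005
  expect_equal(qc_filter(low_maf)$exclusions$reason, "MAF")

  small_grp <- base
  small_grp$n0 <- 400; small_grp$n1 <- 200; small_grp$n2 <- 29
  expect_equal(qc_filter(small_grp)$exclusions$reason, "MIN_GROUP_N")

  bad_hwe <- base
  bad_hwe$n0 <- 0; bad_hwe$n1 <- 2000; bad_hwe$n2 <- 0; bad_hwe$eaf <- 0.5
  expect_equal(qc_filter(bad_hwe)$exclusions$reason, "HWE")

  low_info <- base; low_info$info <- 0.1
  expect_equal(qc_filter(low_info)$exclusions$reason, "INFO")

  low_cr <- base; low_cr$callrate <- 0.9
  expect_equal(qc_filter(low_cr)$exclusions$reason, "CALLRATE")

  # most permissive thresholds: identity
  lax <- qc_thresholds(info_min = 0, hwe_p = 0, callrate = 0, maf = 0,
                       min_group_n = 0)
  expect_equal(nrow(qc_filter(small_grp, lax)$retained), 1)
})

test_that("single-cohort meta-Levene reproduces the classical statistic", {
  set.seed(31)
  worst <- 0
  for (i in 1:50) {
    n <- sample(60:300, 1)
    g <- rbinom(n, 2, runif(1, 0.2, 0.5))
    if (length(unique(g)) < 3) next
    y <- rnorm(n)
    s <- summarize_groups(g, y, "c1")
    mv <- meta_levene(s)
    ld <- levene_direct(y, g)
    worst <- max(worst, abs(mv$L - ld$W) / max(ld$W, 1))
    expect_equal(mv$P_v, ld$p, tolerance = 1e-8)
    expect_equal(mv$df2, n - 3)
  }
  expect_lt(worst, 1e-8)
})

test_that("meta-Levene agrees with an independent Levene implementation", {
  set.seed(32)
  n <- 400
  g <- rbinom(n, 2, 0.35)
  y <- rnorm(n) * (1 + 0.4 * g)   # genuine variance heterogeneity
  mv <- meta_levene(summarize_groups(g, y, "c1"))
  ct <- car::leveneTest(y, factor(g), center = mean)
  expect_equal(mv$L, ct$`F value`[1], tolerance = 1e-10)
  expect_equal(mv$P_v, ct$`Pr(>F)`[1], tolerance = 1e-10)
})

test_that("meta-Levene pools cohorts exactly like pooled individuals", {
  set.seed(33)
  g1 <- rbinom(150, 2, 0.4); y1 <- rnorm(150)
  g2 <- rbinom(250, 2, 0.4); y2 <- rnorm(250, 0, 1.3)
  s <- rbind(summarize_groups(g1, y1, "A"), summarize_groups(g2, y2, "B"))
  mv <- meta_levene(s)
  # Z must be computed within cohort before pooling: build the pooled oracle
  # the same way from per-cohort deviations
  z <- c(absolute_deviations(y1, g1)$values, absolute_deviations(y2, g2)$values)
  g <- c(g1, g2)
  grp_mean <- tapply(z, g, mean)
  N <- length(z)
  ssb <- sum(tapply(z, g, length) * (grp_mean - mean(z))^2)
  ssw <- sum((z - grp_mean[as.character(g)])^2)
  W <- (N - 3) / 2 * ssb / ssw
  expect_equal(mv$L, W, tolerance = 1e-10)
  expect_equal(mv$N, N)

  # cohort order is irrelevant
  mv2 <- meta_levene(s[2:1, ])
  expect_equal(mv$L, mv2$L, tolerance = 1e-12)
})

test_that("meta-Levene degenerate and skip paths behave as specified", {
  set.seed(34)
  g <- rbinom(300, 2, 0.4)
  y <- rnorm(300)
  s <- summarize_groups(g, y, "c1")
  # equal group means of Z across cohorts -> L = 0, P = 1
  s$meanZ0 <- s$meanZ1 <- s$meanZ2 <- 0.5
  s$varZ0 <- s$varZ1 <- s$varZ2 <- 0.2
  mv <- meta_levene(s)
  expect_equal(mv$L, 0)
  expect_equal(mv$P_v, 1)

  # missing pooled genotype group -> skip with reason
  s2 <- summarize_groups(c(0, 0, 1, 1, 1, 0), rnorm(6), "c1")
  mv2 <- meta_levene(s2)
  expect_equal(mv2$reason, "MISSING_GROUP")
  expect_true(is.na(mv2$L))
})

test_that("inflating one genotype group's spread increases the statistic", {
  set.seed(35)
  g <- rbinom(500, 2, 0.4)
  y <- rnorm(500)
  W0 <- levene_direct(y, g)$W
  y_infl <- ifelse(g == 2, y * 3, y)     # spread one group's phenotype
  W1 <- levene_direct(y_infl, g)$W
  expect_gt(W1, W0)
  # and the statistic is invariant to overall scale
  expect_equal(levene_direct(y * 5, g)$W, W0, tolerance = 1e-12)
})

test_that("allele harmonization aligns, swaps or drops cohort rows", {
  set.seed(36)
  g <- rbinom(400, 2, 0.3)
  y <- rnorm(400)
  ref <- summarize_groups(g, y, "ref", snp_id = "rs1", ea = "A", oa = "G")
  # a second cohort reported on the other allele
  swapped <- summarize_groups(2 - g, y, "swp", snp_id = "rs1",
                              ea = "G", oa = "A")
  out <- harmonize_summaries(rbind(ref, swapped))
  expect_equal(nrow(out$harmonized), 2)
  h <- out$harmonized[2, ]
  expect_equal(h$ea, "A")
  expect_equal(h$n0, ref$n0)
  expect_equal(h$meanZ2, ref$meanZ2)
  expect_equal(h$eaf, ref$eaf, tolerance = 1e-12)
  # meta-analysis of the two aligned rows equals pooling the same data twice
  mv <- meta_levene(out$harmonized)
  expect_equal(mv$N, 800)

  # ambiguous A/T SNP with uninformative frequency is dropped
  amb_ref <- summarize_groups(g, y, "r", snp_id = "rs2", ea = "A", oa = "T")
  amb_ref$eaf <- 0.5
  amb2 <- summarize_groups(g, y, "s", snp_id = "rs2", ea = "A", oa = "T")
  amb2$eaf <- 0.5
  out2 <- harmonize_summaries(rbind(amb_ref, amb2))
  expect_true("AMBIGUOUS_STRAND" %in% out2$dropped$reason)
})

test_that("group summaries round-trip bit-stably through the exchange format", {
  set.seed(37)
  s <- rbind(summarize_groups(rbinom(200, 2, 0.3), rnorm(200), "A"),
             summarize_groups(c(0, 0, 0, 1, 1, 2), rnorm(6), "B"))
  path <- file.path(tempdir(), "summ.tsv")
  write_group_summaries(s, path)
  back <- read_group_summaries(path)
  expect_equal(back$meanZ1, s$meanZ1, tolerance = 1e-9)
  expect_true(is.na(back$varZ2[2]))       # '.' for undefined survives
  # writing the re-read table reproduces the file byte-for-byte
  path2 <- file.path(tempdir(), "summ2.tsv")
  write_group_summaries(back, path2)
  expect_identical(readLines(path), readLines(path2))

  bad <- back; bad$varZ2[2] <- 0.5        # variance defined for n < 2
  p3 <- file.path(tempdir(), "summ3.tsv")
  write_group_summaries(bad, p3)
  expect_error(read_group_summaries(p3), "n < 2")
})
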