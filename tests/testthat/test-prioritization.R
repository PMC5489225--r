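test_that("percentile ranks map the lowest P to the 100th percentile", {
  expect_equal(percentile_ranks(c(0.001, 0.5)), c(100, 50))
  # ties share the average-rank percentile
  expect_equal(percentile_ranks(rep(0.2, 4)), rep(100 * (4 - 2.5 + 1) / 4, 4))
  set.seed(71)
  p <- runif(1000)
  pct <- percentile_ranks(p)
  expect_equal(pct[which.min(p)], 100)
  expect_equal(sort(pct), seq(0.1, 100, 0.1), tolerance = 1e-12)
  # monotone decreasing in P
  expect_true(all(diff(pct[order(p)]) < 0))
  # non-finite excluded
  pct2 <- percentile_ranks(c(0.1, NA, 0.9))
  expect_true(is.na(pct2[2]))
  expect_equal(pct2[c(1, 3)], c(100, 50))
})

test_that("Spearman subset correlations match definition-based recomputation", {
  set.seed(72)
  x <- runif(300); y <- x^2 + 0           # strictly increasing function
  expect_equal(spearman_test(x, y)$rho, 1)
  y2 <- runif(300)
  st <- spearman_test(x, y2)
  expect_equal(st$rho, cor(x, y2, method = "spearman"), tolerance = 1e-12)
  ct <- suppressWarnings(cor.test(x, y2, method = "spearman", exact = FALSE))
  expect_equal(st$p, ct$p.value, tolerance = 1e-10)
  expect_equal(spearman_test(x, -y2)$rho, -st$rho, tolerance = 1e-12)

  tbl <- data.frame(P_m = x, P_v = y2)
  rep_ <- spearman_by_subset(tbl, subsets = list(all = rep(TRUE, 300),
                                                 low = x < 0.2))
  expect_equal(rep_$n, c(300, sum(x < 0.2)))
  expect_true(is.na(rep_$p_equality[1]))
  expect_false(is.na(rep_$p_equality[2]))
  # too-small subsets are flagged, not errors
  rep2 <- spearman_by_subset(tbl, subsets = list(all = rep(TRUE, 300),
                                                 none = x < 0))
  expect_true(is.na(rep2$rho[2]))
})

test_that("null Spearman correlations are small and non-significant", {
  # under independence rho is approximately N(0, 1/(m-1)); at m = 2000 that
  # puts |rho| < 0.05 at probability 2*pnorm(0.05*sqrt(1999)) - 1 = 0.9746,
  # and |rho| < 0.075 at 0.9992
  set.seed(73)
  rhos <- replicate(200, spearman_test(runif(2000), runif(2000))$rho)
  p_true <- 2 * pnorm(0.05 * sqrt(1999)) - 1
  mc_se <- sqrt(p_true * (1 - p_true) / 200)
  expect_gte(mean(abs(rhos) < 0.05), p_true - 3 * mc_se)
  expect_gte(mean(abs(rhos) < 0.075), 0.99)
})

test_that("the correlation equality test matches its closed form", {
  expect_equal(correlation_equality_test(0.3, 100, 0.3, 200), 1)
  # atanh(0.5) * sqrt(50) = 3.885 -> P = 1.02e-4
  p <- correlation_equality_test(0.5, 103, 0.0, 103)
  expect_equal(p, 2 * pnorm(-atanh(0.5) * sqrt(50)))
  expect_equal(p, 1.02e-4, tolerance = 1e-2)
  expect_equal(correlation_equality_test(0.0, 103, 0.5, 103), p)
  expect_error(correlation_equality_test(1, 10, 0, 10), "Fisher")
  expect_error(correlation_equality_test(0.2, 3, 0.1, 10), "n > 3")
})

test_that("exact binomial enrichment agrees with pmf summation", {
  pmf_oracle <- function(n, k, p) sum(dbinom(k:n, n, p))
  for (case in list(c(50, 3), c(200, 17), c(5000, 278), c(71, 10))) {
    n <- case[1]; k <- case[2]
    be <- binomial_enrichment(n, k)
    expect_equal(be$p, pmf_oracle(n, k, 0.05), tolerance = 1e-12)
    expect_equal(be$expected, n * 0.05)
  }
  expect_equal(binomial_enrichment(100, 0)$p, 1)
  expect_error(binomial_enrichment(10, 11), "k <= n")
  two <- binomial_enrichment(100, 10, alternative = "two.sided")
  expect_lte(two$p, 1)
  expect_gte(two$p, binomial_enrichment(100, 10)$p)
})

test_that("odds ratios and Woolf intervals match closed forms", {
  o <- odds_ratio_2x2(10, 10, 10, 10)
  expect_equal(o$or, 1)
  expect_true(o$ci[1] < 1 && o$ci[2] > 1)

  o2 <- odds_ratio_2x2(20, 10, 10, 20)
  expect_equal(o2$or, 4)
  se <- sqrt(1/20 + 1/10 + 1/10 + 1/20)
  expect_equal(o2$ci, exp(log(4) + c(-1, 1) * qnorm(0.975) * se))
  expect_equal(o2$ci, c(1.37, 11.7), tolerance = 0.01)

  o3 <- odds_ratio_2x2(40, 20, 20, 40)   # doubled: same OR, narrower CI
  expect_equal(o3$or, 4)
  expect_lt(diff(log(o3$ci)), diff(log(o2$ci)))

  o4 <- odds_ratio_2x2(5, 0, 3, 7)
  expect_true(o4$haldane)
  o5 <- odds_ratio_2x2(0, 3, 5, 0)
  expect_true(o5$undefined)
})

test_that("Mann-Whitney agrees with exhaustive enumeration for small samples", {
  set.seed(74)
  for (rep_i in 1:20) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    x <- rnorm(n1); y <- rnorm(n2)
    mt <- mw_test(x, y, method = "exact")
    expect_equal(mt$p, mw_enumerate_p(x, y), tolerance = 1e-12)
  }
  # against base wilcox.test in both regimes
  x <- rnorm(8); y <- rnorm(7, 0.5)
  expect_equal(mw_test(x, y, method = "exact")$p,
               wilcox.test(x, y, exact = TRUE)$p.value, tolerance = 1e-12)
  x2 <- rnorm(60); y2 <- rnorm(55, 0.3)
  expect_equal(mw_test(x2, y2, method = "normal")$p,
               wilcox.test(x2, y2, exact = FALSE, correct = FALSE)$p.value,
               tolerance = 1e-10)
  # identical pooled values: U at its mean, P = 1
  mt <- mw_test(rep(1, 5), rep(1, 6))
  expect_equal(mt$U, 15)
  expect_equal(mt$p, 1)
})

test_that("centile-shift tests split bands correctly and stay null-centred", {
  set.seed(75)
  m <- 5000
  split_p <- runif(m); test_p <- runif(m)
  sp <- percentile_ranks(split_p); tp <- percentile_ranks(test_p)
  rs <- rank_shift_test(sp, tp, 100)
  expect_equal(rs$n_band, sum(sp > 99))
  expect_equal(rs$n_rest, m - rs$n_band)
  # unselected group's median percentile sits near 50 under the null
  expect_lt(abs(rs$median_rest - 50), 2)
  rs99 <- rank_shift_test(sp, tp, 99)
  expect_equal(rs99$n_band, sum(sp > 98 & sp <= 99))
  expect_equal(rs99$n_band + rs99$n_rest, sum(sp <= 99))

  # tiny instance agrees with the enumeration oracle via the exact method
  sp6 <- percentile_ranks(c(0.001, 0.002, 0.003, 0.5, 0.6, 0.7))
  tp6 <- percentile_ranks(c(0.2, 0.9, 0.05, 0.4, 0.8, 0.3))
  rs6 <- rank_shift_test(sp6, tp6, 100, method = "exact")
  # here the "100th centile" band is the single lowest-P SNP
  expect_equal(rs6$p, mw_enumerate_p(tp6[which.max(sp6)], tp6[-which.max(sp6)]))

  expect_error(rank_shift_test(sp, tp, 98), "centile_band")
})

test_that("proximity exclusion respects chromosome and the inclusive window", {
  tbl <- data.frame(snp_id = c("a", "b", "c", "d", "e"),
                    chrom = c("1", "1", "1", "2", "1"),
                    pos = c(1e6, 1.5e6, 1.5e6 + 1, 1e6, 5e6))
  known <- data.frame(snp_id = "k", chrom = "1", pos = 1e6)
  mask <- exclude_proximal(tbl, known, window_bp = 5e5)
  expect_equal(mask, c(TRUE, TRUE, FALSE, FALSE, FALSE))
  # the known SNP itself is always excluded, wherever it sits
  tbl2 <- rbind(tbl, data.frame(snp_id = "k", chrom = "3", pos = 1))
  expect_true(tail(exclude_proximal(tbl2, known), 1))
  expect_equal(exclude_proximal(tbl, known[0, ]), rep(FALSE, 5))
})

test_that("average-rank enrichment combines two scans as specified", {
  set.seed(76)
  p1 <- percentile_ranks(runif(2000))
  # identical scans: the average is the rank itself
  ar <- average_rank_enrichment(p1, p1)
  expect_equal(ar$avg_rank, p1)
  expect_equal(ar$n, 2000)

  # independent uniform ranks: success rate near 0.005
  succ <- mean(replicate(50, {
    a <- percentile_ranks(runif(2000)); b <- percentile_ranks(runif(2000))
    mean((a + b) / 2 > 95)
  }))
  expect_lt(abs(succ - 0.005), 0.002)

  # missing-in-one-scan SNPs are excluded and counted
  p2 <- p1; p2[1:10] <- NA
  ar2 <- average_rank_enrichment(p1, p2)
  expect_equal(ar2$n, 1990)
  expect_equal(ar2$n_missing, 10)
})

test_that("rank tables carry percentiles and subset flags", {
  set.seed(77)
  meta <- data.frame(snp_id = paste0("s", 1:50), chrom = "1",
                     pos = seq(1e5, 5e6, length.out = 50))
  known <- meta[c(10, 40), ]
  tbl <- build_rank_table(meta, runif(50), runif(50),
                          P_int = list(ea = runif(50)),
                          pruned_ids = meta$snp_id[1:30], known = known)
  expect_equal(sum(tbl$is_known), 2)
  expect_true(all(tbl$near_known[tbl$is_known]))
  expect_equal(sum(tbl$in_pruned), 30)
  expect_equal(tbl$pct_v[which.min(tbl$P_v)], 100)
  expect_true("pct_int_ea" %in% names(tbl))
})
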