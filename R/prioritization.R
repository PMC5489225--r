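# Prioritization statistics: percentile-scaled ranks, subset Spearman
# correlations with equality tests, exact binomial enrichment, odds ratios,
# Mann-Whitney centile-shift tests, proximity exclusion, and average-rank
# enrichment across two interaction scans.

#' Percentile-scaled ranks of P-values
#'
#' P-values are ranked ascending (rank 1 = lowest P, average ranks for ties)
#' and rescaled so the lowest P maps to the 100th percentile:
#' percentile = 100 * (m - r + 1) / m. Non-finite P-values get NA.
#'
#' @param p numeric vector of P-values.
#' @return percentile vector in (0, 100].
#' @examples
#' percentile_ranks(c(0.001, 0.5))  # 100, 50
#' @export
percentile_ranks <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- is.finite(p)
  if (!any(ok)) stop("data error: no finite P-values")
  m <- sum(ok)
  r <- rank(p[ok], ties.method = "average")
  out[ok] <- 100 * (m - r + 1) / m
  out
}

#' Spearman rank correlation with t-approximation P-value
#'
#' rho is the Pearson correlation of average ranks; the two-sided P uses
#' t = rho * sqrt((n-2)/(1-rho^2)) on n-2 degrees of freedom.
#'
#' @param x,y numeric vectors.
#' @return list: n, rho, p.
#' @export
spearman_test <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  n <- sum(ok)
  if (n < 3) return(list(n = n, rho = NA_real_, p = NA_real_))
  rho <- stats::cor(rank(x[ok]), rank(y[ok]))
  if (abs(rho) >= 1) return(list(n = n, rho = rho, p = .P_FLOOR))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  list(n = n, rho = rho, p = .floor_p(2 * stats::pt(-abs(tstat), n - 2)))
}

#' Subset Spearman correlations between two P-value columns
#'
#' Computes the Spearman correlation between two P-value types over named
#' subsets of a rank table (e.g. all pruned SNPs; P_m < 0.05; P_m < 1e-4;
#' known loci) plus, for each non-reference subset, the Fisher-z test for
#' equality of its correlation with the reference subset's.
#'
#' @param tbl data.frame holding the two P columns.
#' @param x_col,y_col column names (default "P_m", "P_v").
#' @param subsets named list of logical vectors over rows of `tbl`; the first
#'   is the reference subset.
#' @return data.frame: subset, n, rho, p, p_equality (NA for the reference,
#'   or where a subset has fewer than 3 SNPs).
#' @export
spearman_by_subset <- function(tbl, x_col = "P_m", y_col = "P_v", subsets) {
  stopifnot(length(subsets) >= 1, !is.null(names(subsets)))
  res <- lapply(subsets, function(sel) {
    spearman_test(tbl[[x_col]][sel], tbl[[y_col]][sel])
  })
  ref <- res[[1]]
  peq <- vapply(seq_along(res), function(i) {
    if (i == 1 || is.na(res[[i]]$rho) || is.na(ref$rho)) return(NA_real_)
    correlation_equality_test(res[[i]]$rho, res[[i]]$n, ref$rho, ref$n)
  }, 0)
  data.frame(subset = names(subsets),
             n = vapply(res, `[[`, 0, "n"),
             rho = vapply(res, `[[`, 0, "rho"),
             p = vapply(res, `[[`, 0, "p"),
             p_equality = peq,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Test for equality of two correlations
#'
#' Fisher z-transform of both correlations; the statistic
#' (atanh(rho1) - atanh(rho2)) / sqrt(1/(n1-3) + 1/(n2-3)) is referred to a
#' standard normal, two-sided. This is the independent-samples form; when the
#' compared subsets are nested the overlap is ignored (documented behaviour,
#' matching common practice for this screen).
#'
#' @param rho1,n1,rho2,n2 correlations and sample sizes; |rho| < 1, n > 3.
#' @return two-sided P-value.
#' @examples
#' correlation_equality_test(0.5, 103, 0.0, 103)  # 1.02e-4
#' @export
correlation_equality_test <- function(rho1, n1, rho2, n2) {
  if (any(abs(c(rho1, rho2)) >= 1))
    stop("data error: |rho| must be < 1 for the Fisher transform")
  if (n1 <= 3 || n2 <= 3) stop("data error: need n > 3 in both groups")
  z <- (atanh(rho1) - atanh(rho2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  .floor_p(2 * stats::pnorm(-abs(z)))
}

#' Exact binomial enrichment test
#'
#' One-sided upper-tail exact binomial probability of observing at least `k`
#' successes among `n` eligible SNPs at the null rate (default 0.05, the
#' nominal significance level): P(X >= k), X ~ Binomial(n, null_rate).
#'
#' @param n_eligible number of eligible SNPs.
#' @param k_observed observed count below the significance threshold.
#' @param null_rate expected rate under no enrichment.
#' @param alternative "greater" (default, the screening question) or
#'   "two.sided" (doubled one-tail, capped at 1).
#' @return list: n, k, expected, p.
#' @examples
#' binomial_enrichment(71, 10)$p    # 3e-3 at printed precision
#' binomial_enrichment(2351, 182)$p # 8.63e-9
#' @export
binomial_enrichment <- function(n_eligible, k_observed, null_rate = 0.05,
                                alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (k_observed < 0 || k_observed > n_eligible)
    stop("data error: need 0 <= k <= n")
  if (null_rate <= 0 || null_rate >= 1)
    stop("configuration error: null_rate must be in (0, 1)")
  p_up <- stats::pbinom(k_observed - 1, n_eligible, null_rate,
                        lower.tail = FALSE)
  p <- if (alternative == "greater") p_up else {
    p_lo <- stats::pbinom(k_observed, n_eligible, null_rate)
    min(1, 2 * min(p_up, p_lo))
  }
  list(n = n_eligible, k = k_observed, expected = n_eligible * null_rate,
       p = p)
}

#' Odds ratio of a 2x2 table with Woolf confidence interval
#'
#' OR = ad/bc with 95% CI exp(log OR +/- 1.96 * sqrt(1/a+1/b+1/c+1/d)).
#' When any cell is zero the Haldane-Anscombe 0.5 correction is applied to
#' all cells (flagged); a zero diagonal leaves the OR undefined.
#'
#' @param a,b,c,d cell counts; rows index one P-threshold indicator, columns
#'   the other (a = both below threshold).
#' @return list: or, ci (length 2), haldane (logical), undefined (logical).
#' @export
odds_ratio_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0)) stop("data error: negative cell count")
  if ((a == 0 && d == 0) || (b == 0 && c == 0))
    return(list(or = NA_real_, ci = c(NA_real_, NA_real_),
                haldane = FALSE, undefined = TRUE))
  haldane <- any(cells == 0)
  if (haldane) cells <- cells + 0.5
  lo <- log(cells[1]) + log(cells[4]) - log(cells[2]) - log(cells[3])
  se <- sqrt(sum(1 / cells))
  list(or = exp(lo), ci = exp(lo + c(-1, 1) * stats::qnorm(0.975) * se),
       haldane = haldane, undefined = FALSE)
}

#' Mann-Whitney U test (rank-sum)
#'
#' Two-sided test that two samples come from the same distribution. The
#' exact null distribution (base `pwilcox`) is used when both groups are
#' small and there are no ties; otherwise the normal approximation with
#' tie-corrected variance (no continuity correction) is used.
#'
#' @param x,y numeric samples.
#' @param method "auto" (default), "exact" or "normal".
#' @param exact_max use the exact distribution when n1+n2 does not exceed
#'   this (and no ties) under "auto".
#' @return list: U (for `x`), n1, n2, z (NA for exact), p.
#' @export
mw_test <- function(x, y, method = c("auto", "exact", "normal"),
                    exact_max = 50) {
  method <- match.arg(method)
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) stop("data error: empty group")
  r <- rank(c(x, y))
  ties <- any(duplicated(c(x, y)))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  use_exact <- method == "exact" ||
    (method == "auto" && !ties && (n1 + n2) <= exact_max)
  if (use_exact && !ties) {
    # two-sided: double the smaller tail, capped at 1 (wilcox.test convention)
    p_lo <- stats::pwilcox(U, n1, n2)
    p_hi <- stats::pwilcox(U - 1, n1, n2, lower.tail = FALSE)
    p <- min(1, 2 * min(p_lo, p_hi))
    return(list(U = U, n1 = n1, n2 = n2, z = NA_real_, p = p))
  }
  N <- n1 + n2
  mu <- n1 * n2 / 2
  tie_tab <- table(r)
  sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
  if (sigma2 <= 0) return(list(U = U, n1 = n1, n2 = n2, z = 0, p = 1))
  z <- (U - mu) / sqrt(sigma2)
  list(U = U, n1 = n1, n2 = n2, z = z, p = min(1, 2 * stats::pnorm(-abs(z))))
}

#' Centile-shift (rank-shift) test between P-value types
#'
#' Splits SNPs by a centile band of one P-type's percentile ranks and asks,
#' via the Mann-Whitney U test, whether the other P-type's percentile ranks
#' differ between the band and the comparison group. Band conventions:
#' the "100th centile" is percentile > 99; the "99th centile" is
#' 98 < percentile <= 99, compared against the 98th-1st centiles
#' (percentile <= 98).
#'
#' @param split_pct percentile ranks (from [percentile_ranks()]) of the
#'   splitting P-type.
#' @param test_pct percentile ranks of the tested P-type.
#' @param centile_band 100 (top band vs all the rest) or 99 (the 99th band
#'   vs the 98th-1st).
#' @param exclude optional logical mask of SNPs to drop first (e.g. from
#'   [exclude_proximal()]).
#' @param method Mann-Whitney method, see [mw_test()]; default "normal".
#' @return list: n_band, n_rest, median_band, median_rest, U, z, p.
#' @export
rank_shift_test <- function(split_pct, test_pct, centile_band = 100,
                            exclude = NULL, method = "normal") {
  stopifnot(length(split_pct) == length(test_pct))
  keep <- is.finite(split_pct) & is.finite(test_pct)
  if (!is.null(exclude)) keep <- keep & !exclude
  sp <- split_pct[keep]; tp <- test_pct[keep]
  if (centile_band == 100) {
    in_band <- sp > 99
    in_rest <- !in_band
  } else if (centile_band == 99) {
    in_band <- sp > 98 & sp <= 99
    in_rest <- sp <= 98
  } else {
    stop("configuration error: centile_band must be 100 or 99")
  }
  if (!any(in_band) || !any(in_rest)) stop("data error: empty centile band")
  mw <- mw_test(tp[in_band], tp[in_rest], method = method)
  list(n_band = sum(in_band), n_rest = sum(in_rest),
       median_band = stats::median(tp[in_band]),
       median_rest = stats::median(tp[in_rest]),
       U = mw$U, z = mw$z, p = mw$p)
}

#' Mask SNPs at or near known loci
#'
#' TRUE for any SNP on the same chromosome within +/- `window_bp` (inclusive)
#' of a known-locus position, and for the known SNPs themselves (matched by
#' id). SNPs with missing coordinates are retained with a warning.
#'
#' @param tbl data.frame with snp_id, chrom, pos.
#' @param known data.frame with snp_id, chrom, pos (known/lead SNPs).
#' @param window_bp exclusion half-width in base pairs (default 500,000).
#' @return logical mask over rows of `tbl`.
#' @export
exclude_proximal <- function(tbl, known, window_bp = 5e5) {
  mask <- tbl$snp_id %in% known$snp_id
  if (!nrow(known)) return(mask)
  nocoord <- is.na(tbl$chrom) | is.na(tbl$pos)
  if (any(nocoord))
    warning(sum(nocoord), " SNP(s) lack coordinates; retained")
  for (ch in unique(known$chrom)) {
    kp <- known$pos[known$chrom == ch]
    on_ch <- which(!nocoord & tbl$chrom == ch)
    if (!length(on_ch)) next
    # nearest known position is within the window <=> some known one is
    d <- vapply(tbl$pos[on_ch], function(p) min(abs(p - kp)), 0)
    mask[on_ch] <- mask[on_ch] | d <= window_bp
  }
  mask
}

#' Average-rank enrichment across two interaction scans
#'
#' Averages, per SNP, the percentile ranks from two exposure-specific
#' interaction scans and tests whether more eligible SNPs exceed the centile
#' cut than expected: success = average rank > `centile_cut`, null rate
#' (100 - centile_cut)/100, one-sided exact binomial.
#'
#' @param pct1,pct2 percentile ranks from the two scans (same SNP order).
#' @param eligible logical mask of eligible SNPs (e.g. known loci).
#' @param centile_cut percentile cut (default 95).
#' @return list as [binomial_enrichment()] plus `avg_rank` (full vector) and
#'   `n_missing` (eligible SNPs absent from a scan).
#' @export
average_rank_enrichment <- function(pct1, pct2, eligible = NULL,
                                    centile_cut = 95) {
  stopifnot(length(pct1) == length(pct2))
  if (is.null(eligible)) eligible <- rep(TRUE, length(pct1))
  avg <- (pct1 + pct2) / 2
  use <- eligible & is.finite(avg)
  n_missing <- sum(eligible & !is.finite(avg))
  res <- binomial_enrichment(sum(use), sum(avg[use] > centile_cut),
                             null_rate = (100 - centile_cut) / 100)
  res$avg_rank <- avg
  res$n_missing <- n_missing
  res
}

#' Assemble a rank table
#'
#' Joins the marginal, variance and (optional) interaction scan results into
#' the per-SNP table the prioritization statistics operate on, adding
#' percentile-scaled ranks and subset flags.
#'
#' @param snp_meta data.frame snp_id, chrom, pos.
#' @param P_m,P_v numeric P-value vectors aligned to `snp_meta`.
#' @param P_int optional named list of P_int vectors (one per exposure).
#' @param pruned_ids SNP ids in the pruned set (default: all).
#' @param known data.frame of known loci (snp_id, chrom, pos); optional.
#' @param window_bp proximity window for the exclusion flag.
#' @return data.frame with P columns, `pct_*` percentile columns, and flags
#'   `in_pruned`, `is_known`, `near_known`.
#' @export
build_rank_table <- function(snp_meta, P_m, P_v, P_int = NULL,
                             pruned_ids = NULL, known = NULL,
                             window_bp = 5e5) {
  tbl <- data.frame(snp_id = snp_meta$snp_id, chrom = snp_meta$chrom,
                    pos = snp_meta$pos, P_m = P_m, P_v = P_v,
                    stringsAsFactors = FALSE)
  tbl$pct_m <- percentile_ranks(P_m)
  tbl$pct_v <- percentile_ranks(P_v)
  if (!is.null(P_int)) {
    for (nm in names(P_int)) {
      tbl[[paste0("P_int_", nm)]] <- P_int[[nm]]
      tbl[[paste0("pct_int_", nm)]] <- percentile_ranks(P_int[[nm]])
    }
  }
  tbl$in_pruned <- if (is.null(pruned_ids)) TRUE else tbl$snp_id %in% pruned_ids
  if (!is.null(known)) {
    tbl$is_known <- tbl$snp_id %in% known$snp_id
    tbl$near_known <- exclude_proximal(tbl, known, window_bp)
  } else {
    tbl$is_known <- FALSE
    tbl$near_known <- FALSE
  }
  tbl
}
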