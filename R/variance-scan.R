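# Variance-heterogeneity scan: per-cohort genotype-group summaries, QC, and
# the summary-statistic meta-analysis of Levene's test.

#' Call hard genotypes from dosages
#'
#' Classes are the nearest integer in 0/1/2. With a hard-call threshold `t`,
#' dosages whose distance to the nearest integer exceeds `t` are set missing;
#' the default `t = 0.5` never declares a call missing.
#'
#' @param dosage numeric vector in [0, 2] (NA allowed).
#' @param threshold maximum allowed distance to the nearest integer.
#' @return integer vector of 0/1/2 with NA for no-calls.
#' @export
call_genotypes <- function(dosage, threshold = 0.5) {
  ok <- !is.na(dosage)
  if (any(ok & (dosage < 0 | dosage > 2)))
    stop("data error: dosage outside [0, 2]")
  g <- as.integer(floor(dosage + 0.5))
  g[ok & abs(dosage - g) > threshold] <- NA_integer_
  g
}

#' Genotype-group summaries for a whole cohort
#'
#' Vectorized workhorse behind [summarize_groups()]: per-genotype counts,
#' means and sample variances of the absolute deviations Z for every SNP in
#' a dosage matrix, one row per SNP in the cohort submission format.
#'
#' @param genotypes n x m dosage matrix (column names = SNP ids).
#' @param prepared `prepared_phenotype` or numeric trait vector.
#' @param cohort_id cohort label.
#' @param snp_meta optional per-SNP data.frame with `ea`, `oa`.
#' @param info optional per-SNP imputation quality vector.
#' @param call_threshold hard-call distance threshold (see
#'   [call_genotypes()]).
#' @return data.frame, one row per SNP (format of [summarize_groups()]).
#' @export
summarize_cohort <- function(genotypes, prepared, cohort_id,
                             snp_meta = NULL, info = NULL,
                             call_threshold = 0.5) {
  y <- .pheno_values(prepared)
  n <- nrow(genotypes)
  m <- ncol(genotypes)
  stopifnot(length(y) == n)
  # hard calls (no-op for integer dosages)
  G <- genotypes
  if (!is.integer(G[1])) {
    rng <- range(G, na.rm = TRUE)
    if (rng[1] < 0 || rng[2] > 2) stop("data error: dosage outside [0, 2]")
    Gc <- floor(G + 0.5)
    Gc[!is.na(G) & abs(G - Gc) > call_threshold] <- NA
    G <- Gc
  }
  fast <- !anyNA(G) && !anyNA(y)
  if (fast) {
    # Genotypes take only the values 0/1/2, so the three group indicators are
    # quadratic polynomials in G (I1 = 2G - G^2, I2 = (G^2 - G)/2,
    # I0 = 1 - I1 - I2) and every per-group column sum reduces to column sums
    # of G- and G^2-weighted quantities. This avoids materializing mask
    # matrices and is the hot path of the calibration harness.
    G2 <- G * G
    C1 <- colSums(G); C2 <- colSums(G2)
    n2g <- (C2 - C1) / 2
    n1g <- 2 * C1 - C2
    n0g <- n - n1g - n2g
    cnt <- rbind(n0g, n1g, n2g)
    W1 <- as.vector(crossprod(G, y)); W2 <- as.vector(crossprod(G2, y))
    sy <- sum(y)
    s1 <- 2 * W1 - W2
    s2 <- (W2 - W1) / 2
    s0 <- sy - s1 - s2
    meanY <- rbind(ifelse(n0g > 0, s0 / n0g, NA),
                   ifelse(n1g > 0, s1 / n1g, NA),
                   ifelse(n2g > 0, s2 / n2g, NA))
    # group mean as a per-column quadratic mu(g) = a + b g + c g^2
    mu0 <- ifelse(is.na(meanY[1, ]), 0, meanY[1, ])
    mu1 <- ifelse(is.na(meanY[2, ]), 0, meanY[2, ])
    mu2 <- ifelse(is.na(meanY[3, ]), 0, meanY[3, ])
    cc <- (mu2 - 2 * mu1 + mu0) / 2
    bb <- mu1 - mu0 - cc
    M <- rep(mu0, each = n) + G * rep(bb, each = n) + G2 * rep(cc, each = n)
    Z <- abs(y - M)
    Z2 <- Z * Z
    T1 <- colSums(Z * G); T2 <- colSums(Z * G2); T0 <- colSums(Z)
    U1 <- colSums(Z2 * G); U2 <- colSums(Z2 * G2); U0 <- colSums(Z2)
    sZ1 <- 2 * T1 - T2; sZ2g <- (T2 - T1) / 2; sZ0 <- T0 - sZ1 - sZ2g
    qZ1 <- 2 * U1 - U2; qZ2 <- (U2 - U1) / 2; qZ0 <- U0 - qZ1 - qZ2
    sZ <- rbind(sZ0, sZ1, sZ2g)
    qZ <- rbind(qZ0, qZ1, qZ2)
    callrate <- rep(1, m)
    eaf <- C1 / (2 * n)
  } else {
    yok <- as.numeric(!is.na(y))
    y0 <- ifelse(is.na(y), 0, y)
    gmiss <- is.na(G)
    callrate <- 1 - colSums(gmiss) / n
    Gz <- G
    if (any(gmiss)) Gz[gmiss] <- -1  # sentinel, matches no group
    eaf_n <- colSums((!gmiss))
    eaf <- colSums(ifelse(gmiss, 0, G)) / (2 * eaf_n)
    cnt <- matrix(0, 3, m)
    meanY <- matrix(NA_real_, 3, m)
    masks <- vector("list", 3)
    for (k in 0:2) {
      Mk <- (Gz == k) * yok         # numeric 0/1 mask: genotype k, phenotype ok
      masks[[k + 1]] <- Mk
      cnt[k + 1, ] <- colSums(Mk)
      meanY[k + 1, ] <- ifelse(cnt[k + 1, ] > 0,
                               colSums(Mk * y0) / cnt[k + 1, ], NA)
    }
    # per-individual group mean at each SNP, then Z = |Y - group mean|
    Mu <- matrix(0, n, m)
    for (k in 0:2) {
      mu_k <- ifelse(is.na(meanY[k + 1, ]), 0, meanY[k + 1, ])
      Mu <- Mu + masks[[k + 1]] * rep(mu_k, each = n)
    }
    Z <- abs(y0 - Mu)                # only meaningful where some mask is 1
    sZ <- matrix(0, 3, m); qZ <- matrix(0, 3, m)
    for (k in 0:2) {
      sZ[k + 1, ] <- colSums(masks[[k + 1]] * Z)
      qZ[k + 1, ] <- colSums(masks[[k + 1]] * Z^2)
    }
  }
  out <- data.frame(snp_id = colnames(genotypes), cohort = cohort_id,
                    stringsAsFactors = FALSE)
  if (!is.null(snp_meta)) {
    out$ea <- snp_meta$ea
    out$oa <- snp_meta$oa
  } else {
    out$ea <- "A"; out$oa <- "G"
  }
  out$eaf <- eaf
  out$info <- if (is.null(info)) NA_real_ else info
  out$callrate <- callrate
  for (k in 0:2) {
    nk <- cnt[k + 1, ]
    mk <- ifelse(nk > 0, sZ[k + 1, ] / nk, NA)
    vk <- ifelse(nk > 1, pmax(qZ[k + 1, ] - nk * mk^2, 0) / (nk - 1), NA)
    out[[paste0("n", k)]] <- nk
    out[[paste0("meanZ", k)]] <- mk
    out[[paste0("varZ", k)]] <- vk
  }
  out
}

#' Genotype-group summary statistics for one SNP in one cohort
#'
#' Computes per-genotype counts, means and sample variances (n-1 denominator)
#' of the absolute deviations Z for a single SNP; the row format is the
#' cohort submission a central Levene meta-analysis consumes.
#'
#' @param dosage dosage vector for the SNP.
#' @param prepared `prepared_phenotype` or numeric trait vector.
#' @param cohort_id cohort label.
#' @param snp_id SNP id (default "snp").
#' @param ea,oa effect / other allele labels.
#' @param info optional imputation quality score.
#' @return one-row data.frame: snp_id, cohort, ea, oa, eaf, info, callrate,
#'   n0..n2, meanZ0..meanZ2, varZ0..varZ2 (variance NA where a group has
#'   fewer than 2 members).
#' @export
summarize_groups <- function(dosage, prepared, cohort_id, snp_id = "snp",
                             ea = "A", oa = "G", info = NA_real_) {
  G <- matrix(dosage, ncol = 1, dimnames = list(NULL, snp_id))
  s <- summarize_cohort(G, prepared, cohort_id,
                        snp_meta = data.frame(ea = ea, oa = oa), info = info)
  s
}

#' Hardy-Weinberg equilibrium goodness-of-fit test
#'
#' One-degree-of-freedom chi-square test of observed genotype counts against
#' HWE expectations at the observed allele frequency. Monomorphic SNPs return
#' P = 1 by convention.
#'
#' @param n0,n1,n2 genotype counts (vectorized).
#' @return P-value vector.
#' @examples
#' hwe_test(8100, 1800, 100)  # exact HWE proportions -> 1
#' @export
hwe_test <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  if (any(n < 1)) stop("data error: empty genotype table")
  p <- (n1 + 2 * n2) / (2 * n)
  e0 <- n * (1 - p)^2
  e1 <- n * 2 * p * (1 - p)
  e2 <- n * p^2
  chi <- rep(0, length(n))
  poly <- p > 0 & p < 1
  chi[poly] <- ((n0 - e0)^2 / e0 + (n1 - e1)^2 / e1 + (n2 - e2)^2 / e2)[poly]
  stats::pchisq(chi, df = 1, lower.tail = FALSE)
}

#' Default quality-control thresholds
#'
#' The reference filter set: imputation info below platform-specific bounds,
#' HWE P < 1e-6, call rate < 95%, MAF < 1%, and fewer than 30 individuals in
#' any genotype group per cohort.
#'
#' @param info_min minimum imputation quality (NA info always passes).
#' @param hwe_p HWE exclusion threshold.
#' @param callrate minimum call rate.
#' @param maf minimum minor allele frequency.
#' @param min_group_n minimum per-genotype-group count per cohort.
#' @param strict_groups if TRUE (default) a cohort must have all three groups
#'   at `min_group_n` or more to contribute a SNP; if FALSE, undersized groups
#'   are masked out and the cohort contributes the remaining groups.
#' @return list of thresholds.
#' @export
qc_thresholds <- function(info_min = 0.3, hwe_p = 1e-6, callrate = 0.95,
                          maf = 0.01, min_group_n = 30, strict_groups = TRUE) {
  list(info_min = info_min, hwe_p = hwe_p, callrate = callrate, maf = maf,
       min_group_n = min_group_n, strict_groups = strict_groups)
}

#' Apply QC filters to genotype-group summaries
#'
#' A SNP x cohort row is retained iff it passes every filter; each exclusion
#' is logged with a reason code (INFO, HWE, CALLRATE, MAF, MIN_GROUP_N).
#'
#' @param summaries summary rows (format of [summarize_groups()]).
#' @param thresholds list from [qc_thresholds()].
#' @return list with `retained` (filtered rows) and `exclusions`
#'   (data.frame snp_id, cohort, reason).
#' @export
qc_filter <- function(summaries, thresholds = qc_thresholds()) {
  th <- thresholds
  s <- summaries
  reason <- rep(NA_character_, nrow(s))
  mafv <- pmin(s$eaf, 1 - s$eaf)
  fail_info <- !is.na(s$info) & s$info < th$info_min
  hwe <- hwe_test(s$n0, s$n1, s$n2)
  fail_hwe <- hwe < th$hwe_p
  fail_cr <- s$callrate < th$callrate
  fail_maf <- mafv < th$maf
  if (th$strict_groups) {
    fail_grp <- s$n0 < th$min_group_n | s$n1 < th$min_group_n |
      s$n2 < th$min_group_n
  } else {
    # mask undersized groups instead of dropping the cohort
    for (k in 0:2) {
      small <- s[[paste0("n", k)]] < th$min_group_n
      s[[paste0("n", k)]][small] <- 0L
      s[[paste0("meanZ", k)]][small] <- NA_real_
      s[[paste0("varZ", k)]][small] <- NA_real_
    }
    fail_grp <- (s$n0 > 0) + (s$n1 > 0) + (s$n2 > 0) < 2
  }
  # first failing filter wins, in the order the filters are stated
  reason[fail_grp] <- "MIN_GROUP_N"
  reason[fail_maf] <- "MAF"
  reason[fail_cr] <- "CALLRATE"
  reason[fail_hwe] <- "HWE"
  reason[fail_info] <- "INFO"
  keep <- is.na(reason)
  list(retained = s[keep, , drop = FALSE],
       exclusions = data.frame(snp_id = s$snp_id[!keep],
                               cohort = s$cohort[!keep],
                               reason = reason[!keep],
                               stringsAsFactors = FALSE))
}

#' Meta-analysis of Levene's test from genotype-group summaries
#'
#' Pools per-cohort genotype-group counts, means and sample variances of the
#' absolute deviations Z into the combined Levene statistic
#' \deqn{L = \frac{N-3}{2} \cdot
#'   \frac{\sum_i \gamma_i \bar Z_i^2 - (\sum_i \gamma_i \bar Z_i)^2}
#'        {\sum_i \gamma_i [\sum_s (\omega_{is} - 1/n_i)\sigma^2_{Zis}
#'          + \omega_{is}\bar Z_{is}^2] - \gamma_i \bar Z_i^2}}
#' with natural weights \eqn{\omega_{is} = n_{is}/n_i} (within-group study
#' weights) and \eqn{\gamma_i = n_i/N} (group weights), and
#' \eqn{\bar Z_i = \sum_s \omega_{is}\bar Z_{is}}. The per-study correction
#' term is read as \eqn{\sigma^2_{Zis}/(N\gamma_i) = \sigma^2_{Zis}/n_i}: under
#' this reading the denominator equals the pooled within-group sum of squares
#' divided by N, so with a single cohort L reproduces the classical
#' mean-centered Levene statistic exactly — the binding contract of this
#' implementation. P_v is the upper tail of F(2, N-3) at L.
#'
#' Groups of size 1 contribute their mean but no variance term (the sample
#' variance is undefined; its weight (n_is - 1)/n_i is zero). SNPs lacking any
#' of the three genotype groups after pooling, or with N - 3 < 1, are skipped
#' with a reason code.
#'
#' @param summaries QC-passed summary rows for one or more SNPs across
#'   cohorts (format of [summarize_groups()]); alleles must already be
#'   harmonized (see [harmonize_summaries()]).
#' @return data.frame, one row per SNP: snp_id, N, L, df1, df2, P_v,
#'   n_cohorts, reason (NA when computed), flag_underflow.
#' @export
meta_levene <- function(summaries) {
  s <- summaries
  snps <- unique(s$snp_id)
  key <- match(s$snp_id, snps)
  ns <- length(snps)
  n_i <- matrix(0, ns, 3)        # pooled group counts, SNP x genotype
  sumZ <- matrix(0, ns, 3)       # sum of n_is * meanZ_is
  ssw <- matrix(0, ns, 3)        # within-group sum of squares accumulator
  for (k in 0:2) {
    nk <- as.numeric(s[[paste0("n", k)]])
    mk0 <- ifelse(is.na(s[[paste0("meanZ", k)]]), 0, s[[paste0("meanZ", k)]])
    vk0 <- ifelse(is.na(s[[paste0("varZ", k)]]), 0, s[[paste0("varZ", k)]])
    # per-study contributions: count, n*meanZ, and (n-1)*var + n*meanZ^2
    # (the -n_i*Zbar_i^2 completing the within-group SS is applied below);
    # rowsum over key 1..ns returns rows in key order
    acc <- rowsum(cbind(nk, nk * mk0, (nk - 1) * vk0 * (nk > 1) + nk * mk0^2),
                  key)
    n_i[, k + 1] <- acc[, 1]
    sumZ[, k + 1] <- acc[, 2]
    ssw[, k + 1] <- acc[, 3]
  }
  n_coh <- as.vector(rowsum(rep(1L, nrow(s)), key))
  N <- rowSums(n_i)
  zbar_i <- ifelse(n_i > 0, sumZ / n_i, NA)
  ssw_i <- ssw - ifelse(n_i > 0, n_i * zbar_i^2, 0)
  ssw_tot <- rowSums(pmax(ssw_i, 0), na.rm = TRUE)
  zbar <- rowSums(sumZ) / N
  ssb <- rowSums(n_i * (zbar_i - zbar)^2, na.rm = TRUE)

  have3 <- rowSums(n_i > 0) == 3
  df2 <- N - 3
  L <- rep(NA_real_, ns)
  P <- rep(NA_real_, ns)
  reason <- rep(NA_character_, ns)
  flag <- rep(FALSE, ns)
  reason[!have3] <- "MISSING_GROUP"
  reason[have3 & df2 < 1] <- "DF"
  ok <- have3 & df2 >= 1
  L[ok] <- (df2[ok] / 2) * ssb[ok] / ssw_tot[ok]
  degen <- ok & ssw_tot == 0
  L[degen & ssb == 0] <- 0
  # zero denominator with nonzero numerator: perfect separation of group
  # spreads; report the floored P
  L[degen & ssb > 0] <- Inf
  P[ok] <- stats::pf(L[ok], 2, df2[ok], lower.tail = FALSE)
  P[degen & ssb == 0] <- 1
  P[degen & ssb > 0] <- .P_FLOOR
  flag[ok & P < .P_FLOOR] <- TRUE
  P[ok] <- .floor_p(P[ok])
  data.frame(snp_id = snps, N = N, L = L, df1 = 2, df2 = df2, P_v = P,
             n_cohorts = n_coh, reason = reason, flag_underflow = flag,
             stringsAsFactors = FALSE)
}

#' Classical individual-level Levene test (mean-centered)
#'
#' Direct one-way ANOVA on the absolute deviations Z for one SNP:
#' W = [(N-k)/(k-1)] * sum n_i (Zbar_i - Zbar)^2 / sum (Z_ij - Zbar_i)^2 with
#' k the number of non-empty genotype groups; P from F(k-1, N-k). Serves as
#' the individual-level check on [meta_levene()].
#'
#' @param prepared `prepared_phenotype` or numeric trait vector.
#' @param genotype_classes 0/1/2 classes (NA excluded).
#' @return list with `W`, `df1`, `df2`, `p`.
#' @export
levene_direct <- function(prepared, genotype_classes) {
  y <- .pheno_values(prepared)
  g <- genotype_classes
  use <- !is.na(y) & !is.na(g)
  y <- y[use]; g <- g[use]
  groups <- sort(unique(g))
  k <- length(groups)
  N <- length(y)
  if (k < 2 || N <= k) stop("data error: need >= 2 non-empty groups and N > k")
  z <- absolute_deviations(y, g)$values
  zb_i <- tapply(z, g, mean)
  n_g <- tapply(z, g, length)
  zb <- mean(z)
  num <- sum(n_g * (zb_i - zb)^2)
  den <- sum((z - zb_i[as.character(g)])^2)
  if (den == 0) {
    W <- if (num == 0) 0 else Inf
  } else {
    W <- ((N - k) / (k - 1)) * num / den
  }
  p <- .floor_p(stats::pf(W, k - 1, N - k, lower.tail = FALSE))
  list(W = W, df1 = k - 1, df2 = N - k, p = p)
}

#' Harmonize summary rows to reference alleles
#'
#' Aligns each SNP x cohort row to the reference effect/other allele pair:
#' rows already aligned pass through; swapped-allele rows have their genotype
#' groups reversed (0 <-> 2) and eaf complemented; strand flips (A<->T,
#' C<->G) are resolved by complementing first. Strand-ambiguous SNPs (A/T or
#' C/G) are aligned by allele frequency when |eaf - 0.5| > `freq_margin` for
#' both the row and the reference, and dropped otherwise.
#'
#' @param summaries summary rows.
#' @param reference data.frame snp_id, ea, oa, and optionally eaf; defaults
#'   to the first row seen per SNP.
#' @param freq_margin frequency-disambiguation margin (default 0.15).
#' @return list with `harmonized` rows and `dropped` (snp_id, cohort, reason).
#' @export
harmonize_summaries <- function(summaries, reference = NULL, freq_margin = 0.15) {
  s <- summaries
  if (is.null(reference)) {
    first <- !duplicated(s$snp_id)
    reference <- s[first, c("snp_id", "ea", "oa", "eaf")]
  }
  idx <- match(s$snp_id, reference$snp_id)
  ref_ea <- reference$ea[idx]
  ref_oa <- reference$oa[idx]
  ref_eaf <- if ("eaf" %in% names(reference)) reference$eaf[idx] else rep(NA_real_, nrow(s))
  comp <- function(a) c(A = "T", T = "A", C = "G", G = "C")[a]
  ambiguous <- (s$ea == comp(s$oa))
  aligned <- s$ea == ref_ea & s$oa == ref_oa
  swapped <- s$ea == ref_oa & s$oa == ref_ea
  flipped <- comp(s$ea) == ref_ea & comp(s$oa) == ref_oa
  flipped_swapped <- comp(s$ea) == ref_oa & comp(s$oa) == ref_ea
  action <- rep(NA_character_, nrow(s))
  action[aligned] <- "keep"
  action[!aligned & swapped] <- "swap"
  action[is.na(action) & flipped] <- "keep"         # strand flip only
  action[is.na(action) & flipped_swapped] <- "swap"
  # ambiguous SNPs: allele labels cannot distinguish strand from swap; use
  # frequency when it is informative on both sides, else drop
  amb <- which(ambiguous & !is.na(action))
  for (i in amb) {
    if (is.na(ref_eaf[i]) || abs(s$eaf[i] - 0.5) <= freq_margin ||
        abs(ref_eaf[i] - 0.5) <= freq_margin) {
      action[i] <- "drop"
    } else {
      action[i] <- if ((s$eaf[i] > 0.5) == (ref_eaf[i] > 0.5)) "keep" else "swap"
    }
  }
  action[is.na(action)] <- "drop"                   # alleles irreconcilable
  sw <- which(action == "swap")
  if (length(sw)) {
    s[sw, c("n0", "n2")] <- s[sw, c("n2", "n0")]
    s[sw, c("meanZ0", "meanZ2")] <- s[sw, c("meanZ2", "meanZ0")]
    s[sw, c("varZ0", "varZ2")] <- s[sw, c("varZ2", "varZ0")]
    s$eaf[sw] <- 1 - s$eaf[sw]
    s$ea[sw] <- ref_ea[sw]; s$oa[sw] <- ref_oa[sw]
  }
  kp <- which(action == "keep")
  s$ea[kp] <- ref_ea[kp]; s$oa[kp] <- ref_oa[kp]
  drop <- action == "drop"
  list(harmonized = s[!drop, , drop = FALSE],
       dropped = data.frame(snp_id = s$snp_id[drop], cohort = s$cohort[drop],
                            reason = ifelse(ambiguous[drop],
                                            "AMBIGUOUS_STRAND", "ALLELE_MISMATCH"),
                            stringsAsFactors = FALSE))
}
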