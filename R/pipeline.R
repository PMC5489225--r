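# End-to-end harnesses: full pipeline run, null calibration, power study.

#' Pipeline configuration
#'
#' All analysis defaults in one place. Reference values are named defaults
#' and can be overridden: QC thresholds (info/HWE/call-rate/MAF/30-per-group),
#' pruning 50/5/0.1 (0.8 for the odds-ratio analysis), Winsor 4 SD, binomial
#' null rate 0.05, 500 kb proximity window, 95th-centile average-rank cut.
#'
#' @param n_individuals total simulated individuals.
#' @param cohort_sizes integer vector partitioning them into cohorts.
#' @param arch an [arch_spec()].
#' @param qc a [qc_thresholds()] list.
#' @param prune a [prune_spec()]; `prune_or` is the laxer spec used for the
#'   interaction odds-ratio analysis.
#' @param winsor_sd Winsor limit in SD units.
#' @param null_rate nominal significance level for enrichment tests.
#' @param window_bp known-locus proximity window in bp.
#' @param centile_cut average-rank enrichment cut.
#' @param subsample_n optional fixed sample size: after simulation, analyses
#'   are restricted to this many randomly chosen individuals (sample-size
#'   equalization across traits).
#' @param seed global seed; every stage derives its own seed from it.
#' @param replicates replicate count for the calibration/power harnesses.
#' @param raw_scale simulate the phenotype on the positive raw scale and run
#'   the full log10 preparation (default TRUE).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_individuals = 2000,
                            cohort_sizes = NULL,
                            arch = arch_spec(m_snps = 2000),
                            qc = qc_thresholds(),
                            prune = prune_spec(),
                            prune_or = prune_spec(r2_max = 0.8),
                            winsor_sd = 4,
                            null_rate = 0.05,
                            window_bp = 5e5,
                            centile_cut = 95,
                            subsample_n = NULL,
                            seed = 1,
                            replicates = 200,
                            raw_scale = TRUE) {
  if (is.null(cohort_sizes)) cohort_sizes <- n_individuals
  if (sum(cohort_sizes) > n_individuals)
    stop("configuration error: cohort sizes exceed n_individuals")
  if (replicates < 1) stop("configuration error: replicates must be >= 1")
  structure(list(n_individuals = n_individuals, cohort_sizes = cohort_sizes,
                 arch = arch, qc = qc, prune = prune, prune_or = prune_or,
                 winsor_sd = winsor_sd, null_rate = null_rate,
                 window_bp = window_bp, centile_cut = centile_cut,
                 subsample_n = subsample_n, seed = seed,
                 replicates = replicates, raw_scale = raw_scale),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()], with `arch`, `qc`,
#' `prune` and `prune_or` as nested mappings passed to [arch_spec()],
#' [qc_thresholds()] and [prune_spec()].
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("configuration error: the yaml package is required to read config files")
  raw <- yaml::read_yaml(path)
  args <- raw
  for (nm in c("arch", "qc", "prune", "prune_or")) {
    if (!is.null(raw[[nm]])) {
      fn <- switch(nm, arch = arch_spec, qc = qc_thresholds, prune_spec)
      args[[nm]] <- do.call(fn, raw[[nm]])
    }
  }
  do.call(pipeline_config, args)
}

# stage logger: counts in/out plus a reason histogram, to stderr
.log_stage <- function(log, stage, rows_in, rows_out, reasons = NULL) {
  hist <- if (is.null(reasons) || !length(reasons)) "" else
    paste(sprintf("%s=%d", names(table(reasons)), as.integer(table(reasons))),
          collapse = ",")
  message(sprintf("[%s] in=%d out=%d %s", stage, rows_in, rows_out, hist))
  rbind(log, data.frame(stage = stage, rows_in = rows_in, rows_out = rows_out,
                        reasons = hist, stringsAsFactors = FALSE))
}

# Core per-dataset scan shared by the harnesses: P_m, P_v (via the
# summary-statistic meta-analysis path) and P_int for every SNP.
.scan_dataset <- function(G, y_prepared, exposure, qc) {
  summ <- summarize_cohort(G, y_prepared, "cohort1")
  qcres <- qc_filter(summ, qc)
  mv <- meta_levene(qcres$retained)
  P_v <- rep(NA_real_, ncol(G))
  idx <- match(mv$snp_id, colnames(G))
  P_v[idx] <- mv$P_v
  ms <- marginal_scan(G, y_prepared)
  is_ <- stratified_interaction_scan(G, y_prepared, exposure)
  list(P_m = ms$P_m, P_v = P_v, P_int = is_$P_int, marginal = ms,
       interaction = is_, meta = mv, qc = qcres)
}

#' Run the full screening pipeline on synthetic (or supplied) data
#'
#' Simulate (or accept) multi-cohort data, prepare the trait per cohort,
#' compute per-cohort genotype-group summaries, QC-filter them, meta-analyse
#' Levene's test, run pooled marginal and exposure-stratified interaction
#' scans (two independent binary exposures are simulated, so the
#' two-interaction-scan analyses run), LD-prune, and produce every
#' prioritization report: subset Spearman correlations with equality tests,
#' odds ratios, binomial enrichment of known loci in P_v and P_int, the
#' interaction-given-variance odds ratio on the laxer pruned set, rank-shift
#' Mann-Whitney tests (both centile bands, with and without proximity
#' exclusion, in both split directions), and the average-rank enrichment.
#' Known loci are the SNPs with nonzero simulated marginal effect.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, every table is written as
#'   deterministic tab-delimited text.
#' @param study optional pre-built list(truth, cohorts) to analyse instead of
#'   simulating (e.g. user-supplied data in the same shape).
#' @return report bundle (list), including the rank table, all reports and a
#'   per-stage row-count log.
#' @export
run_pipeline <- function(config, out_dir = NULL, study = NULL) {
  cfg <- config
  seeds <- derive_seeds(cfg$seed, 4L)
  log <- data.frame()

  if (is.null(study)) {
    study <- simulate_cohort_study(cfg$arch, cfg$n_individuals,
                                   cfg$cohort_sizes, seed = seeds[1],
                                   raw_scale = cfg$raw_scale)
  }
  truth <- study$truth
  cohorts <- study$cohorts
  m <- nrow(truth)
  log <- .log_stage(log, "simulate", m, m)

  # second, independent exposure so the two-scan analyses are exercised
  set.seed(seeds[2])
  exposure_b <- lapply(cohorts, function(co)
    simulate_exposure(length(co$phenotype), cfg$arch$exposure_prevalence))

  # optional sample-size equalization
  if (!is.null(cfg$subsample_n)) {
    set.seed(seeds[3])
    total <- sum(vapply(cohorts, function(co) length(co$phenotype), 0L))
    frac <- cfg$subsample_n / total
    for (k in seq_along(cohorts)) {
      nk <- length(cohorts[[k]]$phenotype)
      keep <- sort(sample.int(nk, round(frac * nk)))
      co <- cohorts[[k]]
      cohorts[[k]] <- cohort_data(co$genotypes[keep, , drop = FALSE],
                                  co$snp_meta, co$phenotype[keep],
                                  co$exposure[keep], co$cohort_id)
      exposure_b[[k]] <- exposure_b[[k]][keep]
    }
  }

  # per-cohort preparation and genotype-group summaries
  prepared <- lapply(cohorts, function(co)
    prepare_trait(co$phenotype, winsor_sd = cfg$winsor_sd,
                  log10 = cfg$raw_scale))
  summ <- do.call(rbind, Map(function(co, pr)
    summarize_cohort(co$genotypes, pr, co$cohort_id, snp_meta = co$snp_meta),
    cohorts, prepared))
  rownames(summ) <- NULL
  log <- .log_stage(log, "summarize", nrow(summ), nrow(summ))

  harm <- harmonize_summaries(summ,
                              reference = truth[, c("snp_id", "ea", "oa")])
  qcres <- qc_filter(harm$harmonized, cfg$qc)
  log <- .log_stage(log, "qc", nrow(summ), nrow(qcres$retained),
                    c(harm$dropped$reason, qcres$exclusions$reason))

  mv <- meta_levene(qcres$retained)
  ok_mv <- is.na(mv$reason)
  log <- .log_stage(log, "meta_levene", nrow(mv), sum(ok_mv),
                    mv$reason[!ok_mv])
  P_v <- rep(NA_real_, m)
  P_v[match(mv$snp_id[ok_mv], truth$snp_id)] <- mv$P_v[ok_mv]

  # pooled scans: per-cohort z-scored traits concatenated
  G_all <- do.call(rbind, lapply(cohorts, `[[`, "genotypes"))
  y_all <- unlist(lapply(prepared, `[[`, "values"), use.names = FALSE)
  E_a <- unlist(lapply(cohorts, `[[`, "exposure"), use.names = FALSE)
  E_b <- unlist(exposure_b, use.names = FALSE)
  ms <- marginal_scan(G_all, y_all)
  int_a <- stratified_interaction_scan(G_all, y_all, E_a)
  int_b <- stratified_interaction_scan(G_all, y_all, E_b)
  log <- .log_stage(log, "scans", m, sum(!is.na(ms$P_m)), ms$flag)

  pr <- prune_windowed(G_all, cfg$prune)
  pr_or <- prune_windowed(G_all, cfg$prune_or)
  log <- .log_stage(log, "prune", m, length(pr$kept))

  known <- truth[truth$beta != 0, c("snp_id", "chrom", "pos")]
  tbl <- build_rank_table(truth, ms$P_m, P_v,
                          P_int = list(ea = int_a$P_int, eb = int_b$P_int),
                          pruned_ids = pr$kept, known = known,
                          window_bp = cfg$window_bp)

  reports <- prioritization_reports(tbl, known = known, cfg = cfg,
                                    pruned_or_ids = pr_or$kept)

  bundle <- list(config = cfg, truth = truth, summaries = summ,
                 qc = qcres, meta = mv, marginal = ms,
                 interaction = list(ea = int_a, eb = int_b),
                 prune = pr, prune_or = pr_or,
                 rank_table = tbl, reports = reports, log = log)
  if (!is.null(out_dir)) write_report_bundle(bundle, out_dir)
  bundle
}

# All prioritization statistics from a rank table; percentile ranks for the
# rank-shift tests are recomputed within the pruned set so that the null
# median sits at 50 by construction.
prioritization_reports <- function(tbl, known, cfg, pruned_or_ids = NULL) {
  pt <- tbl[tbl$in_pruned & is.finite(tbl$P_m) & is.finite(tbl$P_v), ]
  subsets <- list(all = rep(TRUE, nrow(pt)),
                  pm_lt_0.05 = pt$P_m < 0.05,
                  pm_lt_1e.4 = pt$P_m < 1e-4,
                  known = pt$is_known)
  corr <- spearman_by_subset(pt, "P_m", "P_v", subsets)

  or_mv <- with(pt, odds_ratio_2x2(sum(P_m < 0.05 & P_v < 0.05),
                                   sum(P_m < 0.05 & P_v >= 0.05),
                                   sum(P_m >= 0.05 & P_v < 0.05),
                                   sum(P_m >= 0.05 & P_v >= 0.05)))

  kt <- tbl[tbl$is_known & is.finite(tbl$P_v), ]
  enr_known_v <- binomial_enrichment(nrow(kt), sum(kt$P_v < 0.05),
                                     cfg$null_rate)
  int_cols <- grep("^P_int_", names(tbl), value = TRUE)
  enr_known_int <- lapply(int_cols, function(cc) {
    ki <- tbl[tbl$is_known & is.finite(tbl[[cc]]), ]
    binomial_enrichment(nrow(ki), sum(ki[[cc]] < 0.05), cfg$null_rate)
  })
  names(enr_known_int) <- sub("^P_int_", "", int_cols)

  # enrichment of P_v<0.05 among P_int<0.05 SNPs, and the OR on the laxer
  # pruned set
  enr_int_v <- list(); or_int_v <- list()
  ot <- if (is.null(pruned_or_ids)) tbl else tbl[tbl$snp_id %in% pruned_or_ids, ]
  for (cc in int_cols) {
    nm <- sub("^P_int_", "", cc)
    el <- tbl[is.finite(tbl[[cc]]) & is.finite(tbl$P_v) & tbl[[cc]] < 0.05, ]
    enr_int_v[[nm]] <- binomial_enrichment(nrow(el), sum(el$P_v < 0.05),
                                           cfg$null_rate)
    oo <- ot[is.finite(ot[[cc]]) & is.finite(ot$P_v), ]
    or_int_v[[nm]] <- odds_ratio_2x2(sum(oo[[cc]] < 0.05 & oo$P_v < 0.05),
                                     sum(oo[[cc]] >= 0.05 & oo$P_v < 0.05),
                                     sum(oo[[cc]] < 0.05 & oo$P_v >= 0.05),
                                     sum(oo[[cc]] >= 0.05 & oo$P_v >= 0.05))
  }

  # average-rank enrichment across the two interaction scans (known loci)
  avg_rank <- NULL
  if (length(int_cols) >= 2) {
    p1 <- percentile_ranks(tbl[[int_cols[1]]])
    p2 <- percentile_ranks(tbl[[int_cols[2]]])
    avg_rank <- average_rank_enrichment(p1, p2, eligible = tbl$is_known,
                                        centile_cut = cfg$centile_cut)
    avg_rank$avg_rank <- NULL  # keep the report light
  }

  # rank-shift Mann-Whitney tests on pruned-set percentiles; a band emptied
  # by the proximity exclusion is reported, not fatal
  pm_pct <- percentile_ranks(pt$P_m)
  pv_pct <- percentile_ranks(pt$P_v)
  safe_shift <- function(...) {
    tryCatch(rank_shift_test(...),
             error = function(e) list(p = NA_real_, note = conditionMessage(e)))
  }
  shift <- list(
    m_splits_v_top1 = safe_shift(pm_pct, pv_pct, 100),
    m_splits_v_99th = safe_shift(pm_pct, pv_pct, 99),
    m_splits_v_top1_excl = safe_shift(pm_pct, pv_pct, 100,
                                      exclude = pt$near_known),
    m_splits_v_99th_excl = safe_shift(pm_pct, pv_pct, 99,
                                      exclude = pt$near_known),
    v_splits_m_top1 = safe_shift(pv_pct, pm_pct, 100),
    v_splits_m_99th = safe_shift(pv_pct, pm_pct, 99)
  )

  # Fig-1-style export: known-locus percentile positions with significance
  fig_known <- tbl[tbl$is_known,
                   c("snp_id", "chrom", "pos", "P_v", "pct_v")]
  fig_known$sig_v <- !is.na(fig_known$P_v) & fig_known$P_v < 0.05

  list(correlations = corr, or_marginal_variance = or_mv,
       enrichment_known_variance = enr_known_v,
       enrichment_known_interaction = enr_known_int,
       enrichment_interaction_variance = enr_int_v,
       or_interaction_variance = or_int_v,
       average_rank = avg_rank, rank_shift = shift,
       known_percentiles = fig_known)
}

# Serialize the report bundle as deterministic text files.
write_report_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) write_tsv_stable(df, file.path(out_dir, name))
  w(bundle$meta, "meta_levene.tsv")
  w(bundle$marginal, "marginal_scan.tsv")
  w(bundle$interaction$ea, "interaction_ea.tsv")
  w(bundle$interaction$eb, "interaction_eb.tsv")
  w(bundle$rank_table, "rank_table.tsv")
  w(data.frame(snp_id = bundle$prune$kept), "pruned_kept.tsv")
  w(bundle$prune$removals, "prune_removals.tsv")
  w(bundle$reports$correlations, "correlations.tsv")
  w(bundle$reports$known_percentiles, "known_percentiles.tsv")
  flat <- function(x) {
    u <- unlist(x)
    v <- if (is.numeric(u)) sprintf("%.10g", u) else as.character(u)
    data.frame(key = names(u), value = v, stringsAsFactors = FALSE)
  }
  w(flat(bundle$reports$or_marginal_variance), "or_marginal_variance.tsv")
  w(flat(bundle$reports$enrichment_known_variance), "enrichment_known_variance.tsv")
  w(flat(bundle$reports$enrichment_interaction_variance), "enrichment_interaction_variance.tsv")
  w(flat(bundle$reports$or_interaction_variance), "or_interaction_variance.tsv")
  if (!is.null(bundle$reports$average_rank))
    w(flat(bundle$reports$average_rank), "average_rank_enrichment.tsv")
  w(flat(bundle$reports$rank_shift), "rank_shift.tsv")
  w(bundle$log, "stage_log.tsv")
  invisible(out_dir)
}

#' Null-calibration harness
#'
#' Repeats the three simulation analyses on data with no interaction effects
#' (marginal effects allowed, normal error by default): per replicate,
#' P_m, P_v and P_int are computed for every SNP, then (i) the three pairwise
#' Spearman correlation P-values among them, (ii) binomial-enrichment
#' P-values of P_v < 0.05 among SNPs with P_m < 0.05 and among SNPs with
#' P_int < 0.05, and (iii) Mann-Whitney P-values for the top-centile shift
#' (P_m splitting P_v, and the reverse) are recorded. The output carries each
#' P-value family, Kolmogorov-Smirnov uniformity statistics, the pooled
#' fraction of P_v < 0.05, and decile quantiles of the pooled P_v
#' distribution against uniform.
#'
#' The exact binomial P-value is a discrete statistic: with a few hundred
#' eligible SNPs it takes large atoms and is conservative between them, so
#' its raw distribution cannot be continuous-uniform at this scale no matter
#' how well calibrated the test is. The harness therefore also records the
#' randomized-tail version P(X > k) + U P(X = k) (`binomial_u`), which is
#' exactly Uniform(0,1) under the null and is the appropriate KS check for a
#' discrete test.
#'
#' @param config a [pipeline_config()]; its `arch` should have
#'   `interaction$prop = 0`. Replicate seeds derive from `config$seed`.
#' @return list of class `null_calibration`.
#' @export
run_null_calibration <- function(config) {
  cfg <- config
  if (cfg$arch$interaction$prop != 0)
    warning("calibration on a non-null interaction architecture")
  R <- cfg$replicates
  if (R < 20) warning("fewer than 20 replicates: KS checks will be weak")
  seeds <- derive_seeds(cfg$seed, R)
  n <- cfg$n_individuals
  corr_p <- matrix(NA_real_, R, 3,
                   dimnames = list(NULL, c("m_v", "m_int", "v_int")))
  binom_p <- matrix(NA_real_, R, 2, dimnames = list(NULL, c("m", "int")))
  # randomized-tail (uniformized) version of the exact binomial P:
  # P(X > k) + U * P(X = k) is exactly Uniform(0,1) under the null, which is
  # the appropriate uniformity check for a discrete test statistic
  binom_u <- matrix(NA_real_, R, 2, dimnames = list(NULL, c("m", "int")))
  mw_p <- matrix(NA_real_, R, 2,
                 dimnames = list(NULL, c("m_splits_v", "v_splits_m")))
  pv_lt_05 <- 0; pv_total <- 0
  pv_pool_q <- numeric(0)
  for (r in seq_len(R)) {
    sds <- derive_seeds(seeds[r], 4L)
    spec <- cfg$arch
    spec$seed <- sds[1]
    truth <- sample_architecture(spec)
    G <- simulate_genotypes(truth, n, seed = sds[2])
    E <- simulate_exposure(n, spec$exposure_prevalence, seed = sds[3])
    y <- simulate_phenotype(G, truth, E, spec, seed = sds[4])
    if (cfg$raw_scale) y <- to_raw_scale(y)
    prep <- prepare_trait(y, winsor_sd = cfg$winsor_sd, log10 = cfg$raw_scale)
    sc <- .scan_dataset(G, prep, E, cfg$qc)
    ok <- is.finite(sc$P_m) & is.finite(sc$P_v) & is.finite(sc$P_int)
    corr_p[r, 1] <- spearman_test(sc$P_m[ok], sc$P_v[ok])$p
    corr_p[r, 2] <- spearman_test(sc$P_m[ok], sc$P_int[ok])$p
    corr_p[r, 3] <- spearman_test(sc$P_v[ok], sc$P_int[ok])$p
    el_m <- ok & sc$P_m < 0.05
    el_i <- ok & sc$P_int < 0.05
    binom_p[r, 1] <- binomial_enrichment(sum(el_m), sum(sc$P_v[el_m] < 0.05),
                                         cfg$null_rate)$p
    binom_p[r, 2] <- binomial_enrichment(sum(el_i), sum(sc$P_v[el_i] < 0.05),
                                         cfg$null_rate)$p
    for (j in 1:2) {
      el <- if (j == 1) el_m else el_i
      kk <- sum(sc$P_v[el] < 0.05)
      binom_u[r, j] <- stats::pbinom(kk, sum(el), cfg$null_rate,
                                     lower.tail = FALSE) +
        stats::runif(1) * stats::dbinom(kk, sum(el), cfg$null_rate)
    }
    pm_pct <- percentile_ranks(sc$P_m[ok])
    pv_pct <- percentile_ranks(sc$P_v[ok])
    mw_p[r, 1] <- rank_shift_test(pm_pct, pv_pct, 100)$p
    mw_p[r, 2] <- rank_shift_test(pv_pct, pm_pct, 100)$p
    pv_lt_05 <- pv_lt_05 + sum(sc$P_v[ok] < 0.05)
    pv_total <- pv_total + sum(ok)
    pv_pool_q <- pv_pool_q + stats::quantile(sc$P_v[ok], probs = seq(0.1, 0.9, 0.1)) / R
  }
  ks <- function(p) suppressWarnings(stats::ks.test(p, "punif")$p.value)
  structure(list(
    correlation_p = corr_p, binomial_p = binom_p, binomial_u = binom_u,
    mw_p = mw_p,
    pv_frac_lt_05 = pv_lt_05 / pv_total,
    pv_quantiles = pv_pool_q,
    ks = c(correlation = ks(as.vector(corr_p)),
           binomial = ks(as.vector(binom_p)),
           binomial_uniformized = ks(as.vector(binom_u)),
           mann_whitney = ks(as.vector(mw_p))),
    replicates = R, n = n, m = cfg$arch$m_snps
  ), class = "null_calibration")
}

#' @export
print.null_calibration <- function(x, ...) {
  cat(sprintf("null_calibration: %d replicates of %d x %d\n", x$replicates,
              x$n, x$m))
  cat(sprintf("  fraction P_v < 0.05: %.4f\n", x$pv_frac_lt_05))
  cat("  KS uniformity P:",
      paste(sprintf("%s=%.3g", names(x$ks), x$ks), collapse = "  "), "\n")
  invisible(x)
}

#' Power and screening study over an interaction effect-size grid
#'
#' For each interaction effect size delta on a grid, simulates replicates in
#' which a designated subset of SNPs carries that delta, and reports the
#' fraction of interaction SNPs detected by the variance test (P_v < 0.05),
#' by the explicit interaction test (P_int < 0.05), and by both, plus the
#' odds ratio of P_int < 0.05 given P_v < 0.05 over all SNPs — the
#' truth-known analogue of the screening claim that variance signals
#' prioritize interaction loci.
#'
#' @param config a [pipeline_config()]; `config$arch$interaction$prop`
#'   determines how many SNPs carry the effect.
#' @param delta_grid interaction effect sizes to sweep.
#' @param replicates replicates per grid point (default from config).
#' @return data.frame: delta, power_v, power_int, power_both, or, or_lo,
#'   or_hi, frac_null_v (P_v < 0.05 rate among null SNPs).
#' @export
run_power_study <- function(config, delta_grid = c(0, 0.1, 0.2, 0.4),
                            replicates = NULL) {
  cfg <- config
  R <- if (is.null(replicates)) cfg$replicates else replicates
  seeds <- derive_seeds(cfg$seed, length(delta_grid) * R)
  n <- cfg$n_individuals
  out <- data.frame()
  si <- 0L
  for (d in delta_grid) {
    hits_v <- 0; hits_int <- 0; hits_both <- 0; n_delta <- 0
    null_v <- 0; n_null <- 0
    cells <- c(0, 0, 0, 0)
    for (r in seq_len(R)) {
      si <- si + 1L
      sds <- derive_seeds(seeds[si], 4L)
      spec <- cfg$arch
      spec$seed <- sds[1]
      truth <- sample_architecture(spec)
      idx_d <- which(truth$delta != 0)   # designated interaction SNPs
      truth$delta[idx_d] <- d * sign(truth$delta[idx_d])
      G <- simulate_genotypes(truth, n, seed = sds[2])
      E <- simulate_exposure(n, spec$exposure_prevalence, seed = sds[3])
      y <- simulate_phenotype(G, truth, E, spec, seed = sds[4])
      if (cfg$raw_scale) y <- to_raw_scale(y)
      prep <- prepare_trait(y, winsor_sd = cfg$winsor_sd,
                            log10 = cfg$raw_scale)
      sc <- .scan_dataset(G, prep, E, cfg$qc)
      ok <- is.finite(sc$P_v) & is.finite(sc$P_int)
      is_d <- seq_len(nrow(truth)) %in% idx_d & ok
      is_n <- !seq_len(nrow(truth)) %in% idx_d & ok
      hits_v <- hits_v + sum(sc$P_v[is_d] < 0.05)
      hits_int <- hits_int + sum(sc$P_int[is_d] < 0.05)
      hits_both <- hits_both + sum(sc$P_v[is_d] < 0.05 & sc$P_int[is_d] < 0.05)
      n_delta <- n_delta + sum(is_d)
      null_v <- null_v + sum(sc$P_v[is_n] < 0.05)
      n_null <- n_null + sum(is_n)
      cells <- cells + c(sum(sc$P_int[ok] < 0.05 & sc$P_v[ok] < 0.05),
                         sum(sc$P_int[ok] >= 0.05 & sc$P_v[ok] < 0.05),
                         sum(sc$P_int[ok] < 0.05 & sc$P_v[ok] >= 0.05),
                         sum(sc$P_int[ok] >= 0.05 & sc$P_v[ok] >= 0.05))
    }
    orr <- odds_ratio_2x2(cells[1], cells[2], cells[3], cells[4])
    out <- rbind(out, data.frame(
      delta = d,
      power_v = if (n_delta) hits_v / n_delta else NA_real_,
      power_int = if (n_delta) hits_int / n_delta else NA_real_,
      power_both = if (n_delta) hits_both / n_delta else NA_real_,
      or = orr$or, or_lo = orr$ci[1], or_hi = orr$ci[2],
      frac_null_v = null_v / n_null))
  }
  out
}
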