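# Synthetic multi-cohort generator: Hardy-Weinberg genotypes with a GWAS-like
# effect-size architecture, a binary exposure, and an optionally skewed error,
# so that every downstream stage can run on self-contained data.

#' Specify a synthetic genetic architecture
#'
#' Describes the simulated study conditions: number of SNPs, allele-frequency
#' range, the mixture of null and non-null marginal effects, the
#' gene-environment interaction effects, the binary exposure, and the error
#' model. Defaults follow the reference design this generator emulates:
#' a pruned set of 50,335 SNPs with GWAS-like allele frequencies and effect
#' sizes, a binary interacting factor with 30% prevalence, and a right-skewed
#' error resembling a log- and z-transformed BMI-like trait.
#'
#' @param m_snps number of SNPs.
#' @param maf_range length-2 numeric in (0, 0.5], range of the uniform
#'   distribution effect-allele frequencies are drawn from.
#' @param effect list with `prop` (proportion of SNPs with a nonzero marginal
#'   effect) and `sd` (SD of those effects, trait z-units per allele).
#' @param interaction list with `prop` and `sd` for the GxE effects `delta`;
#'   default has no interaction effects (the null design).
#' @param exposure_prevalence probability in (0,1); prevalence of the binary
#'   exposure.
#' @param exposure_main_effect main effect of the exposure on the trait
#'   (z-units).
#' @param error_model list with `family` ("normal", "lognormal" or "none"),
#'   `sd` (target error SD) and for the lognormal family `sdlog` (log-scale
#'   shape; the default 0.25 gives a standardized-trait skewness of roughly
#'   0.3-0.8 once mixed with the genetic component).
#' @param seed optional integer; fixing it makes [sample_architecture()]
#'   deterministic.
#' @return an object of class `arch_spec` (a validated list).
#' @seealso [sample_architecture()], [simulate_cohort_study()]
#' @export
arch_spec <- function(m_snps = 50335,
                      maf_range = c(0.05, 0.5),
                      effect = list(prop = 0.01, sd = 0.05),
                      interaction = list(prop = 0, sd = 0.1),
                      exposure_prevalence = 0.3,
                      exposure_main_effect = 0.2,
                      error_model = list(family = "lognormal", sd = 1, sdlog = 0.25),
                      seed = NULL) {
  spec <- list(m_snps = as.integer(m_snps), maf_range = maf_range,
               effect = effect, interaction = interaction,
               exposure_prevalence = exposure_prevalence,
               exposure_main_effect = exposure_main_effect,
               error_model = error_model, seed = seed)
  validate_arch_spec(spec)
  class(spec) <- "arch_spec"
  spec
}

validate_arch_spec <- function(spec) {
  with(spec, {
    if (length(m_snps) != 1L || is.na(m_snps) || m_snps < 1L)
      stop("configuration error: m_snps must be a positive count")
    if (length(maf_range) != 2L || any(maf_range <= 0) || any(maf_range > 0.5) ||
        maf_range[1] > maf_range[2])
      stop("configuration error: maf_range must lie within (0, 0.5]")
    for (mix in list(effect, interaction)) {
      if (mix$prop < 0 || mix$prop > 1)
        stop("configuration error: mixture proportions must be in [0, 1]")
      if (mix$sd < 0) stop("configuration error: effect scales must be >= 0")
    }
    if (exposure_prevalence <= 0 || exposure_prevalence >= 1)
      stop("configuration error: exposure_prevalence must be in (0, 1)")
    if (!error_model$family %in% c("normal", "lognormal", "none"))
      stop("configuration error: unknown error family ", error_model$family)
  })
  invisible(spec)
}

#' Draw the per-SNP truth table for an architecture
#'
#' Samples effect-allele frequencies uniformly from `maf_range` and assigns
#' nonzero marginal (`beta`) and interaction (`delta`) effects to exactly
#' `round(prop * m_snps)` SNPs each (independently chosen subsets), with
#' effect sizes drawn from centered normals of the configured SD. Positions
#' are laid out on one synthetic chromosome at fixed 10 kb spacing so that
#' coordinate-based logic (proximity exclusion, pruning windows) is exercised.
#'
#' @param spec an [arch_spec()].
#' @return data.frame with one row per SNP: `snp_id`, `chrom`, `pos`, `ea`,
#'   `oa`, `maf`, `beta`, `delta`.
#' @export
sample_architecture <- function(spec) {
  validate_arch_spec(spec)
  .seed_if(spec$seed)
  m <- spec$m_snps
  maf <- stats::runif(m, spec$maf_range[1], spec$maf_range[2])
  beta <- numeric(m)
  delta <- numeric(m)
  n_b <- round(spec$effect$prop * m)
  n_d <- round(spec$interaction$prop * m)
  if (n_b > 0) {
    idx <- sample.int(m, n_b)
    beta[idx] <- stats::rnorm(n_b, 0, spec$effect$sd)
  }
  if (n_d > 0) {
    idx <- sample.int(m, n_d)
    delta[idx] <- stats::rnorm(n_d, 0, spec$interaction$sd)
  }
  # non-ambiguous allele pairs only, so strand harmonization stays exact
  pairs <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C"), ncol = 2, byrow = TRUE)
  pick <- sample.int(4L, m, replace = TRUE)
  data.frame(
    snp_id = sprintf("s%06d", seq_len(m)),
    chrom = "1",
    pos = 10000L * seq_len(m),
    ea = pairs[pick, 1], oa = pairs[pick, 2],
    maf = maf, beta = beta, delta = delta,
    stringsAsFactors = FALSE
  )
}

#' Simulate hard-call genotypes under Hardy-Weinberg equilibrium
#'
#' Each SNP is drawn i.i.d. across individuals with genotype probabilities
#' ((1-p)^2, 2p(1-p), p^2) for effect-allele dosage 0/1/2. With `ld`, SNPs
#' within consecutive blocks are coupled at the haplotype level by an
#' autoregressive copy rule (allele j copies allele j-1 with probability
#' `rho`, else is drawn fresh), producing decaying within-block LD; this
#' exists solely to exercise [prune_windowed()].
#'
#' @param truth truth table from [sample_architecture()] (uses `maf`, `snp_id`).
#' @param n number of individuals.
#' @param seed optional integer seed.
#' @param ld optional list(block_size, rho) enabling block LD.
#' @param dosage_noise optional SD of bounded noise added to the hard calls
#'   and clipped to [0, 2], to exercise the hard-calling path.
#' @return n x m matrix of dosages in [0, 2], columns named by `snp_id`.
#' @export
simulate_genotypes <- function(truth, n, seed = NULL, ld = NULL,
                               dosage_noise = 0) {
  stopifnot(n >= 1, all(truth$maf >= 0), all(truth$maf <= 1))
  .seed_if(seed)
  m <- nrow(truth)
  if (is.null(ld)) {
    G <- matrix(stats::rbinom(n * m, 2L, rep(truth$maf, each = n)), n, m)
  } else {
    stopifnot(ld$block_size >= 1, ld$rho >= 0, ld$rho <= 1)
    hap <- function() {
      H <- matrix(0L, n, m)
      for (j in seq_len(m)) {
        fresh <- stats::rbinom(n, 1L, truth$maf[j])
        if (j == 1L || (j - 1L) %% ld$block_size == 0L) {
          H[, j] <- fresh
        } else {
          copy <- stats::rbinom(n, 1L, ld$rho)
          H[, j] <- ifelse(copy == 1L, H[, j - 1L], fresh)
        }
      }
      H
    }
    G <- hap() + hap()
  }
  if (dosage_noise > 0) {
    G <- pmin(pmax(G + stats::rnorm(n * m, 0, dosage_noise), 0), 2)
  }
  colnames(G) <- truth$snp_id
  G
}

#' Simulate a binary exposure
#'
#' @param n number of individuals.
#' @param prevalence probability in (0,1); default 0.3 (the reference design's
#'   binary interacting factor).
#' @param seed optional seed.
#' @param exact if TRUE, exactly `round(prevalence * n)` individuals are
#'   exposed (random positions); otherwise i.i.d. Bernoulli draws.
#' @return integer vector of 0/1.
#' @export
simulate_exposure <- function(n, prevalence = 0.3, seed = NULL, exact = FALSE) {
  if (prevalence <= 0 || prevalence >= 1)
    stop("configuration error: prevalence must be in (0, 1)")
  .seed_if(seed)
  if (exact) {
    e <- integer(n)
    e[sample.int(n, round(prevalence * n))] <- 1L
    e
  } else {
    stats::rbinom(n, 1L, prevalence)
  }
}

# Standardized error draw: mean 0, SD = error_model$sd. The lognormal family
# is shifted and scaled, keeping the right skew of exp(N(0, sdlog^2)).
.simulate_error <- function(n, error_model) {
  fam <- error_model$family
  if (fam == "none") return(numeric(n))
  if (fam == "normal") return(stats::rnorm(n, 0, error_model$sd))
  sdlog <- error_model$sdlog
  raw <- stats::rlnorm(n, 0, sdlog)
  mu <- exp(sdlog^2 / 2)
  sigma <- sqrt((exp(sdlog^2) - 1) * exp(sdlog^2))
  (raw - mu) / sigma * error_model$sd
}

#' Simulate the outcome trait
#'
#' The trait is the sum of per-allele marginal effects, an exposure main
#' effect, genotype-by-exposure interaction effects, and a random error:
#' \deqn{Y_i = \sum_j G_{ij}\beta_j + a E_i + \sum_j G_{ij}\delta_j E_i + \epsilon_i.}
#' The value is returned on the analysis (z-like) scale; use
#' [to_raw_scale()] to map it to a positive BMI-like raw trait whose log10
#' transform recovers an affine image of Y exactly.
#'
#' @param genotypes dosage matrix from [simulate_genotypes()].
#' @param truth matching truth table (`beta`, `delta`).
#' @param exposure 0/1 vector of length nrow(genotypes).
#' @param spec the [arch_spec()] (supplies exposure main effect, error model).
#' @param seed optional seed for the error draw.
#' @return numeric phenotype vector.
#' @export
simulate_phenotype <- function(genotypes, truth, exposure, spec, seed = NULL) {
  n <- nrow(genotypes)
  if (ncol(genotypes) != nrow(truth) || length(exposure) != n)
    stop("data error: dimension mismatch between genotypes, truth and exposure")
  .seed_if(seed)
  y <- as.vector(genotypes %*% truth$beta) +
    spec$exposure_main_effect * exposure
  if (any(truth$delta != 0)) {
    y <- y + as.vector(genotypes %*% truth$delta) * exposure
  }
  y + .simulate_error(n, spec$error_model)
}

#' Map an analysis-scale trait to a positive raw scale
#'
#' Inverse of the log10 + z-score preparation: `raw = 10^(sd * y + mean)`.
#' Defaults give a BMI-like raw distribution (median about 26). Because the
#' map is a strictly increasing affine transform in log10 space, preparing
#' the raw trait with [prepare_trait()] recovers the z-scored `y` exactly
#' (up to Winsorization).
#'
#' @param y analysis-scale trait.
#' @param log10_sd,log10_mean affine coefficients in log10 space.
#' @return positive raw-scale trait.
#' @export
to_raw_scale <- function(y, log10_sd = 0.07, log10_mean = 1.42) {
  10^(log10_sd * y + log10_mean)
}

#' Split one simulated sample into disjoint cohorts
#'
#' @param data a `cohort_data` object (see [simulate_cohort_study()]).
#' @param sizes integer vector of cohort sizes, `sum(sizes) <= n`.
#' @param seed optional seed for the random partition.
#' @return list of `cohort_data`, one per size, labelled `cohort1`, ...
#' @export
split_cohorts <- function(data, sizes, seed = NULL) {
  n <- length(data$phenotype)
  if (sum(sizes) > n) stop("data error: cohort sizes exceed available individuals")
  .seed_if(seed)
  perm <- sample.int(n, sum(sizes))
  offs <- c(0L, cumsum(sizes))
  out <- vector("list", length(sizes))
  for (k in seq_along(sizes)) {
    idx <- sort(perm[(offs[k] + 1L):offs[k + 1L]])
    out[[k]] <- cohort_data(
      genotypes = data$genotypes[idx, , drop = FALSE],
      snp_meta = data$snp_meta,
      phenotype = data$phenotype[idx],
      exposure = data$exposure[idx],
      cohort_id = paste0("cohort", k)
    )
  }
  names(out) <- vapply(out, `[[`, "", "cohort_id")
  out
}

#' Construct a cohort data object
#'
#' Individual-level container for one cohort: dosage genotypes, SNP metadata,
#' raw-or-analysis-scale phenotype, binary exposure and a label.
#'
#' @param genotypes n x m dosage matrix in [0, 2].
#' @param snp_meta per-SNP metadata (as from [sample_architecture()]).
#' @param phenotype length-n trait vector.
#' @param exposure length-n 0/1 vector.
#' @param cohort_id label.
#' @return object of class `cohort_data`.
#' @export
cohort_data <- function(genotypes, snp_meta, phenotype, exposure, cohort_id) {
  stopifnot(nrow(genotypes) == length(phenotype),
            length(exposure) == length(phenotype),
            ncol(genotypes) == nrow(snp_meta))
  rng <- range(genotypes, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) stop("data error: dosages outside [0, 2]")
  if (anyNA(snp_meta$snp_id)) stop("data error: missing SNP ids")
  o <- order(snp_meta$chrom, snp_meta$pos)
  if (is.unsorted(o)) stop("data error: SNPs must be position-ordered")
  structure(list(genotypes = genotypes, snp_meta = snp_meta,
                 phenotype = phenotype, exposure = exposure,
                 cohort_id = cohort_id),
            class = "cohort_data")
}

#' @export
print.cohort_data <- function(x, ...) {
  cat(sprintf("cohort_data '%s': %d individuals x %d SNPs, exposure prevalence %.3f\n",
              x$cohort_id, length(x$phenotype), ncol(x$genotypes),
              mean(x$exposure)))
  invisible(x)
}

#' Simulate a complete multi-cohort study
#'
#' Convenience wrapper: draws the architecture, genotypes, exposure and
#' phenotype for `n` individuals and partitions them into cohorts.
#'
#' @param spec an [arch_spec()].
#' @param n total individuals (reference design: 44,000).
#' @param cohort_sizes integer vector summing to at most `n`; default one
#'   cohort of all individuals.
#' @param seed master seed; stage seeds are derived from it.
#' @param raw_scale if TRUE the phenotype is exported via [to_raw_scale()]
#'   (so the full log10 preparation path is exercised); otherwise it stays on
#'   the analysis scale.
#' @return list with `truth` and `cohorts` (list of `cohort_data`).
#' @export
simulate_cohort_study <- function(spec, n, cohort_sizes = n, seed = NULL,
                                  raw_scale = TRUE) {
  seeds <- derive_seeds(seed, 5L)
  spec$seed <- seeds[1]
  truth <- sample_architecture(spec)
  G <- simulate_genotypes(truth, n, seed = seeds[2])
  E <- simulate_exposure(n, spec$exposure_prevalence, seed = seeds[3])
  y <- simulate_phenotype(G, truth, E, spec, seed = seeds[4])
  if (raw_scale) y <- to_raw_scale(y)
  all_data <- cohort_data(G, truth, y, E, "all")
  cohorts <- split_cohorts(all_data, cohort_sizes, seed = seeds[5])
  list(truth = truth, cohorts = cohorts)
}

#' Write cohort data as plain-text files
#'
#' Emits a tab-delimited dosage matrix (first column individual id, then one
#' column per SNP), a two-column phenotype file, a two-column exposure file,
#' and the SNP metadata table. UTF-8, '.' for missing.
#'
#' @param cohort a `cohort_data`.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths.
#' @export
write_cohort_data <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  id <- sprintf("i%06d", seq_along(cohort$phenotype))
  paths <- c(
    genotypes = file.path(dir, paste0(cohort$cohort_id, "_dosage.tsv")),
    phenotype = file.path(dir, paste0(cohort$cohort_id, "_phenotype.tsv")),
    exposure = file.path(dir, paste0(cohort$cohort_id, "_exposure.tsv")),
    snps = file.path(dir, paste0(cohort$cohort_id, "_snps.tsv"))
  )
  gdf <- data.frame(iid = id, cohort$genotypes, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write_tsv_stable(gdf, paths["genotypes"])
  write_tsv_stable(data.frame(iid = id, value = cohort$phenotype), paths["phenotype"])
  write_tsv_stable(data.frame(iid = id, value = cohort$exposure), paths["exposure"])
  write_tsv_stable(cohort$snp_meta, paths["snps"])
  invisible(paths)
}
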