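# Canonical study conditions for the shipped harnesses, defined once so the
# test suite and the acceptance script exercise the same designs.

#' Desk-scale null-calibration conditions
#'
#' The calibration design: marginal effects present, no interaction effects,
#' normal error (variance heterogeneity is exactly null), 2,000 individuals
#' by 2,000 SNPs per replicate, 200 replicates. The MAF range [0.15, 0.5] is
#' the n = 2,000 analogue of the 30-per-genotype-group rule: under HWE the
#' rare-homozygote group reaches 30 only for MAF above about sqrt(30/n).
#'
#' @param n_individuals,m_snps,replicates scale of the design.
#' @param seed global seed.
#' @return a [pipeline_config()].
#' @export
calibration_config <- function(n_individuals = 2000, m_snps = 2000,
                               replicates = 200, seed = 1) {
  pipeline_config(
    n_individuals = n_individuals,
    arch = arch_spec(
      m_snps = m_snps,
      maf_range = c(0.15, 0.5),
      effect = list(prop = 0.01, sd = 0.1),
      interaction = list(prop = 0, sd = 0),
      exposure_prevalence = 0.3,
      exposure_main_effect = 0,
      error_model = list(family = "normal", sd = 1)
    ),
    replicates = replicates, seed = seed
  )
}

#' Known-loci gene-environment recovery scenario
#'
#' A recovery design in which a small panel of "known loci" (SNPs with
#' GWAS-scale marginal effects) mostly carry genuine interaction effects:
#' `n_known` SNPs get beta of magnitude `beta_known` (alternating sign),
#' `n_gxe` of them additionally get delta of magnitude `delta_gxe`
#' (alternating sign, at common MAF in [0.3, 0.4] so the rare-homozygote
#' group is large), and the remaining SNPs are null. Used to show that the
#' binomial enrichment of P_v < 0.05 among known loci detects the
#' interaction signal while matched null loci stay near the nominal rate.
#'
#' The design is deliberately compact. A single shared binary exposure caps
#' how much interaction variance a trait can carry before it becomes a heavy
#' variance mixture: beyond roughly 3-5 units of exposure-conditional
#' interaction variance (on an error SD of 1), per-SNP variance contrasts
#' flatten (the group SD differences scale with the square root of the
#' background) and the Levene F approximation itself turns liberal for all
#' SNPs. A few strong interaction loci maximize per-locus detectability at a
#' fixed total variance load; the exposure main effect is 0 so positive and
#' negative delta are equally detectable.
#'
#' @param m_snps total SNPs.
#' @param n_known number of known loci.
#' @param n_gxe how many of them carry an interaction effect.
#' @param beta_known,delta_gxe effect magnitudes (trait z-units per allele).
#' @param n_individuals sample size.
#' @param seed global seed.
#' @return list: config (a [pipeline_config()]) and a `customize` function
#'   applied to a sampled truth table to impose the scenario.
#' @export
gxe_scenario <- function(m_snps = 300, n_known = 8, n_gxe = 7,
                         beta_known = 0.1, delta_gxe = 1.15,
                         n_individuals = 5000, seed = 1) {
  cfg <- pipeline_config(
    n_individuals = n_individuals,
    arch = arch_spec(
      m_snps = m_snps,
      maf_range = c(0.15, 0.5),
      effect = list(prop = 0, sd = 0),
      interaction = list(prop = 0, sd = 0),
      exposure_prevalence = 0.3,
      exposure_main_effect = 0,
      error_model = list(family = "normal", sd = 1)
    ),
    seed = seed
  )
  customize <- function(truth) {
    stopifnot(nrow(truth) >= n_known, n_gxe <= n_known)
    known_idx <- seq_len(n_known)           # first block: the known loci
    gxe_idx <- known_idx[seq_len(n_gxe)]
    truth$beta[known_idx] <- beta_known * rep_len(c(1, -1), n_known)
    truth$delta[gxe_idx] <- delta_gxe * rep_len(c(1, -1), n_gxe)
    truth$maf[gxe_idx] <- stats::runif(n_gxe, 0.3, 0.4)
    truth
  }
  list(config = cfg, customize = customize,
       n_known = n_known, n_gxe = n_gxe)
}
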