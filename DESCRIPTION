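Package: vqscreen
Title: Variance-Heterogeneity Screening of GWAS Loci for Gene-Environment
    Interaction Candidates
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Prioritizes genome-wide association study (GWAS) loci as
    candidates for gene-environment (GxE) interaction by testing
    between-genotype heterogeneity of phenotypic variance. Implements a
    summary-statistic meta-analysis of Levene's test across cohorts
    (per-genotype counts, means and variances of absolute deviations),
    trait preparation (log10, z-score, Winsorization), marginal and
    exposure-stratified association scans with a between-strata
    heterogeneity interaction test, windowed pairwise-r2 LD pruning, and
    the comparison machinery relating marginal, variance and interaction
    P-value distributions: percentile-scaled ranks, subset Spearman
    correlations with equality tests, exact binomial enrichment of known
    loci, odds ratios, and Mann-Whitney centile-shift tests with
    proximity exclusion. A multi-cohort synthetic-data generator with
    Hardy-Weinberg genotypes, GWAS-like architecture and a non-normal
    error lets every stage run self-contained, including null-calibration
    and power harnesses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), car, jsonlite, yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
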