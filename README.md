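# vqscreen

Variance-heterogeneity screening of GWAS loci for gene–environment
interaction candidates.

## The problem

A gene–environment (G×E) interaction at a SNP leaves a footprint even when
the environmental exposure is unmeasured: in the linear model

    Y = β G + a E + δ (G × E) + ε,

the phenotypic variance differs across the three genotype groups whenever
δ ≠ 0, because each extra effect allele adds δ²·Var(E) to the conditional
variance. Testing for between-genotype *variance heterogeneity* therefore
screens for interaction candidates across all exposures at once, using
genotype and phenotype data alone. `vqscreen` implements this screen and the
statistics needed to relate its P-values (P_v) to marginal-effect P-values
(P_m) and to explicit stratified interaction P-values (P_int), for study
designs where cohorts share only summary statistics.

## The statistic

Each cohort *s* prepares its trait (log10 → z-score → Winsorize at 4 SD),
forms the absolute deviations Z of each participant from their genotype
group mean, and submits per genotype group i ∈ {0,1,2} the counts n_is,
means Z̄_is and sample variances σ²_Zis. With natural weights
ω_is = n_is / n_i and γ_i = n_i / N, the pooled Levene statistic is

    L = (N − 3)/2 · [ Σ_i γ_i Z̄_i² − (Σ_i γ_i Z̄_i)² ]
        / Σ_i γ_i [ Σ_s (ω_is − 1/n_i) σ²_Zis + ω_is Z̄_is² − Z̄_i² ],

with Z̄_i = Σ_s ω_is Z̄_is, referred to F(2, N − 3). With one cohort this is
exactly the classical mean-centered Levene one-way ANOVA on Z (the package
verifies this equivalence to machine precision against an independent
implementation). Around the core test sit:

- QC filters (imputation info, HWE P < 1e-6, call rate ≥ 95%, MAF ≥ 1%,
  ≥ 30 per genotype group per cohort) and cross-cohort allele harmonization;
- marginal OLS scans and exposure-stratified scans with the between-strata
  z heterogeneity test (1-df Cochran's Q) for P_int;
- windowed pairwise-r² LD pruning (50-SNP window, 5-SNP step, r² > 0.1;
  0.8 for the odds-ratio analyses);
- prioritization statistics: percentile-scaled ranks (lowest P → 100th
  percentile), subset Spearman correlations with Fisher-z equality tests,
  one-sided exact binomial enrichment, odds ratios with Woolf intervals,
  Mann–Whitney centile-shift tests with ±500 kb known-locus exclusion, and
  average-rank enrichment across two interaction scans;
- a synthetic multi-cohort generator (Hardy–Weinberg genotypes, GWAS-like
  effect sizes, 30%-prevalence binary exposure, optionally right-skewed
  error) plus null-calibration and power harnesses.

## Worked example

A recovery experiment: 8 "known" loci with marginal effects, 7 of which
carry a real interaction with a binary exposure, among 300 SNPs in 5,000
individuals.

```r
library(vqscreen)

sc    <- gxe_scenario(seed = 42)
cfg   <- sc$config
seeds <- derive_seeds(cfg$seed, 5)
spec  <- cfg$arch; spec$seed <- seeds[1]
truth <- sc$customize(sample_architecture(spec))
G <- simulate_genotypes(truth, cfg$n_individuals, seed = seeds[2])
E <- simulate_exposure(cfg$n_individuals, 0.3, seed = seeds[3])
y <- to_raw_scale(simulate_phenotype(G, truth, E, spec, seed = seeds[4]))

prep <- prepare_trait(y)                        # log10 -> z -> winsor
summ <- summarize_cohort(G, prep, "cohort1")    # per-genotype Z summaries
mv   <- meta_levene(qc_filter(summ, cfg$qc)$retained)
ms   <- marginal_scan(G, prep)
int  <- stratified_interaction_scan(G, prep, E)
```

The screen recovers the interaction loci:

```
prepared_phenotype: n=5000 (log10=TRUE, mean=1.44, sd=0.1158, winsor=4 SD, clamped=14)
known loci with P_v < 0.05: 7 of 8 (expected 0.4), P_binomial = 6e-09
OR of P_int<0.05 given P_v<0.05: 9.44 (95% CI 3.58-24.87)
```

Seven of the eight known loci fall in the nominally significant part of the
P_v distribution where 0.4 were expected by chance, and a SNP with
P_v < 0.05 has 9-fold higher odds of a nominally significant explicit
interaction test — the screening property the package exists to measure.
`run_pipeline(pipeline_config(...))` chains all of the above, LD pruning and
every report into one deterministic bundle.

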