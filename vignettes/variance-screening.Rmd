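---
title: "Screening GWAS loci for gene-environment interactions by variance heterogeneity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening GWAS loci for gene-environment interactions by variance heterogeneity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vqscreen)
```

## The model and its assumptions

Consider a quantitative trait influenced by a SNP with dosage $G \in
\{0,1,2\}$, a binary exposure $E$, and their interaction:

$$Y = \beta G + aE + \delta\,GE + \varepsilon .$$

Conditional on genotype, $\mathrm{Var}(Y \mid G=g) = (a + g\delta)^2
p_E(1-p_E) + \sigma^2_\varepsilon$: an interaction ($\delta \neq 0$) makes
the phenotypic variance change with allele count even when $E$ is never
observed. The screen tests this *variance heterogeneity* with Levene's
test — a one-way ANOVA across the three genotype groups of the absolute
deviations $Z_i = |Y_i - \bar Y_{g(i)}|$ — and compares the resulting
$P_v$ distribution against marginal-effect $P$-values ($P_m$) and explicit
exposure-stratified interaction $P$-values ($P_{int}$).

The key practical constraint is that cohorts do not share individual-level
data. Each cohort therefore submits, per SNP, only the per-genotype counts
$n_{is}$, means $\bar Z_{is}$ and sample variances $\sigma^2_{Z_{is}}$ of
$Z$. The meta-analysis statistic pools these with natural weights
$\omega_{is} = n_{is}/n_i$ and $\gamma_i = n_i/N$:

$$L = \frac{N-3}{2}\cdot
\frac{\sum_i \gamma_i \bar Z_i^2 - \big(\sum_i \gamma_i \bar Z_i\big)^2}
{\sum_i \gamma_i\Big[\sum_s \big(\omega_{is} - \tfrac1{n_i}\big)
\sigma^2_{Z_{is}} + \omega_{is}\bar Z_{is}^2\Big] - \gamma_i \bar Z_i^2},
\qquad \bar Z_i = \sum_s \omega_{is}\bar Z_{is},$$

referred to $F(2, N-3)$. The per-study variance correction admits more than
one algebraic transcription; this implementation fixes the reading
$\sigma^2_{Z_{is}}/(N\gamma_i) = \sigma^2_{Z_{is}}/n_i$, under which the
denominator is exactly the pooled within-group sum of squares divided by
$N$. That choice is pinned by a contract, not taste: with a single cohort,
$L$ must equal the classical mean-centered Levene statistic on the same
individuals, and the test suite verifies $|L - W|/\max(W,1) < 10^{-8}$ over
a thousand randomized cohorts (and against the independent `car`
implementation). Under the same reading, cohorts that duplicate the same
individuals pool to the classical statistic on the concatenated sample.

Assumptions worth stating: errors are i.i.d. within cohort (no covariate
adjustment is applied anywhere in the Levene pipeline — deviations are taken
from genotype-group means of the prepared trait); genotype groups are formed
from hard calls (imputed dosages are rounded, with an optional distance
threshold for no-calls); and $Z$ is computed within cohort before any
pooling, so cohort-specific trait locations do not masquerade as variance
signals.

## Trait preparation

Raw traits are prepared per cohort as log10 → z-score → Winsorization at 4
SD. The z-score uses the sample SD ($n-1$); the convention is recorded in
the returned transform log so any external check can reproduce it. No
re-standardization happens after clamping; the clamp count is logged.
Because the pipeline log-transforms first, any positive rescaling of the
raw trait cancels exactly — z-scores, $Z$, and $L$ are invariant, which the
tests assert to $10^{-12}$.

## Quality control and harmonization

Defaults mirror standard GWAS meta-analysis practice: imputation info below
platform thresholds, HWE $P < 10^{-6}$ (1-df goodness of fit), call rate
below 95%, MAF below 1%, and — specific to the variance test — at least 30
participants per genotype group per cohort, since the group variance of $Z$
is the submitted sufficient statistic and small groups estimate it poorly.
Strict mode (default) drops a cohort×SNP when any group is undersized; a
permissive mode instead masks undersized groups, because the pooled test
needs all three groups only after pooling. Alleles are harmonized to a
reference orientation before meta-analysis; strand-ambiguous A/T and C/G
SNPs are aligned by allele frequency only when both frequencies are at
least 0.15 away from 0.5, and dropped otherwise.

## Prioritization statistics

Percentile-scaled ranks assign the lowest $P$ the 100th percentile:
$\mathrm{pct} = 100(m - r + 1)/m$ with average ranks for ties. On an
LD-pruned set (windowed pairwise $r^2$, default 50/5/0.1; removal drops the
lower-MAF member of an offending pair, ties drop the later position —
deterministic where the reference tool leaves the choice to implementation
details), the package computes:

- Spearman correlations between $P_m$ and $P_v$ for nested subsets (all
  pruned SNPs; $P_m < 0.05$; $P_m < 10^{-4}$; known loci), each with a
  Fisher-z equality test against the reference subset. The equality test is
  the independent-samples form although the subsets are nested; this is
  documented rather than silently altered, as the dependence correction
  requires the joint distribution the summary data do not carry.
- One-sided upper-tail exact binomial enrichment: among $n$ eligible SNPs,
  the probability of at least $k$ with $P < 0.05$ at null rate 0.05. No
  multiple-testing correction is applied anywhere; reports carry the number
  of tests.
- Odds ratios of threshold indicators with Woolf intervals
  (Haldane-Anscombe 0.5 on zero cells, flagged).
- Mann-Whitney centile-shift tests: the "100th centile" band is percentile
  $> 99$, the "99th centile" band is $(98, 99]$ against $\le 98$ —
  half-open on the left, so bands partition exactly. The normal
  approximation with tie-corrected variance (no continuity correction) is
  the default at scan scale; an exact path (base `pwilcox`) is used for
  small tie-free samples and is checked against exhaustive enumeration.
  Known loci and SNPs within ±500 kb (inclusive) of one can be excluded.
- Average-rank enrichment across two interaction scans: success is an
  average percentile above 95, tested at null rate 0.05. Under independent
  uniform ranks the true success probability is 0.005, so this cut is
  conservative by construction; it is kept because it matches the
  published convention.

## The synthetic-data generator

The generator emulates the study conditions the analysis was designed for:
HWE genotypes for a pruned (independent-SNP) panel — 50,335 SNPs and 44,000
individuals at reference scale — GWAS-like architecture (a small fraction
of SNPs with normal-scale marginal effects), a fixed binary exposure of 30%
prevalence, and an error whose prepared trait is right-skewed like
transformed BMI. The skewed family is a shifted, variance-standardized
log-normal; with shape `sdlog = 0.25` the prepared trait's skewness lands
in [0.3, 0.8] (asserted in tests on a 200,000-individual draw). Positions
sit on one synthetic chromosome at 10 kb spacing, so coordinate logic runs
without a real map; an autoregressive haplotype-coupling option creates
within-block LD solely to exercise the pruner. The generator does not model
real LD maps, population structure, relatedness or imputation uncertainty —
so passing tests demonstrate the statistics are computed correctly under
the stated model, not that the screen is robust to confounding a real
cohort may carry.

## Numerical choices

Upper-tail $P$-values are floored at $10^{-300}$ and flagged; exact-fit
regressions report the floor rather than zero. Group variances use the
$n-1$ denominator everywhere, with singleton groups contributing their mean
but no variance term (their variance weight $(n_{is}-1)/n_i$ vanishes).
Zero within-group variance with nonzero between-group dispersion yields the
floored $P$; fully degenerate inputs yield $L = 0$, $P = 1$. All random
stages take explicit seeds; replicate seeds derive from one master seed so
any subset of replicates reproduces independently. Report files are written
with fixed 10-significant-digit formatting, making identical analyses
byte-identical — the determinism the acceptance checks assert with file
hashes.

## Desk-scale study designs

Two standing experiment designs ship with the package (used by both the
test suite and `scripts/acceptance.R`):

**Null calibration** (`calibration_config()`): 200 replicates of 2,000
individuals × 2,000 SNPs, marginal effects present (1% of SNPs,
SD 0.1), no interactions, normal error. Normal error is the right null
here: the variance test's $F$ reference is exact under it, and the
[0.04, 0.06] band asserted for the fraction of $P_v < 0.05$ is meaningful.
The MAF floor of 0.15 is the $n = 2{,}000$ analogue of the 30-per-group
rule (under HWE the rare-homozygote group reaches 30 around MAF
$\sqrt{30/n} \approx 0.12$). Per replicate the harness records the three
pairwise Spearman correlation $P$-values among $P_m/P_v/P_{int}$, binomial
enrichment $P$-values of $P_v<0.05$ among $P_m<0.05$ and among
$P_{int}<0.05$, and top-centile Mann-Whitney $P$-values in both directions.
A caveat discovered by running the design: with ~100 eligible SNPs the
exact binomial $P$ is a *discrete* statistic with atoms up to ~0.15, so its
raw distribution cannot pass a continuous-uniformity KS test at any
calibration — its CDF touches the diagonal only at the atoms and is
conservative in between (measured $P(P \le 0.05) \approx 0.03$). The
harness therefore also records the randomized-tail version
$P(X > k) + U\,P(X = k)$, exactly Uniform(0,1) under the null, as the
discreteness-correct uniformity check; the raw conservativity is asserted
as bounds.

**Known-loci G×E recovery** (`gxe_scenario()`): 300 SNPs × 5,000
individuals; 8 known loci with $\beta = \pm 0.1$, 7 of them with
$\delta = \pm 1.15$ at MAF 0.3-0.4; exposure main effect 0; normal error.
The design is compact on purpose. A single shared exposure caps the total
interaction variance a trait can carry: each interaction SNP adds
$2pq\delta^2$ to the exposed stratum's variance, and once that load passes
roughly 3-5 (on unit error SD) the trait becomes a pronounced variance
mixture — per-SNP group-SD contrasts flatten like
$\sqrt{1 + v + 4\delta^2} - \sqrt{1 + v}$ in the background load $v$, and
the $F$ approximation of the Levene test turns liberal for *all* SNPs at
these group sizes. Within that budget, a few strong interaction loci at
common MAF (large rare-homozygote groups) maximize per-locus power; a zero
exposure main effect keeps $+\delta$ and $-\delta$ equally detectable,
since the stratum-variance contrast is $(a + g\delta)^2 - a^2$. Even so the
mixture leaves the null loci mildly liberal (about 6% at nominal 5%), which
is why the recovery design asserts "near nominal" (within two percentage
points) for matched null loci while the strict band lives in the all-null
calibration. This liberality at moderate group sizes — a textbook property
of mean-centered Levene under heavy-tailed data, reproduced here under a
skewed log-normal error as well — is worth remembering when interpreting
real screens at modest cohort sizes.

## Known limitations

Levene $P$-values are approximate for skewed or heavy-tailed traits at
moderate per-group sizes (mildly anticonservative; see above) — the trait
preparation exists precisely to temper this, and the reference-scale
analyses operate at group sizes where the approximation is comfortable.
The marginal and stratified scans are single-sample OLS without covariates,
standing in for consortium meta-analysis results; the equality-of-
correlations test ignores subset nesting; the average-rank cut is
conservative; and the generator's independence assumptions mean LD-driven
artefacts (e.g. variance misclassification near haplotypes carrying rare
functional variants) are out of scope for what the tests can demonstrate.
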