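---
title: "Methods: phenotype derivation, gene-based association and cohort combination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phenotype derivation, gene-based association and cohort combination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adpgx)
```

# Scope

`adpgx` implements a complete pharmacogenetic association pipeline for
antidepressant treatment response in major depressive disorder (MDD):
derivation of treatment-response phenotypes from 21-item Hamilton Rating
Scale for Depression (HRSD-21) trajectories, multiple imputation of
missing phenotype values, genotype quality control, covariate-adjusted
single-marker association, a permutation-based gene-level test, and
combination of two cohorts by Fisher (inverse-gamma) meta-analysis and
pooled mega-analysis. A synthetic two-cohort trial generator with known
ground truth exercises the pipeline end to end.

# Treatment-response phenotypes

Subjects are assessed at weeks 0 (baseline), 2, 4 and 8. Four phenotypes
are derived per subject:

1. **Remitted** — week-8 HRSD-21 total: coded 1 if the total exceeds 7,
   2 (remitted) otherwise. A total of exactly 7 is remitted; the coding
   is forced by "greater than 7, otherwise remitted".
2. **Response** — percent change at week 4,
   $\%\Delta = (T_4 - T_0)/T_0$ (negative = improvement): non-response
   if the reduction is less than 50%, response otherwise, so a reduction
   of exactly 50% counts as response.
3. **Percent change** — the signed continuous $\%\Delta$ itself, kept at
   week 4 for consistency with the binary response definition (whether
   the continuous index should be read at week 4 or week 8 is
   ambiguous in the source material; week 4 is used and flagged here).
4. **Stem-depressed** — HRSD item 1 ("depressed mood") at week 4: coded
   1 if the score is 3 or 4 (moderately severe or severe), 2 otherwise.

Phenotypes are computed on observed data; a phenotype whose defining
visit is missing is `NA` and only the imputation module fills it.

# Multiple imputation

Missing weekly measures are imputed by chained-equation stochastic
regression (`impute_stack()`): each incomplete variable is regressed on
the covariates and the other weekly measures, and each missing cell is
filled with the regression prediction **plus a residual draw** from the
fitted residual distribution — two subjects with identical predictors
receive different imputed values, preserving natural variability. The
chained pass is repeated over `cycles = 4` sweeps and the whole
procedure `m = 30` times by default (both configurable; the pipeline
demo uses smaller `m` purely as a problem-size choice). The named model
family in the source material is a "linear mixed regression"; its exact
random-effects structure is unstated, so the package realizes it as
chained normal linear regressions in which a subject's other observed
visit totals act as the subject-level information — this preserves the
two stated properties (random error added; variability maintained) with
a single, auditable model. Categorical codes are never imputed
directly: the continuous totals are imputed and the codes re-derived, so
coding rules stay single-sourced.

Estimates across the $m$ completed datasets are pooled by Rubin's rules
(`pool_rubin()`): $\bar Q = \tfrac1m\sum Q_i$,
$\bar W = \tfrac1m\sum W_i$, $B = \mathrm{var}(Q_i)$,
$T = \bar W + (1 + 1/m)B$, with degrees of freedom
$(m-1)\,(1 + \bar W/((1+1/m)B))^2$ (Barnard–Rubin adjusted when the
complete-data df is supplied). For $m = 1$, $B$ is defined as 0.

# Genotype quality control

Markers: exact conditional Hardy–Weinberg test (two-sided: the sum of
probabilities of all heterozygote configurations no more probable than
observed, given the allele counts), genotype missing rate, and minor
allele frequency. The retention rule is `HWE p > 1e-4` (strict),
`missing rate <= 0.05` (inclusive) and `MAF >= 0.05` (inclusive). The
mid-p variant of the exact test is not used; the standard exact test is
the dominant convention at this threshold. Samples: call rate (strictly
greater than 0.97 retained), inbreeding coefficient
$F = 1 - H_{obs}/H_{exp}$, pairwise identity-by-state distance, and
classical (Torgerson) multidimensional scaling of the IBS distance with
a median-absolute-deviation outlier rule (default 6 MADs, exposed, not
asserted — the source material does not state numeric kinship or
outlier cutoffs). Plate metadata is not modelled; plate-level checks
reduce to the per-sample call rate. Kinship pairs drop the member with
the lower call rate.

# Single-marker association

Additive (1-df) coding counts minor-allele copies, with orientation
computed on the analysis sample. Continuous phenotypes use least
squares, binary phenotypes maximum-likelihood logistic regression, both
adjusted for age and sex and tested by the Wald statistic
(`single_marker_test()`), complete-case per variant. Binary codes map
to events so that OR > 1 always means a better outcome for the minor
allele (remitted = event; response = event; not-stem-depressed =
event). The chi-square difference test omits the Yates correction and
the t-test pools variances, both configurable conventions.

# Gene-based permutation test

For a gene region (1-based inclusive coordinates, 50 kb flanks on both
sides, boundary positions included):

1. Map variants into the flanked window.
2. **Prune for LD** in ascending position order: a variant is kept iff
   its $r^2$ (squared Pearson correlation of dosages) with every
   already-kept variant is below 0.5. Position order — not p-value
   order — makes the retained set phenotype-independent, so it is fixed
   across permutations; this is essential for calibration.
3. Compute marker p-values on the retained set and the truncated-Fisher
   statistic $T = \sum_{p_j < 0.1} -2\ln p_j$ ($T = 0$ if no marker
   qualifies). The choice of $-2\ln p$ as the "summed association
   signal" is a design decision (the source names no formula); under
   the permutation null any monotone choice yields a valid empirical p.
4. Draw the null by permuting the **subject labels of the genotype
   block** while phenotype–covariate pairs stay fixed: marker–marker LD
   is preserved exactly in every permutation — this is the sense in
   which the sum is "corrected for LD". The p < 0.1 truncation is
   phenotype-dependent and therefore re-applied inside every
   permutation.
5. Empirical p $= (1 + \#\{T^{perm} \ge T^{obs}\})/(K+1)$ with
   $K = 50{,}000$ by default; ties count against significance.

Marker p-values inside the permutation loop come from a fast engine:
for the linear family a partial-correlation t-test that is
algebraically identical to the Wald t from `lm()`; for the logistic
family an efficient score test against the null model
`y ~ covariates`, which is fixed across permutations and fitted once.
The user-facing `single_marker_test()` is an independent route and the
test suite cross-checks the two.

**Calibration and the truncation atom.** Under the null, a gene whose
retained markers all have $p \ge 0.1$ has $T^{obs} = 0$; every
permutation then ties it ($T^{perm} \ge 0$ always), so its empirical p
is exactly 1. The truncated statistic therefore has an atom at 1 (about
a quarter of null genes under the default simulation conditions) and is
*conservative*, not uniform, over the full range; its size at 0.05 is
unaffected because the lower tail comes from genes with real signal
exceedances. The suite verifies full-range uniformity for the
untruncated statistic (every marker contributes, $T$ continuous) and
the 0.05-level size for both versions. Missing dosages inside the gene
engine are per-variant mean-imputed (synthetic genotypes are complete;
this matters only for user-supplied data with sporadic missingness).

# Cohort combination

Per-cohort p-values are combined by the inverse-gamma model
(`inverse_gamma_combine()`): each $p_i$ maps to the upper-tail
$\Gamma(\alpha, 1)$ quantile, the sum refers to the upper tail of
$\Gamma(k\alpha, 1)$. With $\alpha = 1$ this is exactly Fisher's
method ($-2\ln p$ against $\chi^2_{2k}$), and a single p-value passes
through unchanged. Fisher combination is direction-blind: opposite-sign
effects can reinforce; this matches the published method choice and is
deliberately not "fixed".

Mega-analysis pools the two cohorts' genotypes (`merge_cohorts()`:
variant-id intersection, ref/alt-swap dosage flipping, dropping of
irreconcilable and of common strand-ambiguous A/T / C/G variants) and
reruns the identical scan machinery, adjusting for age and sex only by
default (a cohort indicator is available via `covariates` — whether the
published mega-analysis included one is unstated, so the default
follows the stated covariate list).

Marker tiers are significant / suggestive / weak at
$5\times10^{-4}$ / $5\times10^{-3}$ / $10^{-2}$ and gene tiers
significant / suggestive at $10^{-2}$ / $5\times10^{-2}$, strict `<`
comparison; the headline counting rule requires the threshold in
**both** meta- and mega-analysis. The LD-adjusted Bonferroni divisor is
the Li–Ji effective number of tests,
$M_{eff} = \sum_i [\,I(\lambda_i \ge 1) + (\lambda_i -
\lfloor\lambda_i\rfloor)\,]$ over eigenvalues of the absolute dosage
correlation matrix (the cited correction method names no formula; Li–Ji
is the conventional choice, and the fixed tier scheme above is treated
as authoritative for reproduction).

# The synthetic-data generator

`sim_config()` defaults describe the emulated study conditions:

* Two cohorts of 253 and 175 subjects; male fractions 0.174 / 0.451;
  ages $\mathcal N(41.0, 13.7^2)$ / $\mathcal N(47.4, 15.1^2)$ years.
* **Genotypes**: independent LD blocks; within a block all variants
  share one target allele frequency (drawn uniformly from the MAF range
  0.05–0.5) and haplotype alleles are thresholded from an equicorrelated
  latent Gaussian with correlation `block_cor`. This is the simplest
  mechanism giving tunable pairwise $r^2$ for the pruning machinery; a
  correlation of 1 makes a block's call vectors identical. Blocks are
  independent, so long-range LD decay is *not* modelled.
* **Trajectories**: baseline total $\ge 14$ (trial inclusion floor),
  truncated normal around 22 (s.d. 3); weekly totals
  $T_w = T_0 + d_i\, s(w) + \varepsilon$ with a nonlinear time scale
  $s = (0, 3.68, 4.35, 5.5)$ at weeks 0/2/4/8, per-subject decline
  $d_i \sim \mathcal N(-2.25, 0.6^2)$ plus additive causal-dosage
  effects, and visit noise s.d. 1.5. These values were solved from the
  target marginals — remission 6.1% / 13.3% / 32.7% at weeks 2/4/8 and
  week-4 response 38.7% — and then fixed; at $n = 2000$ the realized
  rates land within about one percentage point of the targets.
* **Items**: each weekly total is spread over the 21 items by weighted
  largest-remainder allocation capped at item maxima (ten items 0–4,
  eleven 0–2), with item-1 weight 3.8 chosen so the stem-depressed rate
  is near 11.4%. The allocation is deterministic; real item profiles
  are more heterogeneous, but only item 1 and the total matter
  downstream.
* **Missingness**: per subject, 0 / 1 / 2 post-baseline visits are
  removed with probabilities 0.92 / 0.07 / 0.01; baseline is never
  removed. "Two or more" is realized as exactly two (the detailed
  published pattern table is not available; only the marginals are
  emulated).

What passing tests on this generator show — and what they do not: the
generator reproduces the marginal response distributions, block LD and
missingness patterns, so calibration, recovery and round-trip results
transfer to data with those features. It does not model item-level
measurement error, informative (MNAR) dropout, long-range LD,
drug-specific pharmacokinetics, or genotype imputation uncertainty;
conclusions about those aspects of real data are outside what the test
suite can certify.

# Numerical choices and degenerate inputs

* HWE exact probabilities are computed in log space; the two-sided sum
  uses a $1 + 10^{-10}$ relative tie tolerance.
* Monomorphic dosages, perfect logistic separation (se > 20) and
  fewer than 10 complete cases yield status flags, never exceptions.
* A zero baseline total is an error for percent change (undefined
  ratio); generated baselines are $\ge 14$.
* Empirical p-values use the add-one estimator, bounded in
  $[1/(K+1), 1]$.
* Every stochastic routine takes an explicit seed; per-stage child
  seeds are derived from the master seed, so reruns are bit-identical.

# Problem sizes

The packaged tests and the acceptance script use scaled problem sizes
chosen as reasonable simulation designs: 500 null genes at
$K = 999$ permutations for calibration, 200 replicates for effect
recovery, $n = 2000$ generator draws for marginal checks, and small
two-cohort pipelines (about 130 subjects, 12 variants, $K = 99$,
$m = 2$) for end-to-end determinism. The full-scale defaults
($K = 50{,}000$, $m = 30$) remain the package defaults for real use.

# Known limitations

* The permutation gene test is exchangeable-null based; confounding
  that differs between genotype rows (e.g. population structure not
  captured by the covariates) is not protected against beyond the QC
  MDS screen.
* Fisher meta-analysis ignores effect direction.
* The chained-equation imputer assumes approximate normality of the
  weekly totals; codes are re-derived after imputation rather than
  imputed on their own scale.
* The overall remission rate of 36.21% reported alongside the weekly
  rates in the source material has no stated denominator and is not
  reproduced.
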