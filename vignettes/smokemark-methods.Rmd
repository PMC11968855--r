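---
title: "smokemark: models, generators and numerical conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{smokemark: models, generators and numerical conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the models it
fits, the worlds its generators state, the numerical conventions that make
its tests exact, and the design choices made where the design was
genuinely open. It states no empirical result that the test suite does not
itself compute.

## 1. The analysis problem

Cumulative smoking exposure is measured by *pack years* (years smoked ×
cigarettes per day / 20, zero for never smokers). Whole-blood DNA
methylation carries a dose-dependent smoking signature, which supports two
complementary analyses:

* an **EWAS**: which CpG sites associate with pack years, and how much of
  the phenotype's variance does methylation explain jointly?
* a **biomarker**: a sparse linear score over CpGs that predicts pack
  years and discriminates current, former and never smokers in cohorts it
  was never trained on.

The cohorts that motivate this package are under restricted access, so
every pipeline stage is exercised on synthetic cohorts whose statistical
structure matches what the analyses assume (section 5).

## 2. The Bayesian mixture EWAS

With `y` the processed phenotype and `X` the processed methylation matrix
(section 3), the model is

$$y = X\beta + e,\qquad
\beta_j \sim \pi_0\,\delta_0 + \sum_{k=1}^{4}\pi_k\,
N(0,\,c_k\,\sigma^2_\beta),\qquad
c = (0.001,\,0.01,\,0.1,\,1),$$

a discrete spike at the origin plus four Gaussian slabs whose variances
are fixed fractions — 0.1%, 1%, 10% and 100% — of a common effect-scale
parameter $\sigma^2_\beta$. This is the standard BayesR parameterization;
the stated percentages are read as fractions *of the sampled scale*, not
absolute variances. Remaining priors (defaults exposed in
`mixture_prior()`): $\pi \sim \mathrm{Dirichlet}(1,1,1,1,1)$ and scaled
inverse-chi-square with 4 degrees of freedom on both $\sigma^2_\beta$
(scale 0.01) and $\sigma^2_e$ (scale 1). These hyperpriors are
weakly-informative defaults of this package, documented rather than
asserted to equal any external software's.

One Gibbs sweep samples, for each CpG in input order, the 5-way component
indicator from its full conditional with the effect integrated out
analytically per component (log weights with max subtraction for
stability), then the effect given the indicator; afterwards $\pi$ from
its Dirichlet full conditional and both variances from scaled
inverse-chi-square full conditionals. The chain default follows the
published protocol: burn-in 5000, then every fifth sample retained across
10,000 post-burn-in iterations, i.e. 2000 retained draws. ("10,000
iterations" is read as post-burn-in iterations; the other reading is a
one-line `chain_config` change.) The update order is fixed for
reproducibility; `random_scan = TRUE` enables a permuted scan.

Implementation: for `p ≤ cache_max_p` the sampler caches $C = X'X$ once
and maintains $u = X'r$ and $w = C\beta$ by rank-one updates — only
coefficients that actually move touch them — making a sweep
$O(p + kp)$ with $k$ the number of active CpGs instead of $O(np)$. The
streaming fallback handles larger `p`. Both paths are cross-checked in
the tests, and a `check_residual` mode verifies that the maintained
statistic never drifts more than 1e-8 from a from-scratch recompute.

Outputs per CpG: the posterior inclusion probability (share of retained
draws with a non-zero indicator), the posterior mean effect, and mean
component probabilities. Variance explained is computed per retained draw
as $\mathrm{var}(X\beta)/\mathrm{var}(y)$ with population variance;
`variance_explained()` reports the mean and an equal-tailed percentile
interval. Significance calling is *strict*: PIP > 0.95 (epigenome-wide
significant) and PIP > 0.80 tiers, a PIP exactly at a threshold is
excluded.

## 3. Phenotype and methylation processing

* pack years: `years × cigs/day / 20`; years = stop − start for former
  smokers (abstinent gaps are not subtracted — the questionnaire has no
  gap information), current age − start for current smokers; zero for
  never smokers. Negative durations become record errors, never clipped
  values.
* consistency screen (`flag_inconsistent_records`): never smokers with
  nonzero consumption or any start/stop age; stop ≤ start; start after
  current age; current smokers with a stop age. Flagged records are
  excluded everywhere downstream, and the screen is idempotent.
* phenotype: ln(pack years + 1), residualized on age and sex, scaled to
  mean 0 and variance 1. **Population (1/n) variance** is the convention
  throughout the package so that "variance of 1" is exact at any n.
* methylation: each CpG residualized on age, sex (0/1 indicator) and
  batch (full dummy coding, reference = first sorted level; the source
  protocol is silent on coding) and standardized. Residualization is a
  separate up-front step — both EWAS modules consume the same
  residualized matrix — rather than joint fitting. Zero-residual-variance
  CpGs are dropped with a warning.
* array fractions are analysed on the M-value (logit) scale where linear
  models are better specified; `beta_to_mvalue()`/`mvalue_to_beta()`
  convert with a 1e-6 boundary clamp.

## 4. Marginal EWAS, coverage QC, matching

`ewas_lm` regresses *methylation on smoking* (site as outcome), matching
the printed effect direction of the motivating analyses, with covariates
age and sex; p-values use the t reference at the exact residual degrees
of freedom — at n = 46 the normal approximation is visibly wrong.
Phenotype codings: binary (current vs never), ordinal 0/1/2
(never/former/current, treated as continuous), or continuous. λ is the
median observed 1-df chi-square over its null median. Tiers are strict:
P < 3.6×10⁻⁸ genome-wide, P < 1×10⁻⁵ suggestive; the small-sample brain
mode uses the single 1×10⁻⁵ tier. Cross-platform overlap intersects
tiered hits by exact half-open interval identity after a genome-build
check; no fuzzy windowing.

Coverage QC applies, in order: (1) mask per-sample entries with depth
< 2 (sites left with no observed entry are removed); (2) remove sites
whose mean observed depth is *strictly greater than* the 0.99 quantile
(type 7) of the per-site mean-depth distribution — per-site, because the
filter acts on loci; ties at the quantile survive, so a constant-depth
table loses nothing; (3) remove sites overlapping the supplied C→T
polymorphism BED (the mask is an input — reproducing it needs an external
variant database); (4) retain sites covered in ≥ 40 samples at ≥ 10
(short-read panel) or ≥ 5 (long-read) reads. The audit log accounts for
every site: per-step removals plus survivors equal the input count.
Long-read per-strand records are collapsed to the forward-strand CpG
dinucleotide by summing counts (CpG methylation is palindromic).

Matching: cases are the top pack-years current smokers per sex (ties
broken by sample id); controls are never smokers matched greedily within
sex by nearest age, processing cases with the fewest eligible controls
first, each control used once. The published contract — sex identical,
age gap strictly under 12 months — is enforced independently by
`validate_pairs`, so the matcher's internals are free. Ages are compared
in days where available; the day-level window is stricter than the
integer-year reading and satisfies the same contract.

## 5. The synthetic-data generators

`simulate_methylation_cohort` states the following world (defaults in
`sim_config()`):

* covariates: age ~ round N(47.6, 14.9²) clamped to 18–99, 59.1% female,
  4 batches — the demographic shape of a population cohort.
* methylation, on the M-value scale: per-CpG baseline logit-uniform in
  (0.1, 0.9); per-CpG age/sex loadings N(0, 0.1²) and batch offsets
  N(0, 0.2²); idiosyncratic noise with per-CpG SD uniform in (0.4, 1.2);
  optional AR(1) correlation between adjacent CpGs (default 0 — no claim
  of realistic long-range structure, probe chemistry or beadchip
  artefacts). Stored values are inverse-logit beta values in [0, 1].
* effects: a CpG is null with probability 0.99; otherwise it joins slab
  k with proportions (0.006, 0.003, 0.0008, 0.0002) and draws
  N(0, c_k); effects are scaled so the methylation part g (built from
  the *covariate-free, standardized* noise component) has variance
  `target_h2` (default 0.5) of the covariate-adjusted phenotype.
* phenotype: latent trait = 0.2·age_s + 0.1·sex_c + g + e with
  var(e) = var(g)(1 − h²)/h², then pack years
  `expm1(1.25 · (t − t_cut))` with the lowest `never_smoker_fraction`
  (default 0.5) censored to zero — the zero-inflated questionnaire shape,
  with never smokers the lowest-exposure tail. The truth record stores
  g, e and `realized_vexp = var(g)/var(g + e)` (population variances),
  recomputable exactly from the emitted truth columns.
* the per-CpG architecture is returned and can be **reused** to draw an
  independent cohort from the same population — required for any
  cross-cohort score-transfer experiment.

Because effects act on the latent logit scale and the logit is inverted
exactly during analysis, the estimand `realized_vexp` is recoverable; a
green parameter-recovery test establishes that the sampler is calibrated
*in this stated world*, not that real blood methylation satisfies it.
Zero-inflation censors the latent phenotype, so the recovery experiments
(acceptance criteria 1 and 4) run the continuous configuration
(`never_smoker_fraction = 0`); null-calibration and evaluation runs keep
the zero-inflated default. The log-normal-like pack-years shape for
smokers is a stand-in choice, not an inference about any cohort.

In the support-recovery world (criterion 4) the 20 true sites carry
equal-magnitude, random-sign effects, each explaining h²/20 of phenotype
variance. Drawing the 20 effects from a Gaussian slab instead leaves
~40% of "true" sites with marginal correlations below 0.06 —
undetectable at n = 2000 by any selector — and the criterion would then
measure the effect-size lottery rather than the selector.

Questionnaire, coverage and genotype generators: smoking status is
assigned before pack years (never ⇒ 0; smokers' consumption is
log-normal around 15 cigarettes/day); a corruption rate injects exactly
one inconsistency per corrupted record for testing the screen. Read
totals are negative binomial (mean depth × dispersion 3 — the source
protocol states no depth law, so overdispersion is exposed as a knob)
with binomial methylated counts around a bimodal methylome; designated
sites get a case–control fraction shift. Genotypes are Hardy–Weinberg
dosages at uniform allele frequencies with an additive polygenic part
scaled to `h2_snp`; SNPs are independent (no LD).

All generators draw from per-operation RNG streams derived from the
master seed by a fixed Lehmer step (`derive_seed`), so adding a generator
never shifts existing draws, and identical configs are byte-identical.

## 6. Biomarker, evaluation, genotype scan

The elastic net minimises
$\frac{1}{2n}\|y - b_0 - X\beta\|^2 + \lambda(\alpha\|\beta\|_1 +
\frac{1-\alpha}{2}\|\beta\|_2^2)$ with α = 0.5, λ chosen by 10-fold
cross-validation (seeded fold permutation) minimising mean squared
prediction error over a 100-knot path spanning four decades below
λ_max, refit on all data at the selected λ. The fit is delegated to
glmnet — the package the motivating analysis itself used — behind this
module's interface; the KKT residual check and a proximal-gradient
oracle are independent code, so solver and oracle never collapse onto
one library. One numerical subtlety is load-bearing: glmnet internally
standardizes the response, which rescales the *ridge* component of the
penalty by the response SD; the stated objective therefore corresponds
to the fit exactly when the target has unit population variance — which
the processed phenotype always has. Predictors are standardized
internally (the published model's choice is unstated; both modes are
supported) and weights are stored on the raw methylation scale together
with training means, so projection onto a new cohort imputes absent
sites at their training means (> 50% absent escalates to an error in
strict mode). The training target defaults to the processed phenotype;
raw pack years is a config switch for sensitivity.

Evaluation: incremental R² = R²(y ~ age + sex + score) − R²(y ~ age +
sex), non-negative by nesting; Pearson and Spearman (average ranks)
correlations; ROC-AUC by the rank statistic
(P(case > control) + ½P(tie)); PR-AUC by step-wise interpolation over
observed-score thresholds with ties grouped, anchoring precision at
recall 0 to the highest-score threshold (no interpolation to (0, 1) —
conventions differ, so this one is pinned; under a non-informative score
the expected PR-AUC is the positive-class prevalence). Contrasts are the
three pairwise category comparisons, never multi-class.

The genotype module is an explicit **stand-in**: the mixed-model
machinery that corrects for relatedness in the motivating cohort is
off-the-shelf, so it is replaced by an OLS scan on unrelated simulated
samples (dosage + age + sex + top-k PCs of the standardized dosage
matrix, sign-fixed by the largest loading), λ as above, tiers at
5×10⁻⁸ / 1×10⁻⁵, plus Haseman–Elston regression of off-diagonal
phenotype cross-products on GRM entries
$A_{ij} = \frac{1}{p}\sum_k z_{ik}z_{jk}$ (sample-frequency
standardization, missing dosages mean-imputed) with a delete-one
jackknife SE. No numeric equivalence with any published mixed-model
heritability is claimed — only qualitative recovery on synthetic data.

## 7. Known limitations

* The generators state simple worlds: no array probe chemistry, no cell
  composition, no LD, independent CpGs by default. Green tests establish
  internal correctness and calibration, not biological realism.
* Single-chain inference, as in the motivating protocol; no multi-chain
  convergence machinery.
* The coverage filter's "covered in ≥ 40 samples" rule is applied
  per-platform; whether the source applied it jointly across platforms
  is unstated.
* `score` assumes missingness at random given the training means; heavy
  cross-platform missingness degrades scores silently below the 50%
  escalation threshold.
* HE regression is noisy at small n and is gated to n ≥ 50.
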