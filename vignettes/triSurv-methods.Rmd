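---
title: "Two-way co-clustering and survival prognosis: models and design"
author: "triSurv maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-way co-clustering and survival prognosis: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triSurv)
```

## The problem

High-dimensional radiomic feature tables — hundreds to thousands of
quantitative descriptors extracted from PET and CT tumour delineations — are
used to predict overall survival of cancer patients after treatment. Two
obstacles dominate at typical cohort sizes (one to two hundred patients):
many features are irreproducible between readers, and the reproducible ones
are massively redundant. `triSurv` implements a complete prognostic pipeline
for this setting:

1. **Feature selection** — keep features whose two-reader intraclass
   correlation exceeds 0.75, then greedily prune within-modality Pearson
   redundancy (PET at $|r| \ge 0.76$, CT at $|r| \ge 0.40$).
2. **Two-way clustering** — factorize the patients-by-features matrix
   $X \approx A S Y$ with non-negative factors, $A$ clustering patients into
   $K_s$ risk groups, $Y$ clustering features into $K_f$ families and $S$
   coupling them; the meta-feature matrix $M = AS$ is the low-dimensional
   model input.
3. **Stratification** — Kaplan–Meier curves and (pairwise) log-rank tests on
   the cluster labels, at $K_s = 2$ and $3$.
4. **Prediction** — Cox, Lasso-Cox and random survival forest models on $M$,
   compared by Harrell's C under repeated 3-fold cross-validation, with
   K-means, PCA and clinical-covariate baselines and a three-tier
   feature-combination AUC analysis.

Because no patient-level data are distributed with the package, a synthetic
cohort generator reproduces the statistical structure these methods assume;
every pipeline stage is validated end-to-end against it.

## The factorization model and its optimizer

The model is
$$\min_{A, S, Y \ge 0} \; \lVert X - A S Y \rVert_F^2
  \quad \text{s.t.} \quad A^\top A = I, \; Y Y^\top = I,$$
with $A \in \mathbb{R}_+^{N \times K_s}$, $S \in \mathbb{R}_+^{K_s \times
K_f}$, $Y \in \mathbb{R}_+^{K_f \times F}$. Non-negative columns of $A$ that
are mutually orthogonal must have disjoint supports, i.e. they are
(scaled) cluster indicators; the same holds for the rows of $Y$. The package
takes this observation literally:

* **Initialization.** Each restart runs a randomly started k-means on the
  rows and on the columns of $X$. The resulting partitions define indicator
  matrices $A$ and $Y$ whose off-support entries are exactly zero, so the
  orthogonality constraints hold *by construction* and are preserved by the
  multiplicative updates (a multiplicative update never revives an exact
  zero). $S$ is initialized by clipped least squares.
* **Updates.** Each factor is updated by the multiplicative ratio rule of
  its conditional least-squares subproblem (updating $A$ with $S,Y$ fixed is
  a standard non-negative least-squares step for $X \approx A(SY)$, and
  analogously for $Y$ and $S$). Every step provably does not increase the
  objective, so the recorded trajectory is non-increasing; a validity check
  on the fitted object enforces this at a relative tolerance of $10^{-9}$
  (with an absolute guard of $10^{-12}\max_t \mathrm{obj}_t$ for steps at
  machine zero). After each sweep, column scales of $A$ and row scales of
  $Y$ are absorbed into $S$ — an exactly objective-neutral renormalization.
* **Restarts.** `n_restarts` (default 10) seeded restarts explore different
  co-cluster configurations; the lowest final objective wins. Because all
  restarts live in the same constraint class, their objectives are directly
  comparable.
* **Numerical guards.** Ratio denominators carry an additive
  $\varepsilon = 10^{-12}$. Within-support entries are clamped at
  $10^{-10}$: after per-feature min–max rescaling the lowest-valued patient
  block can be exactly zero in every column, and without the clamp its
  memberships would decay to an untyped all-zero row.

We experimented with the alternative of folding orthogonality into the
update ratios (Lagrangian-style multiplicative rules) and with unconstrained
dense factors. The former visibly increases the plain objective along the
way (it descends a penalized surrogate), the latter converges to
non-indicator global optima in which the row-maximum labels mix clusters —
the unpenalized objective does not identify the co-clustering. The
locked-support scheme gives monotone descent, exact orthogonality and
recoverable labels simultaneously, at the price that soft cluster
memberships are only explored across restarts, not within a run. One
consequence worth knowing: the patient partition usually coincides with the
best k-means partition of the *rescaled* matrix, and the method's value over
plain k-means lies in the meta-features $M = AS$, which carry the
block-profile structure that plain cluster labels discard.

**Rescaling.** Radiomic features (skewness, cluster shade, ...) can be
negative, while the factor model requires a non-negative $X$. Each feature
is affinely mapped to $[0, 1]$; constant features map to zeros. The affine
parameters are stored so held-out patients can be mapped (and clamped) onto
the training scale.

**Fold-honest projection.** Inside cross-validation the factorization is
refit on each training fold; held-out patients are projected by non-negative
least squares of their (rescaled) feature rows against the fixed $SY$,
giving membership rows $a$ and meta-features $aS$. Factorizing once on all
data before CV would leak the held-out patients' feature structure into the
transform. A naive mode (`fold_honest = FALSE` in `sweepKf`) is available
for comparison.

## Survival machinery

* **Cox** (`survival::coxph`, Efron ties — survival times are recorded in
  months, so ties are expected). Hard non-convergence is an error; infinite
  coefficient warnings (separation, which cluster-structured meta-features
  can produce in small folds) are reported and flagged but the capped fit is
  kept.
* **Lasso-Cox** (`glmnet`): penalty chosen by inner 3-fold cross-validated
  partial likelihood on event-stratified folds. The default is the
  one-standard-error rule — the sparsest penalty within one SE of the best —
  the conventional choice when the penalty serves feature selection;
  `rule = "min"` gives the likelihood-optimal penalty.
* **Random survival forest** (`ranger`): log-rank splitting, 500 trees,
  minimum terminal node 5, seeded and single-threaded for reproducibility;
  the risk score is the ensemble cumulative hazard summed over the unique
  event times.
* **Concordance** (`survival::concordance`): Harrell's C with tied risks
  counting 1/2. At tied observed times an event–censoring pair is comparable
  (the censored patient survived at least as long); an event–event tie is
  not. The test suite pins this convention against a brute-force pair
  enumeration oracle.
* **Horizon AUC.** The discrimination endpoint is cumulative/dynamic AUC at
  a 36-month horizon (near the cohort-scale mean survival), with
  inverse-probability-of-censoring weights from the Kaplan–Meier estimator
  of the censoring law: cases ($T \le t$, event) weighted by $1/G(T^-)$,
  controls ($T > t$) by $1/G(t)$. Without censoring this reduces exactly to
  the plain binary AUC. A complete-case variant (`ipcw = FALSE`) drops
  patients censored before the horizon. The horizon and the censoring
  handling are package decisions: there is no single standard for ROC
  analysis of censored outcomes, so the endpoint must be pinned down
  explicitly.

**Protocol constants.** Train/validation split 7:3 by
`round(n * 0.7)` (154 patients give 108/46), event-stratified; repeated
cross-validation 3-fold; $K_s$ fixed at 3 with $K_f$ swept over 2..10;
nested selection with 5 outer and 3 inner folds. All of these are defaults
and arguments, not constants in code.

## The synthetic cohort generator

`simulateCohort()` draws, under one master seed expanded into named
sub-streams (so adding a component never perturbs another):

* **Features.** $X = A^* B Y^* + D + \varepsilon$: indicator matrices of
  balanced latent patient ($K_s = 3$) and feature ($K_f = 9$) groups; a
  block-mean matrix $B$ built as an additive grid plus a doubly centered
  random component, so pairwise row-mean and column-mean gaps equal
  `block_mean_separation` exactly; per-(group, feature) offsets $D$ with sd
  `feature_profile_sd` that individualize features within a block; and iid
  Gaussian noise. Defaults `block_mean_separation = 1`, `noise_sd = 0.8`,
  `feature_profile_sd = 0.9` were fixed once so that same-block features
  correlate around 0.7 (below the PET pruning threshold, as surviving
  radiomic feature families do) and different blocks around 0.5; with 150
  PET and 50 CT columns the pruning then retains a PET-heavy subset
  (~110/200), mirroring how real selections behave. Setting
  `feature_profile_sd = 0` and `noise_sd = 0` recovers exact equal-valued
  blocks (exactly $K_s K_f$ distinct values), the regime used by the
  recovery tests.
* **Survival.** Exponential with rate
  `hazard_multipliers[g] / baseline_scale_months`; defaults $(1, 2, 4)$ and
  50 months give low/medium/high-risk groups with a hazard ratio of 4
  between the extremes, median ~35 months in the low-risk group and
  cohort-level follow-up spread comparable to a 2–60 month registry window.
  The exponential law is a deliberate choice: closed-form means and medians
  ($\ln 2 \cdot \text{scale} / \text{multiplier}$) make the generator
  testable. Censoring is independent uniform on $[0, c_{\max}]$ with
  $c_{\max}$ solved numerically so the *expected* censored fraction equals
  `censoring_rate_target` (default 0.3); at $n = 154$ the realized fraction
  scatters around the target with sd about 0.04.
* **Clinical covariates.** Age, BMI, SUV metrics and blood counts are drawn
  with cohort-scale moments (age $54.9 \pm 13.0$, BMI $22.4 \pm 1.4$, WBC
  $7.2 \pm 2.7$, NC $5.2 \pm 2.5$, LC $1.5 \pm 0.5$, PLT $263 \pm 139$;
  counts log-normal). NLR is NC/LC *by construction*. Prognostic signal is
  planted in two places and two only: T stage (cumulative-logit shift
  `t_stage_shift = 0.8` per risk-group step — weak) and the neutrophil
  count (log-mean shift `inflammation_shift = 0.35` per step — moderate,
  and inherited by NLR). SUV metrics and the remaining counts are noise.
  The three tiers of the feature-combination analysis (clinical+SUV;
  +inflammatory; +meta-features) therefore carry increasing signal, which is
  a *generator design choice*, not an estimate: the strength of the
  true clinical–outcome link in any given cohort is unknown, so these knobs
  were set once to plausible epidemiological effect sizes and are exposed
  in `cohortConfig()`.
* **Rater replicate.** The second-reader table is $X$ plus column-wise
  Gaussian disagreement with per-feature-block sd. Because only the
  replicate carries the disagreement, the population ICC(2,1) is
  $\sigma^2_X / (\sigma^2_X + \mathrm{sd}_b^2 / 2)$ — the ANOVA splits the
  one-sided noise between the rater effect and the residual. The default
  sd 0.3 keeps all blocks reproducible (ICC $\approx$ 0.99); tests exercise
  mixed-reproducibility designs explicitly.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: feature distributions are Gaussian blocks, not the
skewed, heavy-tailed texture statistics of real radiomics; the
patient-group structure is exactly discrete rather than a continuum; hazards
are exponential and depend on the latent group only; censoring is
uninformative by construction; scanner/protocol batch effects are absent.
Two knock-on consequences show up in results: predictive signal saturates at
small $K_f$ (the hazard depends on three groups only, so the summed
concordance curve over $K_f$ is nearly flat rather than peaked), and nested
dimension selection legitimately favors parsimonious values.

## Numerical and design choices

* Strict ">" for the ICC threshold, ">=" for the correlation thresholds,
  matching the protocol's wording.
* Redundancy pruning drops, at each step, the feature (among those in a
  violating pair) with the largest mean absolute correlation to the
  remaining same-modality features; ties break to the later column index.
  Pruning is idempotent. Zero-variance features are removed first with a
  message (Pearson is undefined for them).
* Row/column cluster labels take the factor row/column maximum with ties to
  the lowest index.
* Pairwise log-rank p-values are reported unadjusted by default (the
  stratification contrasts of interest are few and reported raw in this
  literature); Bonferroni is one argument away.
* Event/censoring ties at the same time: events precede censorings.
* Patient order is canonicalized by the feature-table id order at ingestion;
  fold assignment depends only on seeds, not input row order.
* All stochastic stages consume named sub-seeds derived from one master
  seed (`subSeed(seed, tag)`), so components are independently reproducible.

## Problem sizes used by the shipped checks

The package's own validation runs at deliberately modest sizes chosen to
exercise every claim while staying laptop-friendly: recovery fixtures at
$60 \times 40$ to $150 \times 60$; cohort-level comparisons at $n = 154$
with 80–200 features, 3-fold cross-validation with 10–20 repetitions, and
20-seed replications for all qualitative claims. `comparisonConfig()`
defaults to `cv_reps = 20` and `sweep_reps = 5`; raising `cv_reps` to 100
reproduces the full repeated-CV protocol unchanged.

## Known limitations

* The factorization's patient partition is anchored to k-means restarts;
  pathological geometries where k-means systematically fails (elongated or
  nested clusters) will defeat it.
* Orthogonality is achieved by disjoint supports, so genuinely overlapping
  patient memberships are represented only through the magnitude of a
  single membership coefficient.
* The IPCW AUC assumes censoring independent of covariates; informative
  censoring biases it.
* Lasso-Cox under the one-SE rule can shrink every coefficient to zero on
  weak-signal folds; such constant-risk models are flagged and score a
  concordance of 1/2 rather than being dropped.
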