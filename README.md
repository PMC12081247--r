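# triSurv

Censored survival prognosis from high-dimensional radiomic feature tables by
**two-way co-clustering**: reproducibility and redundancy feature selection,
orthogonality-constrained non-negative matrix tri-factorization that clusters
patients and features simultaneously, Kaplan–Meier / log-rank risk
stratification, and Cox / Lasso-Cox / random-survival-forest prediction under
repeated cross-validation — together with K-means, PCA and clinical-covariate
baselines and a synthetic cohort generator that makes the whole pipeline
testable end to end.

The package is aimed at biostatisticians and imaging researchers who model
overall survival from PET/CT radiomics at typical single-institution cohort
sizes (n ≈ 100–200, hundreds of candidate features).

## The model

Given a patients-by-features matrix `X` (rescaled per feature to [0, 1]), the
core decomposition is

    min_{A,S,Y ≥ 0}  ‖X − A S Y‖²_F   s.t.  AᵀA = I,  Y Yᵀ = I

* `A` (N × K_s) — patient sub-cluster memberships (risk groups),
* `Y` (K_f × F) — feature sub-cluster memberships (feature families),
* `S` (K_s × K_f) — scales and group–family interactions,
* `M = A S` (N × K_f) — the **meta-features** used by the survival models.

Non-negative orthogonal factors are cluster indicators up to scale; the
optimizer takes this literally (clustering-seeded restarts with disjoint
supports, provably monotone multiplicative magnitude updates). The methods
vignette (`vignettes/triSurv-methods.Rmd`) derives the updates, documents
every tunable and states what the synthetic generator does and does not
emulate.

Selection defaults follow the standard radiomics protocol: keep features with
two-reader ICC(2,1) > 0.75, then greedily prune within-modality Pearson
redundancy at |r| ≥ 0.76 (PET) / 0.40 (CT). Model protocol defaults: K_s = 3,
K_f swept over 2–10; 3-fold cross-validation (repeatable up to 100×); 7:3
event-stratified train/validation split; random survival forest with 500
trees and minimum leaf 5; 36-month IPCW cumulative/dynamic AUC.

## Worked example

```r
library(triSurv)

# a synthetic cohort with 3 latent risk groups (hazard ratio 4 between the
# extremes), 150 PET + 50 CT features in 9 latent families, 30% censoring
cohort <- simulateCohort(cohortConfig(seed = 1))
cohort
#> RadiomicCohort with 154 patients and 200 features
#>   modality: 150 PET, 50 CT
#>   rater replicate: yes
#>   events: 111/154; follow-up 0.0-74.8 months
#>   generator truth labels present

sel <- selectFeatures(cohort)          # ICC filter + correlation pruning
sel
#> SelectionReport: 200 reproducible features; 93 removed as redundant; 107 retained

X   <- featureValues(cohort)[, selectedFeatures(sel)]
fit <- fitTriFactor(X, k_s = 3, k_f = 9, seed = 1)
fit
#> TriFactorFit: 154 patients x 107 features, k_s = 3, k_f = 9
#>   final objective 384.917 after 4 iterations (converged), 10 restart(s)
#>   orthogonality residuals: ||A'A - I||_F = 3.85e-16, ||YY' - I||_F = 4.44e-16

sv <- survivalData(cohort)
logrankTest(sv$time_months, sv$event, patientClusters(fit))
#> $chi_square  34.80
#> $df          2
#> $p_value     2.8e-08

cv <- repeatedKfoldCindex("cox", metaFeatures(fit),
                          sv$time_months, sv$event, reps = 20, seed = 1)
cv
#> CVSummary: 3-fold x 20 reps, C-index 0.639 +/- 0.049
```

The stratification is decisive (log-rank p ≈ 3×10⁻⁸ across the three fitted
groups) and the meta-feature Cox model reaches a cross-validated concordance
of 0.64 — essentially the ceiling of the generating survival law: with
exponential hazards at multipliers (1, 2, 4), even the true group label only
attains C ≈ 0.64, so the pipeline is recovering close to all of the signal
that exists.

`runFullComparison(cohort, comparisonConfig(seed = 1))` executes the whole
protocol — selection, stratification at K_s = 2 and 3 with pairwise log-rank
tables, repeated-CV comparison of meta-features vs PCA vs clinical
covariates for all three model families, the K_f sweep with the summed
concordance curve, and the three-tier AUC analysis — and `writeReport()`
serializes it deterministically.

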