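#' Configuration for the synthetic cohort generator
#'
#' Defines the study conditions the generator emulates: a biclustered
#' patients-by-features matrix with \code{k_s} latent patient groups and
#' \code{k_f} latent feature groups plus Gaussian noise, a second-rater
#' replicate with controlled per-feature reproducibility, clinical covariates
#' with the neutrophil-to-lymphocyte ratio defined as NC/LC, and exponential
#' survival whose hazard depends on the latent patient group, under
#' independent uniform censoring calibrated to a target rate.
#'
#' @param n_patients cohort size.
#' @param n_features_pet,n_features_ct number of PET- and CT-derived feature
#'   columns (named \code{PET_f...}/\code{CT_f...}).
#' @param k_s,k_f number of latent patient and feature groups (>= 2).
#' @param block_mean_separation guaranteed gap between bicluster block row
#'   means and between block column means (signal scale).
#' @param noise_sd standard deviation of the i.i.d. Gaussian measurement
#'   noise added to the block structure.
#' @param feature_profile_sd sd of the per-(feature, patient-group) offset
#'   that individualizes features within a feature block. Zero gives exact
#'   equal-valued blocks (every same-block feature a duplicate up to noise);
#'   the positive default makes same-block features moderately correlated,
#'   as radiomic feature families are, so the redundancy pruning stage has
#'   realistic work to do.
#' @param hazard_multipliers strictly increasing positive vector, length
#'   \code{k_s}; the exponential hazard of group g is
#'   \code{hazard_multipliers[g] / baseline_scale_months}.
#' @param baseline_scale_months mean survival (months) of a group with
#'   multiplier 1.
#' @param censoring_rate_target expected fraction censored, in [0, 0.9];
#'   0 disables censoring.
#' @param rater2_noise_sd_per_block per-feature-group sd of the Gaussian
#'   disagreement between the two raters (length \code{k_f}).
#' @param t_stage_shift strength of the ordinal association between T stage
#'   and the latent risk group (cumulative-logit shift per group step).
#' @param inflammation_shift shift of the neutrophil count's log-mean per
#'   latent group step (plants prognostic signal in the inflammatory tier).
#' @param seed master seed; every stochastic component draws from a named
#'   sub-stream derived from it.
#' @return a validated list of class \code{"CohortConfig"}.
#' @export
cohortConfig <- function(n_patients = 154,
                         n_features_pet = 150,
                         n_features_ct = 50,
                         k_s = 3,
                         k_f = 9,
                         block_mean_separation = 1,
                         noise_sd = 0.8,
                         feature_profile_sd = 0.9,
                         hazard_multipliers = c(1, 2, 4),
                         baseline_scale_months = 50,
                         censoring_rate_target = 0.3,
                         rater2_noise_sd_per_block = rep(0.3, k_f),
                         t_stage_shift = 0.8,
                         inflammation_shift = 0.35,
                         seed = 1L) {
  cfg <- list(n_patients = n_patients, n_features_pet = n_features_pet,
              n_features_ct = n_features_ct, k_s = k_s, k_f = k_f,
              block_mean_separation = block_mean_separation,
              noise_sd = noise_sd, feature_profile_sd = feature_profile_sd,
              hazard_multipliers = hazard_multipliers,
              baseline_scale_months = baseline_scale_months,
              censoring_rate_target = censoring_rate_target,
              rater2_noise_sd_per_block = rater2_noise_sd_per_block,
              t_stage_shift = t_stage_shift,
              inflammation_shift = inflammation_shift,
              seed = as.integer(seed))
  validateCohortConfig(cfg)
  class(cfg) <- "CohortConfig"
  cfg
}

validateCohortConfig <- function(cfg) {
  with(cfg, {
    stopifnot(n_patients >= 1, n_features_pet >= 0, n_features_ct >= 0,
              n_features_pet + n_features_ct >= 1,
              k_s >= 2, k_f >= 2,
              block_mean_separation > 0, noise_sd >= 0,
              feature_profile_sd >= 0, baseline_scale_months > 0)
    if (k_s > n_patients)
      stop("k_s exceeds the number of patients")
    if (k_f > n_features_pet + n_features_ct)
      stop("k_f exceeds the number of features")
    if (censoring_rate_target < 0 || censoring_rate_target > 0.9)
      stop("censoring_rate_target must lie in [0, 0.9]")
    if (length(hazard_multipliers) != k_s)
      stop("hazard_multipliers must have length k_s")
    if (any(hazard_multipliers <= 0) || any(diff(hazard_multipliers) <= 0))
      stop("hazard_multipliers must be positive and strictly increasing")
    if (length(rater2_noise_sd_per_block) != k_f)
      stop("rater2_noise_sd_per_block must have length k_f")
    if (any(rater2_noise_sd_per_block < 0))
      stop("rater noise sds must be non-negative")
  })
  invisible(TRUE)
}

# Block-mean matrix with pairwise row-mean and column-mean gaps exactly equal
# to `sep`: an additive grid plus a doubly centered random component. The
# centered component perturbs individual block means without moving any row
# or column mean; its amplitude (1 sep) breaks rank degeneracy and keeps the
# patient-group profiles of different feature blocks from being collinear,
# so between-block feature correlations stay moderate.
blockMeanMatrix <- function(k_s, k_f, sep) {
  E <- matrix(runif(k_s * k_f, -1, 1), k_s, k_f)
  E <- sweep(E, 1, rowMeans(E))
  E <- sweep(E, 2, colMeans(E))
  sep * outer(seq_len(k_s) - 1, seq_len(k_f) - 1, "+") + sep * E + 2 * sep
}

# Maximum of the uniform censoring law solved so the expected censored
# fraction over the exponential mixture equals the target.
calibrateCensoringMax <- function(rates, props, target) {
  pcens <- function(cmax)
    sum(props * (1 - exp(-rates * cmax)) / (rates * cmax)) - target
  uniroot(pcens, lower = 1e-9, upper = 1e9, tol = 1e-10)$root
}

#' Generate a synthetic radiomic cohort
#'
#' Builds \code{X = A* B Y* + noise} where \code{A*}/\code{Y*} are indicator
#' matrices of the latent patient/feature groups and \code{B} is a block-mean
#' matrix with guaranteed mean separation; draws exponential survival with
#' group-dependent hazard, uniform censoring calibrated to the target rate,
#' clinical covariates (with NLR = NC/LC by construction), and a second-rater
#' replicate with block-specific disagreement noise.
#'
#' @param config a \code{\link{cohortConfig}}.
#' @return a \linkS4class{RadiomicCohort}; the generator configuration is
#'   stored in \code{metadata(cohort)$config}.
#' @export
simulateCohort <- function(config = cohortConfig()) {
  validateCohortConfig(config)
  n <- config$n_patients
  n_pet <- config$n_features_pet
  n_ct <- config$n_features_ct
  F_all <- n_pet + n_ct
  k_s <- config$k_s; k_f <- config$k_f
  seed <- config$seed

  patient_label <- withSeed(subSeed(seed, "patient_labels"),
                            balancedLabels(n, k_s))
  feature_label <- withSeed(subSeed(seed, "feature_labels"),
                            balancedLabels(F_all, k_f))
  B <- withSeed(subSeed(seed, "block_means"),
                blockMeanMatrix(k_s, k_f, config$block_mean_separation))
  X <- B[patient_label, feature_label]
  if (config$feature_profile_sd > 0) {
    # per-(patient-group, feature) offsets: features of a block share the
    # block profile but are not exact duplicates of each other
    D <- withSeed(subSeed(seed, "feature_profiles"),
                  matrix(rnorm(k_s * F_all, 0, config$feature_profile_sd),
                         k_s, F_all))
    X <- X + D[patient_label, , drop = FALSE]
  }
  if (config$noise_sd > 0)
    X <- X + withSeed(subSeed(seed, "noise"),
                      matrix(rnorm(n * F_all, 0, config$noise_sd), n, F_all))
  feature_names <- c(sprintf("PET_f%03d", seq_len(n_pet)),
                     if (n_ct > 0) sprintf("CT_f%03d", seq_len(n_ct)))
  colnames(X) <- feature_names
  rownames(X) <- sprintf("P%03d", seq_len(n))

  rater2 <- simulateRaterReplicate(X, feature_label,
                                   config$rater2_noise_sd_per_block,
                                   seed = subSeed(seed, "rater2"))

  # survival: exponential with group hazard; uniform censoring
  rates <- config$hazard_multipliers[patient_label] / config$baseline_scale_months
  t_true <- withSeed(subSeed(seed, "survival"), rexp(n, rate = rates))
  if (config$censoring_rate_target > 0) {
    props <- tabulate(patient_label, k_s) / n
    cmax <- calibrateCensoringMax(
      config$hazard_multipliers / config$baseline_scale_months,
      props, config$censoring_rate_target)
    cens <- withSeed(subSeed(seed, "censoring"), runif(n, 0, cmax))
    time <- pmin(t_true, cens)
    event <- as.numeric(t_true <= cens)
  } else {
    time <- t_true
    event <- rep(1, n)
  }
  time <- pmax(time, 1e-6)

  clinical <- withSeed(subSeed(seed, "clinical"),
                       simulateClinical(n, patient_label, k_s,
                                        config$t_stage_shift,
                                        config$inflammation_shift))

  RadiomicCohort(features = X, clinical = clinical,
                 time_months = time, event = event, rater2 = rater2,
                 true_patient_label = patient_label,
                 true_feature_label = feature_label,
                 metadata = list(config = unclass(config)))
}

# Clinical covariates with cohort-level moments matching a mid-sized
# chemoradiotherapy cervical-cancer cohort; the latent risk group leaks
# weakly into T stage and moderately into the neutrophil count (hence NLR),
# so clinical-only models carry some, but less, prognostic signal than the
# radiomic features.
simulateClinical <- function(n, group, k_s, t_stage_shift, inflammation_shift) {
  age <- pmin(pmax(rnorm(n, 54.88, 12.99), 18), 90)
  bmi <- rnorm(n, 22.42, 1.41)
  g_centered <- group - (k_s + 1) / 2

  wbc <- do.call(stats::rlnorm, c(list(n = n), lognormalParams(7.20, 2.74)))
  ncp <- lognormalParams(5.16, 2.47)
  nc <- stats::rlnorm(n, ncp$meanlog + inflammation_shift * g_centered, ncp$sdlog)
  lcp <- lognormalParams(1.53, 0.53)
  lc <- stats::rlnorm(n, lcp$meanlog, lcp$sdlog)
  plt <- do.call(stats::rlnorm, c(list(n = n), lognormalParams(263.44, 138.87)))

  # ordinal T stage via cumulative logit around cohort proportions 38/39/23
  base_cut <- stats::qlogis(cumsum(c(0.383, 0.390))) # thresholds for T2|T3, T3|T4
  z <- stats::rlogis(n) + t_stage_shift * g_centered
  t_stage <- 2L + (z > base_cut[1]) + (z > base_cut[2])

  suv_max <- do.call(stats::rlnorm, c(list(n = n), lognormalParams(15.01, 6.67)))
  suv_mean <- suv_max * runif(n, 0.5, 0.7)
  suv_peak <- suv_max * runif(n, 0.75, 0.95)

  data.frame(
    age = age, bmi = bmi, t_stage = t_stage,
    suv_max = suv_max, suv_mean = suv_mean, suv_peak = suv_peak,
    wbc = wbc, nc = nc, lc = lc, plt = plt, nlr = nc / lc,
    lymph_node_positive = rbinom(n, 1, 0.8182)
  )
}

#' Generate a second-rater replicate with controlled reproducibility
#'
#' Adds column-wise Gaussian disagreement noise whose sd is taken from the
#' feature's latent group. Because the disagreement is carried by the
#' replicate only (the reference table is noise-free), the population
#' ICC(2,1) of feature j is \code{var(X[, j]) / (var(X[, j]) + sd_b^2 / 2)}:
#' the two-way ANOVA splits the one-sided disagreement evenly between the
#' rater effect and the residual.
#'
#' @param X patients-by-features matrix (first rater).
#' @param feature_labels integer feature-group labels in 1..B.
#' @param noise_sd_per_block non-negative sd per feature group.
#' @param seed RNG seed.
#' @return matrix of the same shape as \code{X}.
#' @export
simulateRaterReplicate <- function(X, feature_labels, noise_sd_per_block,
                                   seed = 1L) {
  X <- as.matrix(X)
  if (length(feature_labels) != ncol(X))
    stop("feature_labels must have one entry per feature column")
  if (max(feature_labels) > length(noise_sd_per_block))
    stop("noise_sd_per_block must cover every feature block")
  if (any(noise_sd_per_block < 0))
    stop("rater noise sds must be non-negative")
  sds <- noise_sd_per_block[feature_labels]
  noise <- withSeed(seed, {
    matrix(rnorm(length(X)), nrow(X), ncol(X)) %*% diag(sds, ncol(X))
  })
  out <- X + noise
  dimnames(out) <- dimnames(X)
  out
}
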