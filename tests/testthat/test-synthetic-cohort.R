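test_that("generator config validation rejects impossible designs", {
  expect_error(cohortConfig(n_patients = 2, k_s = 3), "k_s")
  expect_error(cohortConfig(n_features_pet = 2, n_features_ct = 1, k_f = 9),
               "k_f")
  expect_error(cohortConfig(censoring_rate_target = 0.95), "censoring")
  expect_error(cohortConfig(hazard_multipliers = c(2, 1, 4)), "increasing")
  expect_error(cohortConfig(rater2_noise_sd_per_block = rep(-1, 9)),
               "non-negative")
})

test_that("identical config reproduces the cohort bit-for-bit", {
  cfg <- cohortConfig(n_patients = 40, n_features_pet = 20,
                      n_features_ct = 10, k_f = 3, seed = 11)
  a <- simulateCohort(cfg)
  b <- simulateCohort(cfg)
  expect_identical(featureValues(a), featureValues(b))
  expect_identical(raterValues(a), raterValues(b))
  expect_identical(survivalData(a), survivalData(b))
  expect_identical(clinicalTable(a), clinicalTable(b))
  d <- simulateCohort(cohortConfig(n_patients = 40, n_features_pet = 20,
                                   n_features_ct = 10, k_f = 3, seed = 12))
  expect_false(identical(featureValues(a), featureValues(d)))
})

test_that("noiseless block matrix has exactly k_s * k_f distinct values", {
  for (s in c(1, 7)) {
    cfg <- cohortConfig(n_patients = 30, n_features_pet = 12,
                        n_features_ct = 6, k_s = 3, k_f = 4,
                        noise_sd = 0, feature_profile_sd = 0, seed = s)
    co <- simulateCohort(cfg)
    expect_equal(length(unique(as.vector(featureValues(co)))), 12)
  }
})

test_that("cohort components are aligned and labels within range", {
  co <- smallCohort(seed = 3)
  X <- featureValues(co)
  expect_equal(dim(raterValues(co)), dim(X))
  expect_equal(nrow(clinicalTable(co)), nrow(X))
  expect_equal(nrow(survivalData(co)), nrow(X))
  expect_true(all(truePatientLabels(co) %in% 1:3))
  expect_true(all(trueFeatureLabels(co) %in% 1:4))
  expect_equal(length(trueFeatureLabels(co)), ncol(X))
  expect_equal(featureModality(co), rep(c("PET", "CT"), c(40, 20)))
})

test_that("NLR identity holds on every generated row", {
  co <- smallCohort(seed = 5)
  cl <- clinicalTable(co)
  expect_true(all(abs(cl$nlr - cl$nc / cl$lc) < 1e-12))
  expect_true(all(cl$lc > 0))
  expect_true(all(cl$wbc > 0 & cl$nc > 0 & cl$plt > 0))
  expect_true(all(cl$t_stage %in% 2:4))
})

test_that("survival law: per-cluster means follow the hazard multipliers", {
  cfg <- cohortConfig(n_patients = 12000, n_features_pet = 4,
                      n_features_ct = 2, k_s = 3, k_f = 2,
                      hazard_multipliers = c(1, 2, 4),
                      rater2_noise_sd_per_block = rep(0, 2),
                      censoring_rate_target = 0, seed = 2)
  co <- simulateCohort(cfg)
  sv <- survivalData(co)
  g <- truePatientLabels(co)
  m <- tapply(sv$time_months, g, mean)
  # exponential expectation: baseline / multiplier
  expect_equal(unname(m[1] / m[2]), 2, tolerance = 0.05)
  expect_equal(unname(m[1] / m[3]), 4, tolerance = 0.05)
  expect_true(all(sv$event == 1))
})

test_that("Kaplan-Meier median per cluster matches the exponential law", {
  cfg <- cohortConfig(n_patients = 15000, n_features_pet = 4,
                      n_features_ct = 2, k_s = 3, k_f = 2,
                      hazard_multipliers = c(1, 2, 4),
                      rater2_noise_sd_per_block = rep(0, 2),
                      baseline_scale_months = 50,
                      censoring_rate_target = 0, seed = 8)
  co <- simulateCohort(cfg)
  sv <- survivalData(co)
  g <- truePatientLabels(co)
  for (k in 1:3) {
    med <- kmMedian(sv$time_months[g == k], sv$event[g == k])
    theo <- log(2) * 50 / c(1, 2, 4)[k]
    expect_equal(med, theo, tolerance = 0.1)
  }
})

test_that("realized censoring fraction tracks the target over 20 seeds", {
  for (target in c(0.2, 0.4)) {
    fr <- vapply(1:20, function(s) {
      cfg <- cohortConfig(n_patients = 154, n_features_pet = 4,
                          n_features_ct = 2, k_f = 2,
                          rater2_noise_sd_per_block = rep(0, 2),
                          censoring_rate_target = target, seed = s)
      sv <- survivalData(simulateCohort(cfg))
      mean(sv$event == 0)
    }, numeric(1))
    # the calibration is in expectation: the 20-seed aggregate must sit
    # within 0.1 of the target and no single cohort may stray far
    expect_lte(abs(mean(fr) - target), 0.1)
    expect_true(all(abs(fr - target) <= 0.2))
  }
})

test_that("rater replicate controls the expected ICC", {
  # zero rater noise: identical replicate, ICC exactly 1
  X <- matrix(rnorm(200), 50, 4,
              dimnames = list(NULL, sprintf("PET_f%d", 1:4)))
  R0 <- simulateRaterReplicate(X, rep(1:2, each = 2), c(0, 0), seed = 1)
  expect_identical(R0, X)
  expect_equal(icc21(X[, 1], R0[, 1]), 1.0)

  # one-sided disagreement with sd = sqrt(2): population ICC(2,1) is
  # var / (var + sd^2 / 2) = 0.5; empirical values near 0.5 at n = 500
  set.seed(42)
  Xs <- matrix(rnorm(500 * 6, sd = 1), 500, 6,
               dimnames = list(NULL, sprintf("PET_f%d", 1:6)))
  R <- simulateRaterReplicate(Xs, rep(1, 6), sqrt(2), seed = 9)
  iccs <- vapply(1:6, function(j) icc21(Xs[, j], R[, j]), numeric(1))
  expect_true(all(iccs > 0.40 & iccs < 0.60))

  expect_error(simulateRaterReplicate(Xs, rep(1, 6), -0.1), "non-negative")
})

test_that("ICC filter separates reproducible from noisy feature blocks", {
  # block sds chosen for population ICCs 0.9 and 0.3 under the one-sided
  # replicate law: sd_b = sqrt(2 (1/icc - 1))
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    X <- matrix(rnorm(500 * 20), 500, 20,
                dimnames = list(NULL, sprintf("PET_f%02d", 1:20)))
    fl <- rep(1:2, each = 10)
    R <- simulateRaterReplicate(X, fl,
                                sqrt(2 * (1 / c(0.9, 0.3) - 1)),
                                seed = s + 100)
    rep <- filterByICC(X, R, threshold = 0.75)
    kept <- colnames(X) %in% rep@kept_after_icc
    c(sens = mean(kept[fl == 1]), spec = mean(!kept[fl == 2]))
  }, numeric(2))
  expect_gte(mean(hits["sens", ]), 0.95)
  expect_gte(mean(hits["spec", ]), 0.95)
})

test_that("cohort round-trips bit-exactly through write/read", {
  co <- simulateCohort(cohortConfig(n_patients = 20, n_features_pet = 6,
                                    n_features_ct = 4, k_f = 2, seed = 4))
  dir <- withr::local_tempdir()
  manifest <- writeCohort(co, dir, overwrite = TRUE)
  expect_length(manifest, 6)
  expect_true(all(file.exists(manifest)))
  back <- readCohort(dir)
  expect_identical(featureValues(back), featureValues(co))
  expect_identical(raterValues(back), raterValues(co))
  expect_equal(survivalData(back), survivalData(co))
  expect_identical(truePatientLabels(back), truePatientLabels(co))
  expect_identical(trueFeatureLabels(back), trueFeatureLabels(co))
  # refuses to clobber without the flag
  expect_error(writeCohort(co, dir), "overwrite")
})
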