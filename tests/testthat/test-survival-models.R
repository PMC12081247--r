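# shared small fixture: cluster-linked survival with a strong binary marker
riskFixture <- function(n, seed, hr = 10) {
  withSeed(seed <- seed, NULL)
  set.seed(seed)
  x <- rbinom(n, 1, 0.5)
  time <- rexp(n, rate = 0.02 * hr^x)
  cens <- runif(n, 0, quantile(time, 0.9) * 2)
  list(x = x, time = pmin(time, cens), event = as.numeric(time <= cens))
}

test_that("train/validation split honors size and event balance", {
  set.seed(3)
  ev <- rbinom(154, 1, 0.6)
  sp <- splitTrainValidation(154, 0.7, strata = ev, seed = 1)
  expect_length(sp$train, 108)
  expect_length(sp$validation, 46)
  expect_setequal(c(sp$train, sp$validation), 1:154)
  p_tr <- mean(ev[sp$train]); p_va <- mean(ev[sp$validation])
  expect_lte(abs(p_tr - p_va), 1 / length(sp$validation) + 1e-9)

  # balanced toy: exact 5/5 with events 50/50
  ev10 <- rep(c(0, 1), 5)
  sp10 <- splitTrainValidation(10, 0.5, strata = ev10, seed = 2)
  expect_length(sp10$train, 5)
  expect_equal(sum(ev10[sp10$train]), 2.5, tolerance = 0.5)

  expect_identical(splitTrainValidation(50, 0.7, strata = NULL, seed = 9),
                   splitTrainValidation(50, 0.7, strata = NULL, seed = 9))
  expect_error(splitTrainValidation(10, 1.2), "between 0 and 1")
  expect_error(splitTrainValidation(10, 0.5, strata = c(rep(0, 9), 1)),
               "stratum")
})

test_that("Cox fit recovers signal direction and rejects degenerate input", {
  fx <- riskFixture(2000, seed = 11, hr = 4)
  m <- fitCoxModel(cbind(marker = fx$x), fx$time, fx$event)
  beta <- coef(m@fit)
  expect_gt(unname(beta["marker"]), 0)

  # null feature: small coefficient, non-significant Wald test mostly
  nulls <- vapply(1:20, function(s) {
    set.seed(s + 500)
    z <- rnorm(2000)
    mm <- fitCoxModel(cbind(z = z), fx$time, fx$event)
    summary(mm@fit)$coefficients[, "Pr(>|z|)"]
  }, numeric(1))
  expect_gte(sum(nulls > 0.05), 17)

  expect_error(fitCoxModel(cbind(x = c(1, 2)), c(3, 4), c(0, 0)), "events")
  expect_error(fitCoxModel(cbind(x = rep(1, 10)), 1:10, rep(1, 10)),
               "constant|patients")
})

test_that("risk predictions are higher for higher-hazard patients", {
  fx <- riskFixture(400, seed = 13, hr = 8)
  X <- cbind(marker = fx$x)
  for (kind in c("cox", "cox_lasso", "rsf")) {
    m <- fitRiskModel(kind, X, fx$time, fx$event, seed = 7)
    r <- predictRisk(m, X)
    expect_gt(mean(r[fx$x == 1]), mean(r[fx$x == 0]))
  }
})

test_that("lasso limits: infinite penalty zeros, zero penalty matches Cox", {
  set.seed(17)
  n <- 300
  X <- cbind(matrix(rnorm(n * 3), n, 3))
  colnames(X) <- paste0("f", 1:3)
  lp <- 0.8 * X[, 1] - 0.5 * X[, 2]
  time <- rexp(n, rate = 0.05 * exp(lp)) + runif(n, 0, 1e-4)
  event <- rep(1, n)

  m_inf <- suppressWarnings(fitCoxLasso(X, time, event, lambda = 1e4))
  expect_true(all(m_inf@meta$beta == 0))
  expect_true(m_inf@meta$constant_risk)

  m0 <- fitCoxLasso(X, time, event, lambda = 0)
  m_cox <- fitCoxModel(X, time, event)
  expect_equal(unname(m0@meta$beta), unname(coef(m_cox@fit)),
               tolerance = 1e-4)
})

test_that("lasso recovers sparsity with noise features", {
  hits <- 0
  for (s in 1:20) {
    set.seed(s)
    n <- 300
    X <- cbind(signal = rnorm(n), matrix(rnorm(n * 10), n, 10))
    colnames(X) <- c("signal", paste0("noise", 1:10))
    time <- rexp(n, rate = 0.05 * exp(1.2 * X[, "signal"]))
    event <- rbinom(n, 1, 0.85)
    m <- fitCoxLasso(X, time, event, inner_folds = 3, seed = s)
    b <- setNames(m@meta$beta, m@feature_names)
    if (b["signal"] != 0 && sum(b[-1] == 0) >= 8) hits <- hits + 1
  }
  expect_gte(hits, 15)
})

test_that("random survival forest defaults, determinism and signal", {
  expect_equal(formals(fitRSF)$n_trees, 500)
  expect_equal(formals(fitRSF)$min_leaf, 5)

  fx <- riskFixture(400, seed = 19, hr = 10)
  X <- cbind(marker = fx$x)
  m1 <- fitRSF(X, fx$time, fx$event, seed = 3)
  m2 <- fitRSF(X, fx$time, fx$event, seed = 3)
  expect_identical(m1@fit$predictions, m2@fit$predictions)

  cv <- repeatedKfoldCindex("rsf", X, fx$time, fx$event, k = 3, reps = 2,
                            seed = 5)
  expect_gt(cvMean(cv), 0.7)

  expect_error(fitRSF(X, fx$time, fx$event, min_leaf = 500), "min_leaf|few")
})

test_that("concordance matches the exhaustive pair oracle", {
  # perfect inverse ranking of event times
  tm <- c(5, 4, 3, 2, 1); ev <- rep(1, 5); risk <- 1:5
  expect_equal(concordanceIndex(risk, tm, ev), 1.0)
  # constant risk: every comparable pair tied
  expect_equal(concordanceIndex(rep(2, 5), tm, ev), 0.5)
  # 5-patient toy with one censor
  tm2 <- c(2, 4, 3, 7, 5); ev2 <- c(1, 1, 0, 1, 1); r2 <- c(9, 2, 5, 1, 3)
  expect_equal(concordanceIndex(r2, tm2, ev2), oracle_cindex(r2, tm2, ev2),
               tolerance = 1e-12)

  set.seed(23)
  for (i in 1:100) {
    n <- sample(5:12, 1)
    tm <- sample(1:6, n, replace = TRUE)
    ev <- rbinom(n, 1, 0.7)
    r <- sample(1:4, n, replace = TRUE)   # ties in both risk and time
    if (sum(ev) == 0) ev[which.min(tm)] <- 1
    expect_equal(concordanceIndex(r, tm, ev), oracle_cindex(r, tm, ev),
                 tolerance = 1e-12)
  }
  expect_error(concordanceIndex(1:3, c(1, 1, 1), c(0, 0, 0)), "comparable")
})

test_that("repeated k-fold protocol: defaults, null behavior, determinism", {
  expect_equal(formals(repeatedKfoldCindex)$k, 3)
  expect_equal(formals(repeatedKfoldCindex)$reps, 100)

  # null features: concordance centred on 1/2
  set.seed(29)
  n <- 150
  X <- cbind(a = rnorm(n), b = rnorm(n))
  time <- rexp(n, 0.05); event <- rbinom(n, 1, 0.8)
  cv <- repeatedKfoldCindex("cox", X, time, event, k = 3, reps = 10, seed = 1)
  expect_lt(abs(cvMean(cv) - 0.5), 0.05)
  expect_equal(cv@mean, mean(cvFolds(cv)$cindex))
  expect_equal(cv@sd, sd(cvFolds(cv)$cindex))

  cv2 <- repeatedKfoldCindex("cox", X, time, event, k = 3, reps = 1, seed = 4)
  cv3 <- repeatedKfoldCindex("cox", X, time, event, k = 3, reps = 1, seed = 4)
  expect_identical(cvFolds(cv2), cvFolds(cv3))
})

test_that("training concordance exceeds validation concordance on average", {
  diffs <- vapply(1:20, function(s) {
    cfg <- cohortConfig(n_patients = 100, n_features_pet = 30,
                        n_features_ct = 10, k_f = 4, seed = s)
    co <- simulateCohort(cfg)
    fit <- fitTriFactor(featureValues(co), 3, 4, n_restarts = 2,
                        max_iter = 100, seed = s)
    sv <- survivalData(co)
    cv <- suppressWarnings(
      repeatedKfoldCindex("cox", metaFeatures(fit), sv$time_months,
                          sv$event, k = 3, reps = 2, seed = s))
    mean(cvFolds(cv)$cindex_train) - mean(cvFolds(cv)$cindex)
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("K_f sweep covers the grid with fold-honest refits", {
  cfg <- cohortConfig(n_patients = 90, n_features_pet = 30,
                      n_features_ct = 10, k_f = 4, seed = 47)
  co <- simulateCohort(cfg)
  sv <- survivalData(co)
  sw <- sweepKf(featureValues(co), sv$time_months, sv$event, k_s = 3,
                kf_values = c(2, 4), model_kinds = c("cox", "rsf"),
                k = 3, reps = 2, seed = 1,
                fit_opts = list(n_restarts = 1, max_iter = 60, tol = 1e-4))
  expect_equal(nrow(sw), 2 * 2 * 2 * 3)   # kf x model x rep x fold
  expect_setequal(unique(sw$kf), c(2, 4))
  summ <- summarizeSweep(sw)
  expect_equal(nrow(summ), 4)
  expect_true(all(summ$mean > 0 & summ$mean < 1))
  expect_error(sweepKf(featureValues(co), sv$time_months, sv$event,
                       kf_values = 1:3), "kf_values")
})

test_that("matched-capacity factorization beats an undersized one", {
  # signal-capacity check: C-index at the true K_f is at least that at K_f=2
  wins <- 0
  for (s in 1:10) {
    cfg <- cohortConfig(n_patients = 100, n_features_pet = 30,
                        n_features_ct = 10, k_f = 5, seed = s + 100)
    co <- simulateCohort(cfg)
    sv <- survivalData(co)
    sw <- sweepKf(featureValues(co), sv$time_months, sv$event, k_s = 3,
                  kf_values = c(2, 5), model_kinds = "cox", k = 3, reps = 2,
                  seed = s, fit_opts = list(n_restarts = 1, max_iter = 60,
                                            tol = 1e-4))
    summ <- summarizeSweep(sw)
    if (summ$mean[summ$kf == 5] >= summ$mean[summ$kf == 2] - 0.02)
      wins <- wins + 1
  }
  expect_gte(wins, 7)
})

test_that("meta-feature Cox approaches the oracle concordance ceiling", {
  # under exponential hazards with multipliers (1, 2, 4) the best possible
  # Harrell C (risk = true multiplier) is ~0.64; the fitted model should sit
  # within a small margin of the same-cohort oracle
  gaps <- vapply(1:5, function(s) {
    co <- simulateCohort(cohortConfig(seed = s + 70))
    sv <- survivalData(co)
    oracle <- concordanceIndex(
      c(1, 2, 4)[truePatientLabels(co)], sv$time_months, sv$event)
    sel <- suppressMessages(selectFeatures(co))
    X <- featureValues(co)[, selectedFeatures(sel), drop = FALSE]
    tf <- fitTriFactor(X, 3, 9, n_restarts = 2, max_iter = 150, seed = s)
    cv <- suppressWarnings(
      repeatedKfoldCindex("cox", metaFeatures(tf), sv$time_months, sv$event,
                          k = 3, reps = 5, seed = s))
    oracle - cvMean(cv)
  }, numeric(1))
  expect_lte(mean(gaps), 0.05)
})
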