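test_that("unit-interval rescaling follows the declared conventions", {
  X <- cbind(a = c(2, 4, 6), b = c(5, 5, 5), c = c(0, 0.5, 1))
  colnames(X) <- c("PET_f1", "PET_f2", "PET_f3")
  R <- rescaleUnitInterval(X)
  expect_equal(unname(R[, 1]), c(0, 0.5, 1))
  expect_equal(unname(R[, 2]), c(0, 0, 0))     # constant maps to zeros
  expect_equal(unname(R[, 3]), c(0, 0.5, 1))   # already-[0,1] unchanged
  sc <- attr(R, "scaling")
  expect_equal(sc$min, c(2, 5, 0))
  expect_equal(sc$range, c(4, 0, 1))
  # re-application to new rows, with clamping
  Xn <- applyScaling(rbind(c(4, 9, 2)), sc)
  expect_equal(unname(Xn[1, ]), c(0.5, 0, 1))
})

test_that("objective is the squared Frobenius residual", {
  A <- diag(2); S <- diag(2); Y <- matrix(c(1, 0, 0, 0), 2, 2)
  X <- diag(2)
  # residual ((0,0),(0,1)) -> objective 1
  expect_equal(triFactorObjective(X, A, S, Y), 1)
  expect_equal(triFactorObjective(X, A * 0, S, Y), sum(X^2))
  A2 <- matrix(runif(6), 3, 2); S2 <- matrix(runif(4), 2, 2)
  Y2 <- matrix(runif(8), 2, 4)
  X2 <- A2 %*% S2 %*% Y2
  expect_equal(triFactorObjective(X2, A2, S2, Y2), 0)
  expect_error(triFactorObjective(X2, A2, S2, Y2[, 1:3]), "conformable")
})

test_that("noiseless biclustered matrices are recovered exactly", {
  ok <- 0
  for (s in 1:10) {
    cfg <- cohortConfig(n_patients = 60, n_features_pet = 30,
                        n_features_ct = 10, k_s = 3, k_f = 4,
                        noise_sd = 0, feature_profile_sd = 0, seed = s)
    co <- simulateCohort(cfg)
    fit <- fitTriFactor(featureValues(co), 3, 4, n_restarts = 10,
                        max_iter = 500, seed = s)
    tr <- objectiveTrajectory(fit)
    expect_monotone_trajectory(tr)
    rel <- tail(tr, 1) / sum(rescaleUnitInterval(featureValues(co))^2)
    if (rel < 1e-6 &&
        ari(patientClusters(fit), truePatientLabels(co)) == 1 &&
        ari(featureClusters(fit), trueFeatureLabels(co)) == 1)
      ok <- ok + 1
  }
  expect_gte(ok, 9)
})

test_that("objective trajectories are non-increasing on noisy fits", {
  co <- smallCohort(seed = 23)
  for (s in 1:3) {
    fit <- fitTriFactor(featureValues(co), 3, 4, n_restarts = 2,
                        max_iter = 200, seed = s)
    expect_monotone_trajectory(objectiveTrajectory(fit))
    expect_true(all(factorA(fit) >= 0))
    expect_true(all(factorS(fit) >= 0))
    expect_true(all(factorY(fit) >= 0))
  }
})

test_that("same seed reproduces the fit exactly", {
  co <- smallCohort(seed = 29)
  f1 <- fitTriFactor(featureValues(co), 3, 4, n_restarts = 3,
                     max_iter = 100, seed = 42)
  f2 <- fitTriFactor(featureValues(co), 3, 4, n_restarts = 3,
                     max_iter = 100, seed = 42)
  expect_identical(factorA(f1), factorA(f2))
  expect_identical(factorS(f1), factorS(f2))
  expect_identical(factorY(f1), factorY(f2))
  expect_identical(objectiveTrajectory(f1), objectiveTrajectory(f2))
})

test_that("patient labels are recovered under noise at separation/noise 4", {
  ok <- 0
  for (s in 1:20) {
    cfg <- cohortConfig(n_patients = 150, n_features_pet = 40,
                        n_features_ct = 20, k_s = 3, k_f = 4,
                        block_mean_separation = 1, noise_sd = 0.25,
                        feature_profile_sd = 0, seed = s)
    co <- simulateCohort(cfg)
    fit <- fitTriFactor(featureValues(co), 3, 4, n_restarts = 5,
                        max_iter = 300, seed = s)
    if (ari(patientClusters(fit), truePatientLabels(co)) >= 0.9) ok <- ok + 1
  }
  expect_gte(ok, 18)
})

test_that("meta-features are M = A S and label rules break ties low", {
  co <- smallCohort(seed = 31)
  fit <- fitTriFactor(featureValues(co), 3, 4, n_restarts = 2,
                      max_iter = 150, seed = 1)
  M <- metaFeatures(fit)
  expect_equal(dim(M), c(80, 4))
  expect_equal(unname(M), unname(factorA(fit) %*% factorS(fit)),
               tolerance = 1e-12)
  expect_true(all(M >= 0))

  # row/column maximum with ties resolved to the lowest index
  toy <- new("TriFactorFit",
             A = rbind(c(0.9, 0.1, 0), c(0.5, 0.5, 0), c(0, 0.2, 0.8)),
             S = matrix(1, 3, 2), Y = cbind(c(0.1, 0.8), c(0.5, 0.5)),
             k_s = 3L, k_f = 2L, objective_trajectory = c(2, 1),
             orthogonality_residuals = c(A = 0, Y = 0), seed_used = 1L,
             n_restarts = 1L, converged = TRUE,
             feature_scaling = data.frame())
  expect_equal(patientClusters(toy), c(1, 1, 3))
  expect_equal(featureClusters(toy), c(2, 1))
})

test_that("orthogonality residuals are reported and near zero for seeded fits", {
  co <- smallCohort(seed = 37)
  fit <- fitTriFactor(featureValues(co), 3, 4, n_restarts = 2,
                      max_iter = 150, seed = 2)
  res <- orthogonalityResiduals(fit)
  expect_named(res, c("A", "Y"))
  # disjoint supports: off-diagonal inner products vanish
  expect_lt(res["A"], 1e-6)
  expect_lt(res["Y"], 1e-6)
})

test_that("rank bounds and degenerate inputs are rejected", {
  co <- smallCohort(seed = 41)
  X <- featureValues(co)
  expect_error(fitTriFactor(X, 1, 4), "k_s")
  expect_error(fitTriFactor(X, 3, ncol(X) + 1), "k_f")
  expect_error(fitTriFactor(matrix(0, 10, 5), 2, 2, rescale = FALSE),
               "all-zero")
  # the study configuration is accepted on a 154 x 64 input
  cfg <- cohortConfig(n_patients = 154, n_features_pet = 52,
                      n_features_ct = 12, k_s = 3, k_f = 9, seed = 1)
  co2 <- simulateCohort(cfg)
  fit <- fitTriFactor(featureValues(co2), 3, 9, n_restarts = 1,
                      max_iter = 30, seed = 1)
  expect_s4_class(fit, "TriFactorFit")
  expect_equal(dim(factorA(fit)), c(154, 3))
  expect_equal(dim(factorY(fit)), c(9, 64))
})

test_that("held-out patients project onto the fitted factor space", {
  cfg <- cohortConfig(n_patients = 90, n_features_pet = 40,
                      n_features_ct = 20, k_s = 3, k_f = 4, seed = 43)
  co <- simulateCohort(cfg)
  X <- featureValues(co)
  tr_idx <- 1:60
  fit <- fitTriFactor(X[tr_idx, ], 3, 4, n_restarts = 3, max_iter = 200,
                      seed = 5)
  pj <- projectPatients(fit, X[-tr_idx, ])
  expect_equal(dim(pj$M), c(30, 4))
  expect_true(all(pj$A >= 0))
  # projected memberships assign held-out patients to the right group:
  # compare hard labels through the fitted cluster map
  lab_tr <- patientClusters(fit)
  truth_tr <- truePatientLabels(co)[tr_idx]
  map <- vapply(1:3, function(k)
    as.integer(names(which.max(table(truth_tr[lab_tr == k])))), integer(1))
  lab_new <- apply(pj$A, 1, which.max)
  agree <- mean(map[lab_new] == truePatientLabels(co)[-tr_idx])
  expect_gte(agree, 0.9)
})
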