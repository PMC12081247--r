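#' Configuration of the end-to-end comparison pipeline
#'
#' Every tunable of the pipeline with its default: selection thresholds (ICC
#' 0.75, |r| 0.76 PET / 0.40 CT), factorization ranks (K_s = 3, K_f = 9,
#' sweep grid 2..10), the cross-validation protocol (3-fold, repeated), the
#' forest (500 trees, minimum leaf 5), the 7:3 train/validation split and
#' the 36-month AUC horizon. Unknown arguments are rejected.
#'
#' @param seed master seed; all stages draw named sub-seeds from it.
#' @param icc_threshold,r_pet,r_ct feature-selection thresholds.
#' @param k_s,k_f factorization ranks for the headline configuration.
#' @param kf_grid K_f sweep grid.
#' @param cv_k,cv_reps repeated cross-validation protocol for the model
#'   comparison (the full protocol is 3-fold x 100; the default here uses
#'   fewer repetitions to keep a laptop run short - raise \code{cv_reps} to
#'   100 to match the protocol).
#' @param sweep_reps repetitions per K_f in the sweep.
#' @param n_trees,min_leaf random survival forest parameters.
#' @param train_fraction train share of the single train/validation split.
#' @param horizon_months AUC evaluation horizon.
#' @param fit_opts tri-factorization options for the headline fits.
#' @param sweep_fit_opts lighter options used inside fold-honest refits.
#' @param run_sweep include the K_f sweep stage (TRUE by default).
#' @return validated list of class \code{"ComparisonConfig"}.
#' @export
comparisonConfig <- function(seed = 1L,
                             icc_threshold = 0.75, r_pet = 0.76, r_ct = 0.40,
                             k_s = 3, k_f = 9, kf_grid = 2:10,
                             cv_k = 3, cv_reps = 20, sweep_reps = 5,
                             n_trees = 500, min_leaf = 5,
                             train_fraction = 0.7, horizon_months = 36,
                             fit_opts = list(n_restarts = 4, max_iter = 300,
                                             tol = 1e-6),
                             sweep_fit_opts = list(n_restarts = 2,
                                                   max_iter = 150,
                                                   tol = 1e-5),
                             run_sweep = TRUE) {
  cfg <- as.list(environment())
  stopifnot(cfg$cv_k >= 2, cfg$cv_reps >= 1, cfg$k_s >= 2, cfg$k_f >= 2,
            cfg$train_fraction > 0, cfg$train_fraction < 1)
  class(cfg) <- "ComparisonConfig"
  cfg
}

# Repeated k-fold CV of the three model families over a fold-honest feature
# constructor; the fold partitions depend only on (seed, rep) so different
# feature sets evaluated with the same seed are compared on identical folds.
cvFeatureSet <- function(X, time, event, builder, model_kinds, k, reps, seed,
                         n_trees = 500, min_leaf = 5) {
  rows <- list()
  for (r in seq_len(reps)) {
    fold <- makeFolds(event, k, subSeed(seed, paste0("cvrep", r)))
    for (f in seq_len(k)) {
      tr <- fold != f
      fe <- builder(X, tr, sprintf("b_%d_%d", r, f))
      for (mk in model_kinds) {
        extra <- if (mk == "rsf") list(n_trees = n_trees, min_leaf = min_leaf)
                 else list()
        m <- do.call(fitRiskModel,
                     c(list(kind = mk, features = fe$train, time = time[tr],
                            event = event[tr],
                            seed = subSeed(seed, sprintf("cm_%s_%d_%d",
                                                         mk, r, f))),
                       extra))
        rows[[length(rows) + 1]] <- data.frame(
          model = mk, rep = r, fold = f,
          cindex = concordanceIndex(predictRisk(m, fe$test),
                                    time[!tr], event[!tr]))
      }
    }
  }
  do.call(rbind, rows)
}

#' Run the full selection / factorization / stratification / prediction
#' comparison on a cohort
#'
#' Executes the complete pipeline under one master seed: feature selection
#' (ICC filter against the second-rater assay, then correlation pruning),
#' tri-factorization stratification at K_s = 2 and 3 with log-rank and
#' pairwise log-rank tests (with a K-means stratification arm for contrast),
#' repeated cross-validated concordance of the Cox / Lasso-Cox / forest
#' models on tri-factorization meta-features, PCA scores and clinical
#' variables, an optional fold-honest K_f sweep with the summed-concordance
#' curve, and the three-tier feature-combination AUC analysis on a single
#' event-stratified 7:3 train/validation split. Re-running with the same
#' cohort and config reproduces the report exactly.
#'
#' @param cohort a \linkS4class{RadiomicCohort} with a rater2 assay.
#' @param config a \code{\link{comparisonConfig}}.
#' @return list of class \code{"triSurvReport"}; see \code{\link{writeReport}}.
#' @export
runFullComparison <- function(cohort, config = comparisonConfig()) {
  stopifnot(is(cohort, "RadiomicCohort"))
  seed <- config$seed
  surv <- survivalData(cohort)
  time <- surv$time_months; event <- surv$event
  clin <- clinicalTable(cohort)

  ## 1. feature selection
  sel <- selectFeatures(cohort, icc_threshold = config$icc_threshold,
                        threshold_pet = config$r_pet,
                        threshold_ct = config$r_ct)
  X_sel <- featureValues(cohort)[, selectedFeatures(sel), drop = FALSE]

  ## 2. stratification at K_s = 2 and 3 (+ K-means contrast)
  strat_rows <- list()
  strat_fits <- list()
  for (ks in 2:3) {
    fit <- do.call(fitTriFactor,
                   c(list(x = X_sel, k_s = ks, k_f = config$k_f,
                          seed = subSeed(seed, paste0("strat", ks))),
                     config$fit_opts))
    strat_fits[[as.character(ks)]] <- fit
    lab <- patientClusters(fit)
    lr <- logrankTest(time, event, lab)
    km_lab <- kmeansStratify(X_sel, ks, seed = subSeed(seed, paste0("km", ks)))
    lr_km <- logrankTest(time, event, km_lab)
    strat_rows[[length(strat_rows) + 1]] <- data.frame(
      method = c("two_way", "kmeans"), k = ks,
      chi_square = c(lr$chi_square, lr_km$chi_square),
      p_value = c(lr$p_value, lr_km$p_value))
  }
  stratification <- do.call(rbind, strat_rows)
  lab3 <- patientClusters(strat_fits[["3"]])
  pairwise_p <- pairwiseLogrank(time, event, lab3)

  ## 3. model comparison on three feature constructions (paired folds)
  kinds <- c("cox", "cox_lasso", "rsf")
  meta_builder <- function(X, tr, tag)
    foldFeaturesTwoWay(X, tr, config$k_s, config$k_f,
                       seed = subSeed(seed, paste0("mb", tag)),
                       config$sweep_fit_opts)
  pca_builder <- function(X, tr, tag) foldFeaturesPCA(X, tr, config$k_f)
  clin_design <- buildClinicalDesign(clin, include_inflammatory = TRUE,
                                     include_suv = TRUE)
  clin_builder <- function(X, tr, tag)
    list(train = X[tr, , drop = FALSE], test = X[!tr, , drop = FALSE])
  cv_tabs <- list(
    meta = cvFeatureSet(X_sel, time, event, meta_builder, kinds,
                        config$cv_k, config$cv_reps, seed,
                        config$n_trees, config$min_leaf),
    pca = cvFeatureSet(X_sel, time, event, pca_builder, kinds,
                       config$cv_k, config$cv_reps, seed,
                       config$n_trees, config$min_leaf),
    clinical = cvFeatureSet(clin_design, time, event, clin_builder, kinds,
                            config$cv_k, config$cv_reps, seed,
                            config$n_trees, config$min_leaf))
  cv_comparison <- do.call(rbind, lapply(names(cv_tabs), function(nm)
    cbind(feature_set = nm, cv_tabs[[nm]])))
  cv_summary <- aggregate(cindex ~ feature_set + model, data = cv_comparison,
                          FUN = function(v) c(mean = mean(v), sd = sd(v)))
  cv_summary <- data.frame(feature_set = cv_summary$feature_set,
                           model = cv_summary$model,
                           mean = cv_summary$cindex[, "mean"],
                           sd = cv_summary$cindex[, "sd"])
  cv_summary <- cv_summary[order(cv_summary$feature_set, cv_summary$model), ]
  rownames(cv_summary) <- NULL

  ## 4. K_f sweep and summed-concordance curve
  sweep_summary <- NULL; summed_curve <- NULL
  if (config$run_sweep) {
    sw <- sweepKf(X_sel, time, event, k_s = config$k_s,
                  kf_values = config$kf_grid, model_kinds = kinds,
                  k = config$cv_k, reps = config$sweep_reps,
                  seed = subSeed(seed, "sweep"),
                  fit_opts = config$sweep_fit_opts)
    sweep_summary <- summarizeSweep(sw)
    summed_curve <- summedCindexCurve(sweep_summary)
  }

  ## 5. three-tier AUC analysis on the 7:3 split
  sp <- splitTrainValidation(length(time), config$train_fraction,
                             strata = event, seed = subSeed(seed, "split"))
  tiers <- list(
    clinical = buildClinicalDesign(clin, FALSE, include_suv = TRUE),
    clinical_inflammatory = buildClinicalDesign(clin, TRUE, include_suv = TRUE))
  tf_train <- do.call(fitTriFactor,
                      c(list(x = X_sel[sp$train, , drop = FALSE],
                             k_s = config$k_s, k_f = config$k_f,
                             seed = subSeed(seed, "tier_tf")),
                        config$fit_opts))
  M_all <- matrix(NA_real_, length(time), config$k_f)
  M_all[sp$train, ] <- metaFeatures(tf_train)
  M_all[sp$validation, ] <- projectPatients(
    tf_train, X_sel[sp$validation, , drop = FALSE])$M
  colnames(M_all) <- sprintf("MF%d", seq_len(config$k_f))
  tiers$all <- cbind(tiers$clinical_inflammatory, M_all)

  tier_rows <- list()
  for (tn in names(tiers)) {
    D <- tiers[[tn]]
    aucs_val <- aucs_tr <- setNames(numeric(3), kinds)
    for (mk in kinds) {
      extra <- if (mk == "rsf") list(n_trees = config$n_trees,
                                     min_leaf = config$min_leaf) else list()
      m <- do.call(fitRiskModel,
                   c(list(kind = mk, features = D[sp$train, , drop = FALSE],
                          time = time[sp$train], event = event[sp$train],
                          seed = subSeed(seed, paste0("tier_", tn, mk))),
                     extra))
      aucs_val[mk] <- ipcwAUC(predictRisk(m, D[sp$validation, , drop = FALSE]),
                              time[sp$validation], event[sp$validation],
                              config$horizon_months)
      aucs_tr[mk] <- ipcwAUC(predictRisk(m, D[sp$train, , drop = FALSE]),
                             time[sp$train], event[sp$train],
                             config$horizon_months)
    }
    mv <- meanModelAUC(aucs_val); mt <- meanModelAUC(aucs_tr)
    tier_rows[[length(tier_rows) + 1]] <- data.frame(
      tier = tn, cox = aucs_val["cox"], cox_lasso = aucs_val["cox_lasso"],
      rsf = aucs_val["rsf"], mean_auc = mv["mean"], sd_auc = mv["sd"],
      mean_auc_train = mt["mean"], row.names = NULL)
  }
  tier_auc <- do.call(rbind, tier_rows)

  report <- list(
    n_patients = length(time),
    n_features_input = ncol(featureValues(cohort)),
    selection = data.frame(
      stage = c("input", "after_icc", "final"),
      n_features = c(ncol(featureValues(cohort)),
                     length(sel@kept_after_icc),
                     length(selectedFeatures(sel)))),
    stratification = stratification,
    pairwise_logrank_k3 = pairwise_p,
    cv_summary = cv_summary,
    cv_folds = cv_comparison,
    sweep_summary = sweep_summary,
    summed_cindex = summed_curve,
    tier_auc = tier_auc,
    config = unclass(config))
  class(report) <- "triSurvReport"
  report
}

#' Serialize a comparison report deterministically
#'
#' Writes the report tables as CSV plus a human-readable
#' \code{summary.txt}; identical reports produce byte-identical files.
#'
#' @param report a \code{"triSurvReport"} from \code{\link{runFullComparison}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the files written.
#' @export
writeReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  wr <- function(df, name) {
    p <- file.path(dir, name)
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], fmtNum)
    utils::write.csv(df, p, row.names = FALSE, quote = FALSE)
    files <<- c(files, p)
  }
  wr(report$selection, "selection.csv")
  wr(report$stratification, "stratification.csv")
  pw <- as.data.frame(report$pairwise_logrank_k3)
  pw <- cbind(group = rownames(report$pairwise_logrank_k3), pw)
  wr(pw, "pairwise_logrank.csv")
  wr(report$cv_summary, "cv_summary.csv")
  wr(report$cv_folds, "cv_folds.csv")
  if (!is.null(report$sweep_summary)) {
    wr(report$sweep_summary, "sweep_summary.csv")
    wr(report$summed_cindex, "summed_cindex.csv")
  }
  wr(report$tier_auc, "tier_auc.csv")
  txt <- c(
    sprintf("patients: %d; input features: %d; selected: %d",
            report$n_patients, report$n_features_input,
            report$selection$n_features[3]),
    "",
    "cross-validated C-index (mean +/- sd):",
    sprintf("  %-22s %-10s %.4f +/- %.4f", report$cv_summary$feature_set,
            report$cv_summary$model, report$cv_summary$mean,
            report$cv_summary$sd),
    "",
    "validation-set mean AUC by feature tier:",
    sprintf("  %-22s %.4f +/- %.4f", report$tier_auc$tier,
            report$tier_auc$mean_auc, report$tier_auc$sd_auc))
  if (!is.null(report$summed_cindex))
    txt <- c(txt, "",
             sprintf("summed C-index maximal at K_f = %d",
                     attr(report$summed_cindex, "best_kf")))
  writeLines(txt, file.path(dir, "summary.txt"))
  files <- c(files, file.path(dir, "summary.txt"))
  invisible(files)
}
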