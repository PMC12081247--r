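#' CVSummary: repeated k-fold concordance summary
#'
#' @slot fold_cindex data.frame with one row per (rep, fold): columns
#'   \code{rep}, \code{fold}, \code{cindex}, \code{cindex_train}.
#' @slot mean,sd summary of the held-out fold concordances.
#' @slot k,reps,seed protocol metadata.
#' @export
setClass("CVSummary",
         representation(fold_cindex = "data.frame", mean = "numeric",
                        sd = "numeric", k = "integer", reps = "integer",
                        seed = "integer"))

setValidity("CVSummary", function(object) {
  if (nrow(object@fold_cindex) == 0) return("no fold results")
  if (abs(object@mean - mean(object@fold_cindex$cindex)) > 1e-12)
    return("stored mean does not match fold-level values")
  TRUE
})

setMethod("show", "CVSummary", function(object) {
  cat(sprintf("CVSummary: %d-fold x %d reps, C-index %.3f +/- %.3f\n",
              object@k, object@reps, object@mean, object@sd))
})

#' Mean held-out concordance
#' @param object a \linkS4class{CVSummary}.
#' @return numeric scalar.
#' @export
cvMean <- function(object) object@mean

#' Fold-level concordance values
#' @param object a \linkS4class{CVSummary}.
#' @return data.frame of per-(rep, fold) results.
#' @export
cvFolds <- function(object) object@fold_cindex

#' Repeated k-fold cross-validated concordance
#'
#' For each repetition a fresh seeded event-stratified k-fold partition is
#' drawn; the model is fitted on k-1 folds and scored by Harrell's C on the
#' held-out fold. The summary reports the mean and standard deviation over
#' all held-out folds of all repetitions.
#'
#' @param kind model family ("cox", "cox_lasso", "rsf").
#' @param features fixed design matrix (no refitting of upstream transforms;
#'   see \code{\link{sweepKf}} for the fold-honest meta-feature protocol).
#' @param time,event survival outcome.
#' @param k folds (default 3).
#' @param reps repetitions (default 100).
#' @param seed master seed; repetition r uses sub-seed "rep r".
#' @param ... passed to the model fitting function.
#' @return a \linkS4class{CVSummary}.
#' @export
repeatedKfoldCindex <- function(kind, features, time, event, k = 3,
                                reps = 100, seed = 1L, ...) {
  X <- asDesign(features)
  n <- nrow(X)
  if (n < 3 * k) stop("too few patients for ", k, "-fold cross-validation")
  rows <- vector("list", reps * k)
  ri <- 0
  for (r in seq_len(reps)) {
    fold <- makeFolds(event, k, subSeed(seed, paste0("rep", r)))
    for (f in seq_len(k)) {
      tr <- fold != f
      if (sum(event[!tr]) == 0) stop("fold without events")
      model <- fitRiskModel(kind, X[tr, , drop = FALSE], time[tr], event[tr],
                            seed = subSeed(seed, sprintf("fit_%d_%d", r, f)),
                            ...)
      risk_te <- predictRisk(model, X[!tr, , drop = FALSE])
      risk_tr <- predictRisk(model, X[tr, , drop = FALSE])
      ri <- ri + 1
      rows[[ri]] <- data.frame(
        rep = r, fold = f,
        cindex = concordanceIndex(risk_te, time[!tr], event[!tr]),
        cindex_train = concordanceIndex(risk_tr, time[tr], event[tr]))
    }
  }
  tab <- do.call(rbind, rows)
  new("CVSummary", fold_cindex = tab, mean = mean(tab$cindex),
      sd = sd(tab$cindex), k = as.integer(k), reps = as.integer(reps),
      seed = as.integer(seed))
}

# Fold-honest feature constructors used by sweepKf / nestedParamSelect /
# runFullComparison: each returns train/test design matrices built only from
# training information.
foldFeaturesTwoWay <- function(X, tr, k_s, k_f, seed, fit_opts) {
  fit <- do.call(fitTriFactor,
                 c(list(x = X[tr, , drop = FALSE], k_s = k_s, k_f = k_f,
                        seed = seed), fit_opts))
  list(train = metaFeatures(fit),
       test = projectPatients(fit, X[!tr, , drop = FALSE])$M,
       fit = fit)
}

foldFeaturesPCA <- function(X, tr, n_components) {
  sc <- scale(X[tr, , drop = FALSE])
  ctr <- attr(sc, "scaled:center"); scl <- attr(sc, "scaled:scale")
  scl[scl == 0] <- 1
  pc <- prcomp(sc, center = FALSE, scale. = FALSE)
  W <- fixPCASigns(pc$rotation[, seq_len(n_components), drop = FALSE])
  Xte <- sweep(sweep(X[!tr, , drop = FALSE], 2, ctr), 2, scl, "/")
  list(train = sc %*% W, test = Xte %*% W)
}

#' Sweep the number of meta-features under repeated cross-validation
#'
#' For K_s fixed (default 3) and each K_f in the grid, runs repeated k-fold
#' cross-validation in which the tri-factorization is refit on the training
#' folds only and held-out patients are projected by non-negative least
#' squares against the fixed S and Y (fold-honest protocol; set
#' \code{fold_honest = FALSE} to factorize once on all data, the naive
#' variant). All requested model families are evaluated on the same folds.
#'
#' @param X patients-by-features matrix (raw scale; rescaling happens inside
#'   each training fold).
#' @param time,event survival outcome.
#' @param k_s patient sub-clusters (default 3).
#' @param kf_values K_f grid (default 2:10).
#' @param model_kinds model families to evaluate.
#' @param k,reps cross-validation protocol (folds, repetitions).
#' @param seed master seed.
#' @param fit_opts list of options forwarded to \code{\link{fitTriFactor}}
#'   (restarts, max_iter, tol).
#' @param fold_honest refit the factorization inside folds (default TRUE).
#' @return data.frame: \code{kf}, \code{model}, \code{rep}, \code{fold},
#'   \code{cindex}.
#' @export
sweepKf <- function(X, time, event, k_s = 3, kf_values = 2:10,
                    model_kinds = c("cox", "cox_lasso", "rsf"),
                    k = 3, reps = 10, seed = 1L,
                    fit_opts = list(n_restarts = 2, max_iter = 200,
                                    tol = 1e-5),
                    fold_honest = TRUE) {
  X <- asDesign(X)
  if (any(kf_values < 2) || any(kf_values > ncol(X)))
    stop("kf_values must lie in [2, F]")
  rows <- list()
  for (kf in kf_values) {
    full_fit <- NULL
    if (!fold_honest)
      full_fit <- do.call(fitTriFactor,
                          c(list(x = X, k_s = k_s, k_f = kf,
                                 seed = subSeed(seed, paste0("full", kf))),
                            fit_opts))
    for (r in seq_len(reps)) {
      fold <- makeFolds(event, k, subSeed(seed, sprintf("sw_%d_%d", kf, r)))
      for (f in seq_len(k)) {
        tr <- fold != f
        if (fold_honest) {
          feats <- foldFeaturesTwoWay(
            X, tr, k_s, kf,
            seed = subSeed(seed, sprintf("tf_%d_%d_%d", kf, r, f)), fit_opts)
        } else {
          M <- metaFeatures(full_fit)
          feats <- list(train = M[tr, , drop = FALSE],
                        test = M[!tr, , drop = FALSE])
        }
        for (mk in model_kinds) {
          model <- fitRiskModel(mk, feats$train, time[tr], event[tr],
                                seed = subSeed(seed, sprintf("m_%s_%d_%d_%d",
                                                             mk, kf, r, f)))
          ci <- concordanceIndex(predictRisk(model, feats$test),
                                 time[!tr], event[!tr])
          rows[[length(rows) + 1]] <- data.frame(
            kf = kf, model = mk, rep = r, fold = f, cindex = ci)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize a K_f sweep into mean +/- sd per (kf, model)
#'
#' @param sweep_table output of \code{\link{sweepKf}}.
#' @return data.frame: kf, model, mean, sd.
#' @export
summarizeSweep <- function(sweep_table) {
  agg <- aggregate(cindex ~ kf + model, data = sweep_table,
                   FUN = function(v) c(mean = mean(v), sd = sd(v)))
  out <- data.frame(kf = agg$kf, model = agg$model,
                    mean = agg$cindex[, "mean"], sd = agg$cindex[, "sd"])
  out[order(out$kf, out$model), ]
}
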