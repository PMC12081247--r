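#' RiskModel: a fitted mortality-risk model
#'
#' Thin S4 wrapper unifying the three model families used for overall-survival
#' prediction: Cox proportional hazards (partial likelihood, Efron ties),
#' L1-penalized Cox with the penalty chosen by inner cross-validation, and a
#' random survival forest (log-rank splitting). \code{\link{predictRisk}}
#' returns a score where higher always means higher predicted mortality risk:
#' the linear predictor for the Cox family, the summed ensemble cumulative
#' hazard for the forest.
#'
#' @slot kind "cox", "cox_lasso" or "rsf".
#' @slot fit the underlying fitted object.
#' @slot feature_names training feature columns, in order.
#' @slot meta list of training metadata (seed, folds, chosen penalty, flags).
#' @export
setClass("RiskModel",
         representation(kind = "character", fit = "ANY",
                        feature_names = "character", meta = "list"))

setMethod("show", "RiskModel", function(object) {
  cat("RiskModel <", object@kind, "> on ", length(object@feature_names),
      " features\n", sep = "")
  if (object@kind == "cox_lasso")
    cat(sprintf("  lambda = %.5g, %d non-zero coefficients\n",
                object@meta$lambda, object@meta$n_nonzero))
})

asDesign <- function(features) {
  M <- as.matrix(features)
  if (is.null(colnames(M)))
    colnames(M) <- sprintf("x%d", seq_len(ncol(M)))
  storage.mode(M) <- "double"
  M
}

#' Event-stratified train/validation split
#'
#' Splits n subjects into train/validation with the training size equal to
#' \code{round(n * train_fraction)}; events and non-events are sampled
#' separately so the event proportions of the two parts differ by at most one
#' subject's worth.
#'
#' @param n number of subjects.
#' @param train_fraction fraction in (0, 1); default 0.7.
#' @param strata binary event indicator used for stratification (optional:
#'   unstratified split when NULL).
#' @param seed RNG seed.
#' @return list with integer index vectors \code{train} and \code{validation}.
#' @export
splitTrainValidation <- function(n, train_fraction = 0.7, strata = NULL,
                                 seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must lie strictly between 0 and 1")
  n_train <- round(n * train_fraction)
  withSeed(seed, {
    if (is.null(strata)) {
      train <- sort(sample.int(n, n_train))
    } else {
      if (length(strata) != n) stop("strata length mismatch")
      idx1 <- which(strata == 1); idx0 <- which(strata != 1)
      if (length(idx1) < 2 || length(idx0) < 2)
        stop("each stratum must contain at least 2 subjects")
      k1 <- round(length(idx1) * train_fraction)
      k1 <- min(max(k1, n_train - length(idx0)), length(idx1), n_train)
      train <- sort(c(sample(idx1, k1), sample(idx0, n_train - k1)))
    }
    list(train = train, validation = setdiff(seq_len(n), train))
  })
}

# Event-stratified k-fold assignment; every fold gets events when possible.
makeFolds <- function(event, k, seed) {
  withSeed(seed, {
    fold <- integer(length(event))
    for (s in unique(event)) {
      idx <- which(event == s)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    fold
  })
}

#' Fit a Cox proportional hazards model
#'
#' Partial-likelihood maximization with Efron handling of tied event times.
#' Non-convergence or coefficient divergence (separation) is reported as an
#' error rather than silently returned.
#'
#' @param features numeric design matrix (patients x features).
#' @param time,event survival outcome.
#' @return a \linkS4class{RiskModel} of kind \code{"cox"}.
#' @export
fitCoxModel <- function(features, time, event) {
  X <- asDesign(features)
  if (sum(event) == 0) stop("no events; Cox model undefined")
  if (nrow(X) <= ncol(X))
    stop("Cox regression needs more patients than features")
  if (any(apply(X, 2, var) == 0)) stop("constant feature in design")
  df <- data.frame(X, check.names = FALSE)
  df$.time <- time; df$.event <- event
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", colnames(X)), collapse = " + ")))
  flags <- character(0)
  fit <- withCallingHandlers(
    survival::coxph(fml, data = df, ties = "efron"),
    warning = function(w) {
      msg <- conditionMessage(w)
      if (grepl("Ran out of iterations", msg))
        stop("Cox fit did not converge: ", msg)
      if (grepl("infinite|singular", msg)) {
        # separation / collinearity: report, keep the capped fit
        flags <<- c(flags, msg)
        warning("Cox fit flagged (possible separation): ", msg,
                call. = FALSE)
      }
      invokeRestart("muffleWarning")
    })
  new("RiskModel", kind = "cox", fit = fit,
      feature_names = colnames(X), meta = list(flags = flags))
}

#' Fit an L1-penalized Cox model with nested penalty selection
#'
#' The penalty path is handled by \code{glmnet}; the sparsity level is chosen
#' by inner k-fold cross-validated partial likelihood on event-stratified
#' folds. The default rule is the one-standard-error rule
#' (\code{lambda.1se}): the sparsest penalty whose held-out partial
#' likelihood is within one standard error of the best, the conventional
#' choice when the penalty serves feature selection; \code{rule = "min"}
#' selects the likelihood-optimal penalty instead. When every coefficient is
#' shrunk to zero the model is returned with \code{meta$constant_risk = TRUE}
#' and a warning.
#'
#' @param features design matrix (collinearity allowed).
#' @param time,event survival outcome.
#' @param inner_folds folds of the inner selection (default 3).
#' @param seed RNG seed for the fold assignment.
#' @param lambda optional fixed penalty, skipping the inner selection
#'   (0 reproduces the unpenalized Cox fit up to solver tolerance).
#' @param rule \code{"1se"} (default) or \code{"min"}.
#' @return a \linkS4class{RiskModel} of kind \code{"cox_lasso"}.
#' @export
fitCoxLasso <- function(features, time, event, inner_folds = 3, seed = 1L,
                        lambda = NULL, rule = c("1se", "min")) {
  rule <- match.arg(rule)
  X <- asDesign(features)
  if (sum(event) == 0) stop("no events; Cox model undefined")
  feature_names <- colnames(X)
  padded <- ncol(X) == 1   # the penalized solver needs >= 2 columns
  if (padded) X <- cbind(X, .pad = 0)
  y <- survival::Surv(time, event)
  if (is.null(lambda)) {
    foldid <- makeFolds(event, inner_folds, seed)
    cvfit <- withSeed(seed,
      glmnet::cv.glmnet(X, y, family = "cox", foldid = foldid,
                        type.measure = "deviance"))
    lambda <- if (rule == "1se") cvfit$lambda.1se else cvfit$lambda.min
    fit <- cvfit$glmnet.fit
  } else {
    fit <- glmnet::glmnet(X, y, family = "cox", lambda = lambda,
                          thresh = 1e-12)
  }
  beta <- as.numeric(stats::coef(fit, s = lambda))
  if (padded) beta <- beta[1]
  n_nonzero <- sum(beta != 0)
  if (n_nonzero == 0)
    warning("all coefficients shrunk to zero: constant-risk model")
  new("RiskModel", kind = "cox_lasso", fit = fit,
      feature_names = feature_names,
      meta = list(lambda = lambda, n_nonzero = n_nonzero,
                  constant_risk = n_nonzero == 0, seed = seed,
                  inner_folds = inner_folds, beta = beta, padded = padded))
}

#' Fit a random survival forest
#'
#' Log-rank split rule with seeded bootstrap via \code{ranger}; the risk
#' score is the patient's ensemble cumulative hazard summed over the unique
#' event times (a mortality-style summary).
#'
#' @param features design matrix.
#' @param time,event survival outcome.
#' @param n_trees number of trees (default 500).
#' @param min_leaf minimum terminal node size (default 5).
#' @param seed RNG seed.
#' @return a \linkS4class{RiskModel} of kind \code{"rsf"}.
#' @export
fitRSF <- function(features, time, event, n_trees = 500, min_leaf = 5,
                   seed = 1L) {
  X <- asDesign(features)
  if (min_leaf >= nrow(X)) stop("min_leaf must be smaller than N")
  if (nrow(X) < 2 * min_leaf) stop("too few patients for the leaf size")
  df <- data.frame(X, check.names = FALSE)
  df$.time <- time; df$.event <- event
  fit <- ranger::ranger(
    formula = survival::Surv(.time, .event) ~ .,
    data = df, num.trees = n_trees, min.node.size = min_leaf,
    splitrule = "logrank", seed = seed, num.threads = 1)
  new("RiskModel", kind = "rsf", fit = fit, feature_names = colnames(X),
      meta = list(n_trees = n_trees, min_leaf = min_leaf, seed = seed))
}

#' @rdname predictRisk
#' @export
setMethod("predictRisk", "RiskModel", function(object, newdata) {
  X <- asDesign(newdata)[, object@feature_names, drop = FALSE]
  switch(object@kind,
    cox = {
      df <- data.frame(X, check.names = FALSE)
      as.numeric(stats::predict(object@fit, newdata = df, type = "lp"))
    },
    cox_lasso = {
      if (isTRUE(object@meta$padded)) X <- cbind(X, .pad = 0)
      as.numeric(stats::predict(object@fit, newx = X, s = object@meta$lambda,
                                type = "link"))
    },
    rsf = {
      df <- data.frame(X, check.names = FALSE)
      pr <- stats::predict(object@fit, data = df, num.threads = 1)
      rowSums(pr$chf)
    },
    stop("unknown model kind"))
})

#' Unified model fitting front-end
#'
#' @param kind "cox", "cox_lasso" or "rsf".
#' @param features design matrix.
#' @param time,event survival outcome.
#' @param seed RNG seed (ignored by plain Cox).
#' @param ... passed to the specific fitting function.
#' @return a \linkS4class{RiskModel}.
#' @export
fitRiskModel <- function(kind = c("cox", "cox_lasso", "rsf"), features,
                         time, event, seed = 1L, ...) {
  kind <- match.arg(kind)
  switch(kind,
         cox = fitCoxModel(features, time, event, ...),
         cox_lasso = fitCoxLasso(features, time, event, seed = seed, ...),
         rsf = fitRSF(features, time, event, seed = seed, ...))
}

#' Harrell's concordance index
#'
#' Fraction of comparable patient pairs in which the higher predicted risk
#' belongs to the earlier failure; tied risk scores count 1/2. A pair is
#' comparable when the shorter observed time is an event; at tied observed
#' times an event-censoring pair is comparable (the censored patient is
#' known to survive at least as long) while an event-event tie is not.
#'
#' @param risk predicted risk scores (higher = worse).
#' @param time,event survival outcome.
#' @return concordance in [0, 1].
#' @export
concordanceIndex <- function(risk, time, event) {
  if (length(risk) != length(time)) stop("length mismatch")
  cf <- survival::concordance(survival::Surv(time, event) ~ risk,
                              reverse = TRUE)
  n_comparable <- sum(cf$count[c("concordant", "discordant", "tied.x")])
  if (n_comparable == 0) stop("no comparable pairs")
  unname(cf$concordance)
}
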