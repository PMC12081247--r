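#' K-means patient stratification on standardized features
#'
#' Lloyd's algorithm (\code{stats::kmeans}), best of \code{n_init} seeded
#' initializations by within-cluster sum of squares; features are z-scored
#' internally so mixed-scale radiomic features contribute comparably.
#'
#' @param X patients-by-features matrix.
#' @param k number of clusters (>= 1).
#' @param seed RNG seed.
#' @param n_init number of random initializations (default 10).
#' @return integer labels in 1..k.
#' @export
kmeansStratify <- function(X, k, seed = 1L, n_init = 10) {
  X <- asDesign(X)
  if (k < 1) stop("k must be at least 1")
  if (k > nrow(X)) stop("k exceeds the number of patients")
  if (k == 1) return(rep(1L, nrow(X)))
  Z <- scale(X)
  Z[, attr(Z, "scaled:scale") == 0] <- 0
  withSeed(seed, kmeans(Z, centers = k, nstart = n_init,
                        algorithm = "Lloyd", iter.max = 100)$cluster)
}

# Deterministic sign convention: make each loading vector's
# largest-magnitude entry positive.
fixPCASigns <- function(W) {
  for (j in seq_len(ncol(W))) {
    i <- which.max(abs(W[, j]))
    if (W[i, j] < 0) W[, j] <- -W[, j]
  }
  W
}

#' PCA feature reduction with a fixed sign convention
#'
#' Scores on the top principal components of the internally standardized
#' matrix; the sign of each component is fixed by making the
#' largest-magnitude loading positive, so results are reproducible across
#' platforms.
#'
#' @param X patients-by-features matrix.
#' @param n_components number of components, <= min(N, F).
#' @return N x n_components score matrix with the loadings in attribute
#'   \code{"rotation"} and the centering/scaling in \code{"center"}/
#'   \code{"scale"}.
#' @export
pcaReduce <- function(X, n_components) {
  X <- asDesign(X)
  if (n_components < 1 || n_components > min(dim(X)))
    stop("n_components out of range")
  Z <- scale(X)
  scl <- attr(Z, "scaled:scale")
  Z[, scl == 0] <- 0
  pc <- prcomp(Z, center = FALSE, scale. = FALSE)
  W <- fixPCASigns(pc$rotation[, seq_len(n_components), drop = FALSE])
  scores <- Z %*% W
  colnames(scores) <- sprintf("PC%d", seq_len(n_components))
  attr(scores, "rotation") <- W
  attr(scores, "center") <- attr(Z, "scaled:center")
  attr(scores, "scale") <- scl
  scores
}

#' Nested cross-validated selection of the reduction dimension
#'
#' Outer k-fold (default 5): within each outer-training set, an inner
#' cross-validation (default 3-fold) picks the grid value (K_f for the
#' two-way factorization, component count for PCA) maximizing the mean inner
#' held-out concordance; the outer fold then scores a model refit on the full
#' outer-training set at that value. All feature constructions are
#' fold-honest (fitted on training data, held-out patients projected).
#'
#' @param X patients-by-features matrix.
#' @param time,event survival outcome.
#' @param method "two_way" or "pca".
#' @param param_grid candidate dimensions (default 2:10).
#' @param outer_folds,inner_folds protocol (defaults 5 and 3).
#' @param model_kind risk model used for scoring (default "cox").
#' @param k_s patient sub-clusters for the two-way method (default 3).
#' @param seed master seed.
#' @param fit_opts options forwarded to \code{\link{fitTriFactor}}.
#' @return list: \code{best_param} (modal outer selection), \code{mean},
#'   \code{sd} (outer concordance), \code{outer} (per-fold detail).
#' @export
nestedParamSelect <- function(X, time, event, method = c("two_way", "pca"),
                              param_grid = 2:10, outer_folds = 5,
                              inner_folds = 3, model_kind = "cox", k_s = 3,
                              seed = 1L,
                              fit_opts = list(n_restarts = 2, max_iter = 150,
                                              tol = 1e-5)) {
  method <- match.arg(method)
  if (length(param_grid) == 0) stop("empty parameter grid")
  X <- asDesign(X)
  buildFeats <- function(Xs, tr, p, tag) {
    if (method == "two_way")
      foldFeaturesTwoWay(Xs, tr, k_s, p, seed = subSeed(seed, tag), fit_opts)
    else foldFeaturesPCA(Xs, tr, p)
  }
  ofold <- makeFolds(event, outer_folds, subSeed(seed, "outer"))
  outer_rows <- list()
  for (of in seq_len(outer_folds)) {
    otr <- ofold != of
    Xtr <- X[otr, , drop = FALSE]
    ttr <- time[otr]; etr <- event[otr]
    best_p <- param_grid[1]
    if (length(param_grid) > 1) {
      ifold <- makeFolds(etr, inner_folds, subSeed(seed, paste0("inner", of)))
      inner_mean <- vapply(param_grid, function(p) {
        cis <- vapply(seq_len(inner_folds), function(fi) {
          itr <- ifold != fi
          fe <- buildFeats(Xtr, itr, p, sprintf("i_%d_%d_%d", of, fi, p))
          m <- fitRiskModel(model_kind, fe$train, ttr[itr], etr[itr],
                            seed = subSeed(seed, sprintf("im_%d_%d_%d",
                                                         of, fi, p)))
          concordanceIndex(predictRisk(m, fe$test), ttr[!itr], etr[!itr])
        }, numeric(1))
        mean(cis)
      }, numeric(1))
      best_p <- param_grid[which.max(inner_mean)]
    }
    fe <- buildFeats(X, otr, best_p, sprintf("o_%d_%d", of, best_p))
    m <- fitRiskModel(model_kind, fe$train, ttr, etr,
                      seed = subSeed(seed, paste0("om", of)))
    ci <- concordanceIndex(predictRisk(m, fe$test), time[!otr], event[!otr])
    outer_rows[[of]] <- data.frame(fold = of, selected = best_p, cindex = ci)
  }
  outer <- do.call(rbind, outer_rows)
  sel <- outer$selected
  modal <- as.numeric(names(sort(table(sel), decreasing = TRUE))[1])
  list(best_param = modal, mean = mean(outer$cindex),
       sd = sd(outer$cindex), outer = outer)
}

#' Assemble a numeric clinical design matrix
#'
#' Builds the nested feature tiers used in the feature-combination analysis:
#' the base tier holds age, BMI, ordinal-coded T stage and lymph-node status;
#' \code{include_suv} adds the semi-quantitative PET parameters and
#' \code{include_inflammatory} adds WBC, NC, LC, PLT and NLR. The NLR column
#' is recomputed as NC/LC.
#'
#' @param clinical data.frame with the cohort's clinical columns.
#' @param include_inflammatory add the inflammatory markers.
#' @param include_suv add suv_max/suv_mean/suv_peak.
#' @return numeric matrix, one row per patient, fixed column order.
#' @export
buildClinicalDesign <- function(clinical, include_inflammatory = FALSE,
                                include_suv = FALSE) {
  need <- c("age", "bmi", "t_stage", "lymph_node_positive")
  if (include_suv) need <- c(need, "suv_max", "suv_mean", "suv_peak")
  if (include_inflammatory) need <- c(need, "wbc", "nc", "lc", "plt")
  missing <- setdiff(need, colnames(clinical))
  if (length(missing))
    stop("missing clinical column(s): ", paste(missing, collapse = ", "))
  if (anyNA(clinical[need])) stop("missing values in clinical table")
  cols <- list(age = clinical$age, bmi = clinical$bmi,
               t_stage_code = as.numeric(clinical$t_stage),
               lymph_node_positive = as.numeric(clinical$lymph_node_positive))
  if (include_suv)
    cols <- c(cols, list(suv_max = clinical$suv_max,
                         suv_mean = clinical$suv_mean,
                         suv_peak = clinical$suv_peak))
  if (include_inflammatory)
    cols <- c(cols, list(wbc = clinical$wbc, nc = clinical$nc,
                         lc = clinical$lc, plt = clinical$plt,
                         nlr = clinical$nc / clinical$lc))
  do.call(cbind, cols)
}
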