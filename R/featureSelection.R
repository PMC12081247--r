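#' SelectionReport: outcome of the reproducibility/redundancy feature filter
#'
#' @slot icc_per_feature named numeric vector of ICC(2,1) values (NA when the
#'   ICC stage was not run).
#' @slot kept_after_icc feature names surviving the ICC threshold.
#' @slot dropped_redundant data.frame with one row per feature removed by the
#'   correlation pruning: \code{feature}, \code{partner} (a retained feature
#'   it was most correlated with at removal time) and \code{abs_r}.
#' @slot final_features names surviving both stages.
#' @slot icc_threshold,r_pet,r_ct thresholds used.
#' @export
setClass("SelectionReport",
         representation(icc_per_feature = "numeric",
                        kept_after_icc = "character",
                        dropped_redundant = "data.frame",
                        final_features = "character",
                        icc_threshold = "numeric",
                        r_pet = "numeric",
                        r_ct = "numeric"))

setValidity("SelectionReport", function(object) {
  if (length(intersect(object@final_features,
                       object@dropped_redundant$feature)) > 0)
    return("final features overlap the redundant set")
  if (!setequal(object@final_features,
                setdiff(object@kept_after_icc,
                        object@dropped_redundant$feature)))
    return("final_features must equal kept_after_icc minus dropped_redundant")
  TRUE
})

setMethod("show", "SelectionReport", function(object) {
  cat("SelectionReport:",
      length(object@kept_after_icc), "reproducible features;",
      nrow(object@dropped_redundant), "removed as redundant;",
      length(object@final_features), "retained\n")
})

#' Final selected feature names
#' @param report a \linkS4class{SelectionReport}.
#' @return character vector.
#' @export
selectedFeatures <- function(report) report@final_features

#' Intraclass correlation coefficient, ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-rater ICC for two
#' raters, computed from the two-way ANOVA mean squares: with n subjects and
#' k = 2 raters,
#' \deqn{ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n).}
#'
#' @param x1,x2 measurements of the same n >= 3 subjects by the two raters.
#' @return ICC value in [-1, 1] (clipped against rounding overshoot).
#' @export
icc21 <- function(x1, x2) {
  if (length(x1) != length(x2)) stop("rater vectors must have equal length")
  n <- length(x1)
  if (n < 3) stop("at least 3 subjects required")
  if (!all(is.finite(x1)) || !all(is.finite(x2))) stop("non-finite values")
  M <- cbind(x1, x2)
  k <- 2
  grand <- mean(M)
  if (var(as.vector(M)) == 0)
    stop("total variance is zero; ICC undefined")
  row_means <- rowMeans(M)
  col_means <- colMeans(M)
  MSR <- k * sum((row_means - grand)^2) / (n - 1)
  MSC <- n * sum((col_means - grand)^2) / (k - 1)
  SSE <- sum((M - outer(row_means, rep(1, k)) -
                outer(rep(1, n), col_means) + grand)^2)
  MSE <- SSE / ((n - 1) * (k - 1))
  icc <- (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
  max(-1, min(1, icc))
}

#' Keep features whose between-rater ICC exceeds a threshold
#'
#' @param X1,X2 same-shape patients-by-features matrices from the two raters
#'   (same feature order).
#' @param threshold features are kept iff ICC(2,1) is strictly greater than
#'   this (default 0.75).
#' @return a \linkS4class{SelectionReport} with the ICC stage filled in and an
#'   empty redundancy stage.
#' @export
filterByICC <- function(X1, X2, threshold = 0.75) {
  X1 <- as.matrix(X1); X2 <- as.matrix(X2)
  if (!all(dim(X1) == dim(X2)))
    stop("rater matrices must have the same shape")
  if (!identical(colnames(X1), colnames(X2)))
    stop("rater matrices must have the same feature order")
  icc <- vapply(seq_len(ncol(X1)),
                function(j) icc21(X1[, j], X2[, j]), numeric(1))
  names(icc) <- colnames(X1)
  kept <- colnames(X1)[icc > threshold]
  new("SelectionReport", icc_per_feature = icc, kept_after_icc = kept,
      dropped_redundant = data.frame(feature = character(0),
                                     partner = character(0),
                                     abs_r = numeric(0)),
      final_features = kept, icc_threshold = threshold,
      r_pet = NA_real_, r_ct = NA_real_)
}

# Greedy within-modality redundancy pruning: while any pair violates the
# modality threshold, drop (among features in a violating pair) the feature
# with the largest mean absolute correlation to all remaining features of the
# same modality; ties broken by later column index.
pruneModality <- function(R, threshold, col_index) {
  keep <- seq_len(nrow(R))
  dropped <- data.frame(feature = character(0), partner = character(0),
                        abs_r = numeric(0))
  repeat {
    if (length(keep) < 2) break
    sub <- abs(R[keep, keep, drop = FALSE])
    diag(sub) <- 0
    viol <- which(sub >= threshold, arr.ind = TRUE)
    if (nrow(viol) == 0) break
    cand <- unique(viol[, 1])
    mean_abs <- rowSums(sub[cand, , drop = FALSE]) / (length(keep) - 1)
    best <- cand[mean_abs == max(mean_abs)]
    # tie-break: later original column index
    drop_local <- best[which.max(col_index[keep[best]])]
    partners <- viol[viol[, 1] == drop_local, 2]
    top_partner <- partners[which.max(sub[drop_local, partners])]
    dropped <- rbind(dropped, data.frame(
      feature = rownames(R)[keep[drop_local]],
      partner = rownames(R)[keep[top_partner]],
      abs_r = sub[drop_local, top_partner]))
    keep <- keep[-drop_local]
  }
  list(keep = rownames(R)[keep], dropped = dropped)
}

#' Remove redundant features by modality-specific Pearson thresholds
#'
#' Computes the pairwise Pearson correlation matrix within each modality and
#' greedily removes features until no within-modality pair has |r| at or
#' above its modality threshold. Zero-variance features are dropped first
#' (Pearson undefined) and reported via a message.
#'
#' @param X patients-by-features matrix with PET_/CT_ column-name prefixes.
#' @param threshold_pet,threshold_ct absolute-correlation thresholds
#'   (defaults 0.76 and 0.40).
#' @return a \linkS4class{SelectionReport} (ICC stage empty).
#' @export
pruneCorrelated <- function(X, threshold_pet = 0.76, threshold_ct = 0.40) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("at least two patients required")
  mod <- modalityFromNames(colnames(X))
  zero_var <- apply(X, 2, var) == 0
  if (any(zero_var)) {
    message("dropping ", sum(zero_var), " zero-variance feature(s): ",
            paste(utils::head(colnames(X)[zero_var], 5), collapse = ", "))
    X <- X[, !zero_var, drop = FALSE]
    mod <- mod[!zero_var]
  }
  dropped <- data.frame(feature = character(0), partner = character(0),
                        abs_r = numeric(0))
  keep <- character(0)
  for (m in c("PET", "CT")) {
    idx <- which(mod == m)
    if (length(idx) == 0) next
    thr <- if (m == "PET") threshold_pet else threshold_ct
    if (length(idx) == 1) { keep <- c(keep, colnames(X)[idx]); next }
    R <- cor(X[, idx, drop = FALSE])
    res <- pruneModality(R, thr, col_index = idx)
    keep <- c(keep, res$keep)
    dropped <- rbind(dropped, res$dropped)
  }
  keep <- colnames(X)[colnames(X) %in% keep]  # original order
  new("SelectionReport",
      icc_per_feature = setNames(rep(NA_real_, ncol(X)), colnames(X)),
      kept_after_icc = colnames(X), dropped_redundant = dropped,
      final_features = keep, icc_threshold = NA_real_,
      r_pet = threshold_pet, r_ct = threshold_ct)
}

#' Full reproducibility + redundancy feature selection
#'
#' Applies the ICC filter (strictly greater than \code{icc_threshold}) and
#' then the within-modality correlation pruning to the surviving features.
#'
#' @param X1 patients-by-features matrix (rater 1) or a
#'   \linkS4class{RadiomicCohort} carrying a \code{rater2} assay.
#' @param X2 rater-2 matrix; ignored when \code{X1} is a cohort.
#' @param icc_threshold,threshold_pet,threshold_ct stage thresholds.
#' @return a \linkS4class{SelectionReport} covering both stages.
#' @export
selectFeatures <- function(X1, X2 = NULL, icc_threshold = 0.75,
                           threshold_pet = 0.76, threshold_ct = 0.40) {
  if (is(X1, "RadiomicCohort")) {
    X2 <- raterValues(X1)
    X1 <- featureValues(X1)
    if (is.null(X2)) stop("cohort has no rater2 assay for ICC filtering")
  }
  icc_rep <- filterByICC(X1, X2, threshold = icc_threshold)
  kept <- icc_rep@kept_after_icc
  if (length(kept) == 0)
    stop("no feature survived the ICC threshold")
  prune_rep <- pruneCorrelated(X1[, kept, drop = FALSE],
                               threshold_pet, threshold_ct)
  new("SelectionReport", icc_per_feature = icc_rep@icc_per_feature,
      kept_after_icc = kept,
      dropped_redundant = prune_rep@dropped_redundant,
      final_features = prune_rep@final_features,
      icc_threshold = icc_threshold, r_pet = threshold_pet,
      r_ct = threshold_ct)
}

#' Pairwise Pearson correlation matrix of a feature table
#'
#' @param X patients-by-features matrix; zero-variance columns are an error.
#' @return symmetric F x F correlation matrix with unit diagonal.
#' @export
featureCorrelation <- function(X) {
  X <- as.matrix(X)
  v <- apply(X, 2, var)
  if (any(v == 0))
    stop("zero-variance feature(s): ",
         paste(utils::head(colnames(X)[v == 0], 5), collapse = ", "))
  R <- cor(X)
  R <- (R + t(R)) / 2
  diag(R) <- 1
  R
}

#' Export the correlation matrix to CSV
#' @param X patients-by-features matrix.
#' @param path output CSV path.
#' @return invisibly, the matrix written.
#' @export
writeCorrelationMatrix <- function(X, path) {
  R <- featureCorrelation(X)
  df <- data.frame(feature = rownames(R), apply(R, 2, fmtNum),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(R)
}
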