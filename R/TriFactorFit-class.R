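#' TriFactorFit: fitted orthogonal non-negative matrix tri-factorization
#'
#' Result of factorizing a non-negative patients-by-features matrix X as
#' X ~ A S Y with A (N x K_s) encoding patient sub-cluster membership,
#' Y (K_f x F) encoding feature sub-cluster membership, and S (K_s x K_f)
#' carrying scales and patient-group/feature-group interactions. Meta-features
#' are M = A S. Orthogonality of A (columns) and Y (rows) is encouraged by
#' the update rules and reported as residuals, not enforced exactly.
#'
#' @slot A,S,Y non-negative factor matrices.
#' @slot k_s,k_f factorization ranks.
#' @slot objective_trajectory squared Frobenius residual per iteration of the
#'   selected restart.
#' @slot orthogonality_residuals named numeric: Frobenius norms of
#'   \code{t(A) A - I} and \code{Y t(Y) - I} after column/row normalization.
#' @slot seed_used,n_restarts,converged fitting metadata.
#' @slot feature_scaling data.frame of the per-feature affine rescaling
#'   applied before fitting (empty when the input was used as-is).
#' @export
setClass("TriFactorFit",
         representation(A = "matrix", S = "matrix", Y = "matrix",
                        k_s = "integer", k_f = "integer",
                        objective_trajectory = "numeric",
                        orthogonality_residuals = "numeric",
                        seed_used = "integer", n_restarts = "integer",
                        converged = "logical",
                        feature_scaling = "data.frame"))

setValidity("TriFactorFit", function(object) {
  msg <- character(0)
  if (any(object@A < 0) || any(object@S < 0) || any(object@Y < 0))
    msg <- c(msg, "factors must be non-negative")
  if (ncol(object@A) != object@k_s || nrow(object@S) != object@k_s ||
      ncol(object@S) != object@k_f || nrow(object@Y) != object@k_f)
    msg <- c(msg, "factor shapes inconsistent with k_s/k_f")
  tr <- object@objective_trajectory
  if (length(tr) > 1) {
    # relative per-step tolerance, with an absolute guard at the problem
    # scale for steps where the objective has already hit machine zero
    slack <- 1e-9 * tr[-length(tr)] + 1e-12 * max(tr, .Machine$double.xmin)
    if (any(diff(tr) > slack))
      msg <- c(msg, "objective trajectory is not non-increasing")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "TriFactorFit", function(object) {
  cat(sprintf("TriFactorFit: %d patients x %d features, k_s = %d, k_f = %d\n",
              nrow(object@A), ncol(object@Y), object@k_s, object@k_f))
  cat(sprintf("  final objective %.6g after %d iterations (%s), %d restart(s)\n",
              utils::tail(object@objective_trajectory, 1),
              length(object@objective_trajectory),
              if (object@converged) "converged" else "max_iter reached",
              object@n_restarts))
  cat(sprintf("  orthogonality residuals: ||A'A - I||_F = %.3g, ||YY' - I||_F = %.3g\n",
              object@orthogonality_residuals["A"],
              object@orthogonality_residuals["Y"]))
})

#' @rdname metaFeatures
#' @export
setMethod("metaFeatures", "TriFactorFit", function(object) {
  M <- object@A %*% object@S
  colnames(M) <- sprintf("MF%d", seq_len(ncol(M)))
  M
})

#' @rdname patientClusters
#' @export
setMethod("patientClusters", "TriFactorFit", function(object)
  apply(object@A, 1, which.max))

#' @rdname featureClusters
#' @export
setMethod("featureClusters", "TriFactorFit", function(object)
  apply(object@Y, 2, which.max))

#' Objective trajectory accessor
#' @param object a \linkS4class{TriFactorFit}.
#' @return numeric vector of per-iteration objective values.
#' @export
objectiveTrajectory <- function(object) object@objective_trajectory

#' Orthogonality residual accessor
#' @param object a \linkS4class{TriFactorFit}.
#' @return named numeric vector (\code{A}, \code{Y}).
#' @export
orthogonalityResiduals <- function(object) object@orthogonality_residuals

#' Factor accessors
#' @param object a \linkS4class{TriFactorFit}.
#' @return the requested factor matrix.
#' @export
factorA <- function(object) object@A

#' @rdname factorA
#' @export
factorS <- function(object) object@S

#' @rdname factorA
#' @export
factorY <- function(object) object@Y
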