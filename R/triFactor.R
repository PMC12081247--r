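#' Per-feature min-max rescaling to the unit interval
#'
#' The tri-factorization requires a matrix approximable by non-negative
#' factors; radiomic features (e.g. skewness) can be negative, so each
#' feature is affinely mapped to [0, 1]. Constant features map to all-zeros.
#' The affine parameters are stored in the \code{"scaling"} attribute and can
#' be re-applied to new patients with \code{\link{applyScaling}}.
#'
#' @param X patients-by-features numeric matrix.
#' @return rescaled matrix with attribute \code{scaling}: data.frame
#'   (feature, min, range).
#' @export
rescaleUnitInterval <- function(X) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("non-finite values in feature matrix")
  mins <- apply(X, 2, min)
  ranges <- apply(X, 2, max) - mins
  div <- ifelse(ranges == 0, 1, ranges)
  out <- sweep(sweep(X, 2, mins), 2, div, "/")
  out[, ranges == 0] <- 0
  attr(out, "scaling") <- data.frame(
    feature = colnames(X) %||% as.character(seq_len(ncol(X))),
    min = mins, range = ranges, row.names = NULL)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply a stored min-max scaling to new rows
#'
#' Values are clamped to [0, 1] so projected patients stay within the
#' non-negative domain of the factorization.
#'
#' @param X new patients-by-features matrix (same feature order as the
#'   training matrix).
#' @param scaling the \code{scaling} attribute of
#'   \code{\link{rescaleUnitInterval}} output.
#' @return rescaled matrix.
#' @export
applyScaling <- function(X, scaling) {
  X <- as.matrix(X)
  if (ncol(X) != nrow(scaling)) stop("feature count mismatch")
  div <- ifelse(scaling$range == 0, 1, scaling$range)
  out <- sweep(sweep(X, 2, scaling$min), 2, div, "/")
  out[, scaling$range == 0] <- 0
  pmin(pmax(out, 0), 1)
}

#' Tri-factorization objective
#'
#' Squared Frobenius norm of the residual, \code{||X - A S Y||_F^2}.
#'
#' @param X data matrix (N x F).
#' @param A,S,Y conformable factor matrices (N x K_s, K_s x K_f, K_f x F).
#' @return non-negative scalar.
#' @export
triFactorObjective <- function(X, A, S, Y) {
  if (nrow(A) != nrow(X) || ncol(A) != nrow(S) ||
      ncol(S) != nrow(Y) || ncol(Y) != ncol(X))
    stop("factor shapes are not conformable with X")
  sum((X - A %*% S %*% Y)^2)
}

# One alternating-optimization run of the non-negative tri-factorization.
# Each factor is updated by the multiplicative ratio rule of its conditional
# least-squares subproblem (updating A with S, Y fixed is a standard NMF
# step for X ~ A(SY), and likewise for Y and S), so every step provably does
# not increase ||X - ASY||_F^2 and preserves non-negativity. After each
# iteration the column scales of A and row scales of Y are absorbed into S,
# which leaves the objective unchanged and keeps the factors on the
# normalized scale on which the (soft) orthogonality residuals are measured.
# A small epsilon guards the ratio denominators.
onmtfRun <- function(X, A, S, Y, max_iter, tol, eps = 1e-12) {
  trajectory <- numeric(max_iter + 1)
  converged <- FALSE
  it <- 0
  # membership supports from the initialization; entries inside the support
  # are kept at a negligible positive floor so an all-zero data row retains
  # its seeded cluster membership instead of decaying to an untyped zero row
  supA <- A > 0
  supY <- Y > 0
  floor_m <- 1e-10
  prev_obj <- sum((X - A %*% S %*% Y)^2)
  trajectory[1] <- prev_obj   # objective at initialization
  while (it < max_iter) {
    SY <- S %*% Y
    A <- A * (X %*% t(SY)) / (A %*% tcrossprod(SY) + eps)
    A[supA & A < floor_m] <- floor_m
    AS <- A %*% S
    Y <- Y * (t(AS) %*% X) / (crossprod(AS) %*% Y + eps)
    Y[supY & Y < floor_m] <- floor_m
    AtA <- crossprod(A); YYt <- tcrossprod(Y)
    S <- S * (t(A) %*% X %*% t(Y)) / (AtA %*% S %*% YYt + eps)
    # objective-invariant rescaling: unit-norm columns of A, rows of Y
    da <- pmax(sqrt(colSums(A^2)), eps)
    dy <- pmax(sqrt(rowSums(Y^2)), eps)
    A <- sweep(A, 2, da, "/")
    Y <- sweep(Y, 1, dy, "/")
    S <- diag(da, nrow = length(da)) %*% S %*% diag(dy, nrow = length(dy))
    obj <- sum((X - A %*% S %*% Y)^2)
    it <- it + 1
    trajectory[it + 1] <- obj
    if (abs(prev_obj - obj) <= tol * max(prev_obj, eps)) {
      converged <- TRUE
      break
    }
    prev_obj <- obj
  }
  list(A = A, S = S, Y = Y, trajectory = trajectory[seq_len(it + 1)],
       converged = converged)
}

# Clustering-seeded initialization: k-means on rows and columns gives
# indicator A and Y. With exact-zero off-support entries the columns of A
# (and rows of Y) have disjoint supports, so the orthogonality constraints
# hold exactly and are preserved by the multiplicative updates, which then
# only optimize the non-zero magnitudes (per-patient and per-feature
# scales). S is the clipped least-squares coupling.
initKmeans <- function(X, k_s, k_f, floor = 0, nstart = 5) {
  rl <- kmeans(X, centers = k_s, nstart = nstart)$cluster
  cl <- kmeans(t(X), centers = k_f, nstart = nstart)$cluster
  A <- matrix(floor, nrow(X), k_s)
  A[cbind(seq_len(nrow(X)), rl)] <- 1
  Y <- matrix(floor, k_f, ncol(X))
  Y[cbind(cl, seq_len(ncol(X)))] <- 1
  S <- tryCatch(
    solve(crossprod(A), t(A) %*% X %*% t(Y) %*% solve(tcrossprod(Y))),
    error = function(e) matrix(mean(X), k_s, k_f))
  S <- pmax(S, 1e-6)
  list(A = A, S = S, Y = Y)
}

#' @describeIn fitTriFactor fit on a non-negative patients-by-features matrix.
#'
#' Runs \code{n_restarts} independently seeded alternating-optimization runs
#' and returns the one with the lowest final objective. Every restart is
#' clustering-seeded (a fresh randomly started k-means on patients and on
#' features defines the orthogonal supports of A and Y), so restarts explore
#' different co-cluster configurations while staying in the same constraint
#' class and their objectives are directly comparable. A run stops when the
#' relative objective change drops below \code{tol} or after \code{max_iter}
#' iterations.
#'
#' @param max_iter maximum iterations per restart (default 500).
#' @param tol relative objective-change convergence tolerance (default 1e-6).
#' @param n_restarts number of restarts (default 10).
#' @param seed master seed; restart r uses sub-seed r.
#' @param rescale rescale the input with \code{\link{rescaleUnitInterval}}
#'   first (default TRUE; set FALSE when the matrix is already scaled).
#' @export
setMethod("fitTriFactor", "matrix",
  function(x, k_s, k_f, max_iter = 500, tol = 1e-6, n_restarts = 10,
           seed = 1L, rescale = TRUE) {
    if (k_s < 2 || k_s > nrow(x)) stop("k_s out of range [2, N]")
    if (k_f < 2 || k_f > ncol(x)) stop("k_f out of range [2, F]")
    scaling <- data.frame()
    if (rescale) {
      x <- rescaleUnitInterval(x)
      scaling <- attr(x, "scaling")
    }
    if (any(x < 0)) stop("input must be non-negative (use rescale = TRUE)")
    if (all(x == 0)) stop("all-zero input matrix")
    best <- NULL
    for (r in seq_len(n_restarts)) {
      run <- withSeed(subSeed(seed, paste0("restart", r)), {
        init <- initKmeans(x, k_s, k_f, nstart = 1)
        onmtfRun(x, init$A, init$S, init$Y, max_iter = max_iter, tol = tol)
      })
      if (is.null(best) ||
          utils::tail(run$trajectory, 1) < utils::tail(best$trajectory, 1))
        best <- run
    }
    # report orthogonality on scale-normalized factors (column/row scaling is
    # absorbed by S, so residuals measure structure, not magnitude)
    An <- sweep(best$A, 2, pmax(sqrt(colSums(best$A^2)), 1e-12), "/")
    Yn <- sweep(best$Y, 1, pmax(sqrt(rowSums(best$Y^2)), 1e-12), "/")
    ortho <- c(A = norm(crossprod(An) - diag(k_s), "F"),
               Y = norm(tcrossprod(Yn) - diag(k_f), "F"))
    A <- best$A
    rownames(A) <- rownames(x)
    Y <- best$Y
    colnames(Y) <- colnames(x)
    new("TriFactorFit", A = A, S = best$S, Y = Y,
        k_s = as.integer(k_s), k_f = as.integer(k_f),
        objective_trajectory = best$trajectory,
        orthogonality_residuals = ortho,
        seed_used = as.integer(seed), n_restarts = as.integer(n_restarts),
        converged = best$converged, feature_scaling = scaling)
  })

#' @describeIn fitTriFactor fit on the feature assay of a cohort.
#' @export
setMethod("fitTriFactor", "RadiomicCohort",
  function(x, k_s, k_f, ...) fitTriFactor(featureValues(x), k_s, k_f, ...))

#' Project new patients onto a fitted factorization
#'
#' Fold-honest transform for held-out patients: with Y and S fixed from the
#' training fit, each new patient row x solves the non-negative least-squares
#' problem min ||x - a (S Y)||^2, a >= 0, giving its membership row a and
#' meta-features m = a S.
#'
#' @param fit a \linkS4class{TriFactorFit} from training data.
#' @param Xnew new patients-by-features matrix on the training feature set;
#'   if the fit stored a feature scaling it is applied first.
#' @return list with \code{A} (rows of memberships) and \code{M}
#'   (meta-features, rows aligned to \code{Xnew}).
#' @export
projectPatients <- function(fit, Xnew) {
  Xnew <- as.matrix(Xnew)
  if (nrow(fit@feature_scaling) > 0)
    Xnew <- applyScaling(Xnew, fit@feature_scaling)
  SY <- fit@S %*% fit@Y            # k_s x F
  C <- t(SY)                       # F x k_s
  Anew <- t(apply(Xnew, 1, function(xr)
    pracma::lsqnonneg(C, as.numeric(xr))$x))
  if (fit@k_s == 1) Anew <- matrix(Anew, ncol = 1)
  M <- Anew %*% fit@S
  colnames(M) <- sprintf("MF%d", seq_len(ncol(M)))
  rownames(M) <- rownames(Xnew)
  list(A = Anew, M = M)
}
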