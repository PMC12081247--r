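#' @importFrom stats rnorm runif rbinom rexp sd var cor pchisq prcomp kmeans
#'   setNames aggregate uniroot
#' @importFrom methods new validObject is slot setValidity show
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData colData
#' @importFrom S4Vectors DataFrame metadata
NULL

# Derive a reproducible sub-seed (< 2^31) from a master seed and a component
# tag, so adding a stochastic component never perturbs the streams of others.
subSeed <- function(seed, tag) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  codes <- utf8ToInt(tag)
  h <- sum(codes * seq_along(codes)) %% 65521
  as.integer((abs(seed) %% 1000003) * 2011 + h * 7919) %% 2147483563L
}

# Run an expression under a local RNG state (restores the caller's stream).
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Lognormal meanlog/sdlog from a target arithmetic mean and sd.
lognormalParams <- function(m, s) {
  sigma2 <- log(1 + (s / m)^2)
  list(meanlog = log(m) - sigma2 / 2, sdlog = sqrt(sigma2))
}

# Modality tag from a feature name prefix ("PET_" / "CT_").
modalityFromNames <- function(feature_names) {
  mod <- rep(NA_character_, length(feature_names))
  mod[startsWith(feature_names, "PET_")] <- "PET"
  mod[startsWith(feature_names, "CT_")] <- "CT"
  if (anyNA(mod)) {
    bad <- feature_names[is.na(mod)]
    stop("unknown modality prefix for feature(s): ",
         paste(utils::head(bad, 5), collapse = ", "),
         "; feature names must start with 'PET_' or 'CT_'")
  }
  mod
}

# Balanced deterministic label assignment shuffled under the active RNG.
balancedLabels <- function(n, k) {
  sample(rep_len(seq_len(k), n))
}
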