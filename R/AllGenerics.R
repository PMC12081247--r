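#' @title Package generics
#' @name triSurv-generics
#' @keywords internal
NULL

#' Extract the patients-by-features value matrix
#'
#' @param x a \linkS4class{RadiomicCohort} object.
#' @return numeric matrix, patients in rows, features in columns.
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' Extract the second-rater replicate matrix
#'
#' @param x a \linkS4class{RadiomicCohort}.
#' @return numeric matrix (patients x features) or NULL when absent.
#' @export
setGeneric("raterValues", function(x) standardGeneric("raterValues"))

#' Extract the clinical covariate table
#'
#' @param x a \linkS4class{RadiomicCohort}.
#' @return data.frame of per-patient clinical covariates.
#' @export
setGeneric("clinicalTable", function(x) standardGeneric("clinicalTable"))

#' Extract survival follow-up
#'
#' @param x a \linkS4class{RadiomicCohort}.
#' @return data.frame with patient_id, time_months, event.
#' @export
setGeneric("survivalData", function(x) standardGeneric("survivalData"))

#' True (generator) patient group labels, if present
#' @param x a \linkS4class{RadiomicCohort}.
#' @return integer vector or NULL.
#' @export
setGeneric("truePatientLabels", function(x) standardGeneric("truePatientLabels"))

#' True (generator) feature group labels, if present
#' @param x a \linkS4class{RadiomicCohort}.
#' @return integer vector or NULL.
#' @export
setGeneric("trueFeatureLabels", function(x) standardGeneric("trueFeatureLabels"))

#' Per-feature modality tag
#' @param x a \linkS4class{RadiomicCohort}.
#' @return character vector ("PET"/"CT") aligned to features.
#' @export
setGeneric("featureModality", function(x) standardGeneric("featureModality"))

#' Fit the orthogonal non-negative tri-factorization
#'
#' @param x patients-by-features matrix (rescaled to be non-negative) or a
#'   \linkS4class{RadiomicCohort}.
#' @param k_s number of patient sub-clusters (>= 2).
#' @param k_f number of feature sub-clusters / meta-features (>= 2).
#' @param ... further arguments; see the matrix method.
#' @return a \linkS4class{TriFactorFit}.
#' @export
setGeneric("fitTriFactor", function(x, k_s, k_f, ...)
  standardGeneric("fitTriFactor"))

#' Meta-feature matrix M = A S
#' @param object a \linkS4class{TriFactorFit}.
#' @return non-negative numeric matrix, patients x k_f.
#' @export
setGeneric("metaFeatures", function(object) standardGeneric("metaFeatures"))

#' Hard patient cluster labels from the A factor
#' @param object a \linkS4class{TriFactorFit}.
#' @return integer vector in 1..k_s (row-maximum rule, ties to lowest index).
#' @export
setGeneric("patientClusters", function(object) standardGeneric("patientClusters"))

#' Hard feature cluster labels from the Y factor
#' @param object a \linkS4class{TriFactorFit}.
#' @return integer vector in 1..k_f (column-maximum rule, ties to lowest index).
#' @export
setGeneric("featureClusters", function(object) standardGeneric("featureClusters"))

#' Predict a mortality risk score
#'
#' Higher scores always mean higher predicted risk of death.
#'
#' @param object a fitted \linkS4class{RiskModel}.
#' @param newdata matrix or data.frame with the model's features as columns.
#' @return numeric risk score per row of \code{newdata}.
#' @export
setGeneric("predictRisk", function(object, newdata) standardGeneric("predictRisk"))
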