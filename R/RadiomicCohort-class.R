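#' RadiomicCohort: a patients-by-features cohort with survival follow-up
#'
#' Container for a radiomic study cohort, built on
#' \link[SummarizedExperiment]{SummarizedExperiment}. Following the
#' Bioconductor convention, features are stored in rows and patients in
#' columns of the assay; the user-facing accessors (\code{featureValues},
#' \code{raterValues}) return the transposed, patients-by-features
#' orientation that the statistical pipeline works in.
#'
#' Assays: \code{"features"} (required) and optionally \code{"rater2"}, a
#' second-rater replicate used for intraclass-correlation filtering.
#' \code{rowData} carries the per-feature \code{modality} ("PET"/"CT") and,
#' for simulated cohorts, \code{true_feature_label}. \code{colData} carries
#' the clinical covariates plus \code{time_months} (overall survival, months)
#' and \code{event} (1 = death observed), and for simulated cohorts
#' \code{true_patient_label}.
#'
#' @aliases RadiomicCohort-class
#' @export
setClass("RadiomicCohort", contains = "SummarizedExperiment")

setValidity("RadiomicCohort", function(object) {
  msg <- character(0)
  anames <- SummarizedExperiment::assayNames(object)
  if (!("features" %in% anames))
    msg <- c(msg, "assay 'features' is required")
  else {
    X <- SummarizedExperiment::assay(object, "features")
    if (!is.numeric(X)) msg <- c(msg, "'features' assay must be numeric")
    if (anyNA(X)) msg <- c(msg, "'features' assay contains missing values")
  }
  if ("rater2" %in% anames) {
    X2 <- SummarizedExperiment::assay(object, "rater2")
    if (anyNA(X2)) msg <- c(msg, "'rater2' assay contains missing values")
  }
  rd <- SummarizedExperiment::rowData(object)
  if (!("modality" %in% colnames(rd)))
    msg <- c(msg, "rowData must carry a 'modality' column")
  else if (!all(rd$modality %in% c("PET", "CT")))
    msg <- c(msg, "modality must be 'PET' or 'CT'")
  cd <- SummarizedExperiment::colData(object)
  if (all(c("time_months", "event") %in% colnames(cd))) {
    if (any(cd$time_months <= 0)) msg <- c(msg, "time_months must be > 0")
    if (!all(cd$event %in% c(0, 1))) msg <- c(msg, "event must be 0/1")
  } else {
    msg <- c(msg, "colData must carry 'time_months' and 'event'")
  }
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicated patient ids")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicated feature names")
  if (length(msg)) msg else TRUE
})

#' Construct a RadiomicCohort
#'
#' @param features patients-by-features numeric matrix; column names must
#'   carry a \code{"PET_"} or \code{"CT_"} prefix, row names are patient ids.
#' @param clinical data.frame of clinical covariates, one row per patient in
#'   the same order as \code{features}.
#' @param time_months positive survival/censoring times in months.
#' @param event 0/1 event indicator (1 = death observed).
#' @param rater2 optional replicate matrix of the same shape as
#'   \code{features} (second reader's delineation).
#' @param true_patient_label,true_feature_label optional generator truth.
#' @param metadata list stored in the object metadata (e.g. generator config).
#' @return a \linkS4class{RadiomicCohort}.
#' @export
RadiomicCohort <- function(features, clinical = NULL, time_months, event,
                           rater2 = NULL, true_patient_label = NULL,
                           true_feature_label = NULL, metadata = list()) {
  features <- as.matrix(features)
  if (is.null(rownames(features)))
    rownames(features) <- sprintf("P%03d", seq_len(nrow(features)))
  if (is.null(colnames(features)))
    stop("feature columns must be named (PET_/CT_ prefixes)")
  modality <- modalityFromNames(colnames(features))
  assays <- list(features = t(features))
  if (!is.null(rater2)) {
    rater2 <- as.matrix(rater2)
    if (!all(dim(rater2) == dim(features)))
      stop("rater2 must have the same shape as features")
    dimnames(rater2) <- dimnames(features)
    assays$rater2 <- t(rater2)
  }
  cd <- if (is.null(clinical)) {
    S4Vectors::DataFrame(row.names = rownames(features))
  } else {
    S4Vectors::DataFrame(clinical, row.names = rownames(features))
  }
  cd$time_months <- as.numeric(time_months)
  cd$event <- as.numeric(event)
  if (!is.null(true_patient_label)) cd$true_patient_label <- as.integer(true_patient_label)
  rd <- S4Vectors::DataFrame(modality = modality, row.names = colnames(features))
  if (!is.null(true_feature_label)) rd$true_feature_label <- as.integer(true_feature_label)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays, rowData = rd, colData = cd, metadata = metadata)
  new("RadiomicCohort", se)
}

#' @rdname featureValues
#' @export
setMethod("featureValues", "RadiomicCohort", function(x)
  t(SummarizedExperiment::assay(x, "features")))

#' @rdname raterValues
#' @export
setMethod("raterValues", "RadiomicCohort", function(x) {
  if (!("rater2" %in% SummarizedExperiment::assayNames(x))) return(NULL)
  t(SummarizedExperiment::assay(x, "rater2"))
})

#' @rdname clinicalTable
#' @export
setMethod("clinicalTable", "RadiomicCohort", function(x) {
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  drop <- intersect(c("time_months", "event", "true_patient_label"), colnames(cd))
  cd[setdiff(colnames(cd), drop)]
})

#' @rdname survivalData
#' @export
setMethod("survivalData", "RadiomicCohort", function(x) {
  cd <- SummarizedExperiment::colData(x)
  data.frame(patient_id = colnames(x),
             time_months = cd$time_months,
             event = cd$event,
             stringsAsFactors = FALSE)
})

#' @rdname truePatientLabels
#' @export
setMethod("truePatientLabels", "RadiomicCohort", function(x) {
  cd <- SummarizedExperiment::colData(x)
  if ("true_patient_label" %in% colnames(cd)) as.integer(cd$true_patient_label) else NULL
})

#' @rdname trueFeatureLabels
#' @export
setMethod("trueFeatureLabels", "RadiomicCohort", function(x) {
  rd <- SummarizedExperiment::rowData(x)
  if ("true_feature_label" %in% colnames(rd)) as.integer(rd$true_feature_label) else NULL
})

#' @rdname featureModality
#' @export
setMethod("featureModality", "RadiomicCohort", function(x)
  as.character(SummarizedExperiment::rowData(x)$modality))

setMethod("show", "RadiomicCohort", function(object) {
  cat("RadiomicCohort with", ncol(object), "patients and",
      nrow(object), "features\n")
  mod <- featureModality(object)
  cat("  modality: ", sum(mod == "PET"), " PET, ", sum(mod == "CT"), " CT\n",
      sep = "")
  cat("  rater replicate:",
      if ("rater2" %in% SummarizedExperiment::assayNames(object)) "yes" else "no",
      "\n")
  cd <- SummarizedExperiment::colData(object)
  cat(sprintf("  events: %d/%d; follow-up %.1f-%.1f months\n",
              sum(cd$event), ncol(object),
              min(cd$time_months), max(cd$time_months)))
  if (!is.null(truePatientLabels(object)))
    cat("  generator truth labels present\n")
})
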