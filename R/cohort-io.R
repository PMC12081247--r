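## CSV ingestion and serialization. All tables are UTF-8 CSV with a header
## row; numeric values are serialized with %.17g so write/read round-trips
## are bit-exact.

fmtNum <- function(x) sprintf("%.17g", x)

writeNumericCSV <- function(M, path, id_col = "patient_id") {
  df <- data.frame(rownames(M), apply(M, 2, fmtNum), check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c(id_col, colnames(M))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

readNumericCSV <- function(path, id_col = "patient_id") {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (colnames(df)[1] != id_col)
    stop("first column of ", path, " must be '", id_col, "'")
  M <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(M) <- "double"
  rownames(M) <- df[[1]]
  M
}

#' Write a cohort to a directory of plain-text files
#'
#' Emits \code{features.csv}, \code{features_rater2.csv}, \code{clinical.csv},
#' \code{survival.csv}, \code{truth.csv} and \code{config.txt}; numeric
#' values round-trip bit-exactly through \code{\link{readCohort}}.
#'
#' @param cohort a \linkS4class{RadiomicCohort}.
#' @param dir output directory (created if absent).
#' @param overwrite allow writing into a non-empty directory.
#' @return invisibly, the manifest: character vector of files written.
#' @export
writeCohort <- function(cohort, dir, overwrite = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !overwrite)
    stop("directory ", dir, " is not empty; use overwrite = TRUE")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  X <- featureValues(cohort)
  writeNumericCSV(X, file.path(dir, "features.csv"))
  X2 <- raterValues(cohort)
  if (is.null(X2)) X2 <- X
  writeNumericCSV(X2, file.path(dir, "features_rater2.csv"))

  clin <- clinicalTable(cohort)
  clin_out <- data.frame(patient_id = colnames(cohort),
                         lapply(clin, fmtNum),
                         stringsAsFactors = FALSE, check.names = FALSE)
  utils::write.csv(clin_out, file.path(dir, "clinical.csv"),
                   row.names = FALSE, quote = FALSE)

  surv <- survivalData(cohort)
  surv_out <- data.frame(patient_id = surv$patient_id,
                         time_months = fmtNum(surv$time_months),
                         event = as.integer(surv$event))
  utils::write.csv(surv_out, file.path(dir, "survival.csv"),
                   row.names = FALSE, quote = FALSE)

  pl <- truePatientLabels(cohort)
  fl <- trueFeatureLabels(cohort)
  truth <- data.frame(
    id = c(colnames(cohort), rownames(cohort)),
    kind = c(rep("patient", ncol(cohort)), rep("feature", nrow(cohort))),
    label = c(if (is.null(pl)) rep(NA_integer_, ncol(cohort)) else pl,
              if (is.null(fl)) rep(NA_integer_, nrow(cohort)) else fl))
  utils::write.csv(truth, file.path(dir, "truth.csv"),
                   row.names = FALSE, quote = FALSE)

  cfg <- S4Vectors::metadata(cohort)$config
  lines <- if (is.null(cfg)) character(0) else
    vapply(names(cfg), function(k) {
      v <- cfg[[k]]
      val <- if (is.numeric(v)) paste(fmtNum(v), collapse = ",")
             else paste(v, collapse = ",")
      paste0(k, "=", val)
    }, character(1))
  writeLines(lines, file.path(dir, "config.txt"))

  manifest <- c("features.csv", "features_rater2.csv", "clinical.csv",
                "survival.csv", "truth.csv", "config.txt")
  invisible(file.path(dir, manifest))
}

#' Read a cohort written by \code{\link{writeCohort}}
#'
#' @param dir directory containing the cohort files.
#' @return a \linkS4class{RadiomicCohort}.
#' @export
readCohort <- function(dir) {
  X <- readFeatureTable(file.path(dir, "features.csv"))
  X2 <- readFeatureTable(file.path(dir, "features_rater2.csv"))
  attr(X, "modality_counts") <- NULL
  attr(X2, "modality_counts") <- NULL
  cs <- readClinicalSurvival(file.path(dir, "clinical.csv"),
                             file.path(dir, "survival.csv"),
                             patient_ids = rownames(X))
  truth <- utils::read.csv(file.path(dir, "truth.csv"),
                           stringsAsFactors = FALSE)
  pl <- truth$label[truth$kind == "patient"]
  fl <- truth$label[truth$kind == "feature"]
  cfg_lines <- readLines(file.path(dir, "config.txt"))
  cfg <- list()
  for (ln in cfg_lines[nzchar(cfg_lines)]) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    vals <- strsplit(kv[2], ",", fixed = TRUE)[[1]]
    num <- suppressWarnings(as.numeric(vals))
    cfg[[kv[1]]] <- if (anyNA(num)) vals else num
  }
  RadiomicCohort(features = X, clinical = cs$clinical,
                 time_months = cs$survival$time_months,
                 event = cs$survival$event, rater2 = X2,
                 true_patient_label = if (all(is.na(pl))) NULL else pl,
                 true_feature_label = if (all(is.na(fl))) NULL else fl,
                 metadata = list(config = cfg))
}

#' Read and validate a patients-by-features table
#'
#' CSV with a header; first column \code{patient_id}; remaining columns are
#' numeric feature values with \code{PET_}/\code{CT_} name prefixes. Missing
#' or non-numeric cells are an error naming the offending cells.
#'
#' @param path CSV file path.
#' @return numeric matrix with patient ids as row names; per-modality feature
#'   counts are attached as attribute \code{"modality_counts"}.
#' @export
readFeatureTable <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (colnames(df)[1] != "patient_id")
    stop("first column must be 'patient_id'")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stop("duplicate patient ids in ", path)
  if (anyDuplicated(colnames(df)[-1])) stop("duplicate feature names in ", path)
  M <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(storage.mode(M) <- "double")
  if (anyNA(M)) {
    bad <- which(is.na(M), arr.ind = TRUE)
    bad <- utils::head(bad, 10)
    stop("missing/non-numeric cells in ", path, ": ",
         paste(sprintf("(row %s, column %s)", ids[bad[, 1]],
                       colnames(M)[bad[, 2]]), collapse = "; "))
  }
  rownames(M) <- ids
  mod <- modalityFromNames(colnames(M))
  attr(M, "modality_counts") <- table(mod)
  M
}

#' Read clinical and survival tables aligned to a patient ordering
#'
#' Types are checked, patient ids aligned (error on mismatch), times must be
#' positive and events 0/1. The neutrophil-to-lymphocyte ratio is recomputed
#' as NC/LC and cross-checked against any provided \code{nlr} column; a
#' discrepancy above 1e-6 raises a warning.
#'
#' @param clinical_path,survival_path CSV paths.
#' @param patient_ids optional canonical patient order (e.g. from the feature
#'   table); both tables are reordered to it.
#' @return list with elements \code{clinical} (data.frame) and \code{survival}
#'   (data.frame: patient_id, time_months, event).
#' @export
readClinicalSurvival <- function(clinical_path, survival_path,
                                 patient_ids = NULL) {
  clin <- utils::read.csv(clinical_path, stringsAsFactors = FALSE)
  surv <- utils::read.csv(survival_path, stringsAsFactors = FALSE)
  for (d in list(clin, surv))
    if (!("patient_id" %in% colnames(d)))
      stop("tables must carry a 'patient_id' column")
  if (is.null(patient_ids)) patient_ids <- sort(clin$patient_id)
  for (nm in c("clinical", "survival")) {
    d <- if (nm == "clinical") clin else surv
    missing <- setdiff(patient_ids, d$patient_id)
    if (length(missing))
      stop("patients absent from the ", nm, " table: ",
           paste(utils::head(missing, 5), collapse = ", "))
  }
  clin <- clin[match(patient_ids, clin$patient_id), , drop = FALSE]
  surv <- surv[match(patient_ids, surv$patient_id), , drop = FALSE]
  if (!all(c("time_months", "event") %in% colnames(surv)))
    stop("survival table must have time_months and event columns")
  if (any(surv$time_months <= 0)) stop("survival times must be positive")
  if (!all(surv$event %in% c(0, 1))) stop("event must be coded 0/1")
  if (all(c("nc", "lc") %in% colnames(clin))) {
    nlr <- clin$nc / clin$lc
    if ("nlr" %in% colnames(clin) &&
        any(abs(clin$nlr - nlr) > 1e-6))
      warning("provided nlr column disagrees with nc/lc; recomputed")
    clin$nlr <- nlr
  }
  rownames(clin) <- clin$patient_id
  list(clinical = clin[setdiff(colnames(clin), "patient_id")],
       survival = data.frame(patient_id = surv$patient_id,
                             time_months = as.numeric(surv$time_months),
                             event = as.numeric(surv$event)))
}
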