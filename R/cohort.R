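# Longitudinal containers: one patient's visit series and a cohort thereof.

#' One patient's longitudinal series
#'
#' @param patient_id opaque patient label.
#' @param times strictly increasing visit times in years.
#' @param observations `T x K` numeric matrix of feature values, one row per
#'   visit, no missing values.
#' @param covariates optional data frame of auxiliary per-visit columns
#'   (e.g. a clinical staging variable); carried through for reporting only,
#'   never used in the likelihood.
#'
#' @return An object of class `patient_series`.
#' @export
patient_series <- function(patient_id, times, observations,
                           covariates = NULL) {
  observations <- as.matrix(observations)
  if (!is.numeric(observations)) {
    stop("observations must be numeric", call. = FALSE)
  }
  times <- as.numeric(times)
  if (length(times) < 1L) {
    stop("a patient needs at least one visit", call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop(sprintf("visit times of patient '%s' must be strictly increasing",
                 patient_id), call. = FALSE)
  }
  if (nrow(observations) != length(times)) {
    stop("one observation row per visit time required", call. = FALSE)
  }
  if (any(!is.finite(observations))) {
    stop(sprintf("patient '%s' has non-finite feature values", patient_id),
         call. = FALSE)
  }
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != length(times)) {
      stop("covariates must have one row per visit", call. = FALSE)
    }
  }
  structure(
    list(patient_id = as.character(patient_id), times = times,
         observations = observations, covariates = covariates),
    class = "patient_series"
  )
}

#' A cohort of patient series
#'
#' @param patients list of [patient_series()] objects with unique ids and a
#'   common number of features.
#' @param features character vector of feature names (length `K`).
#'
#' @return An object of class `cthmm_cohort`.
#' @export
cthmm_cohort <- function(patients, features) {
  if (!length(patients)) {
    stop("cohort must contain at least one patient", call. = FALSE)
  }
  K <- length(features)
  ids <- vapply(patients, function(p) p$patient_id, character(1))
  if (anyDuplicated(ids)) {
    stop("patient ids must be unique", call. = FALSE)
  }
  ks <- vapply(patients, function(p) ncol(p$observations), integer(1))
  if (any(ks != K)) {
    stop("all patients must share the same feature columns", call. = FALSE)
  }
  structure(list(patients = patients, features = as.character(features)),
            class = "cthmm_cohort")
}

#' @export
print.cthmm_cohort <- function(x, ...) {
  nv <- vapply(x$patients, function(p) length(p$times), integer(1))
  cat(sprintf(
    "CTHMM cohort: %d patients, %d visits (%.1f per patient), %d features\n",
    length(x$patients), sum(nv), mean(nv), length(x$features)))
  invisible(x)
}

#' @export
length.cthmm_cohort <- function(x) length(x$patients)

#' Build a cohort from a long-format data frame
#'
#' Converts a tidy table with one row per patient-visit into a
#' [cthmm_cohort()]. Rows are sorted by time within patient.
#'
#' @param data data frame in long format.
#' @param id_col,time_col names of the patient-id and visit-time columns.
#' @param feature_cols character vector of feature column names.
#' @param covariate_cols optional auxiliary columns to carry along.
#'
#' @return A `cthmm_cohort`.
#' @export
as_cohort <- function(data, id_col = "patient_id", time_col = "visit_time",
                      feature_cols, covariate_cols = NULL) {
  need <- c(id_col, time_col, feature_cols, covariate_cols)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  key <- interaction(data[[id_col]], data[[time_col]], drop = TRUE)
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key))[1]
    stop(sprintf("duplicate (patient, time) row, e.g. row %d", dup),
         call. = FALSE)
  }
  ids <- unique(as.character(data[[id_col]]))
  patients <- lapply(ids, function(id) {
    rows <- data[as.character(data[[id_col]]) == id, , drop = FALSE]
    rows <- rows[order(rows[[time_col]]), , drop = FALSE]
    cov <- if (is.null(covariate_cols)) NULL else
      rows[, covariate_cols, drop = FALSE]
    patient_series(id, rows[[time_col]],
                   as.matrix(rows[, feature_cols, drop = FALSE]),
                   covariates = cov)
  })
  cthmm_cohort(patients, feature_cols)
}

#' Flatten a cohort to a long-format data frame
#'
#' Inverse of [as_cohort()]: one row per patient-visit, features and any
#' covariates as columns.
#'
#' @param cohort a `cthmm_cohort`.
#' @return A data frame.
#' @export
cohort_to_df <- function(cohort) {
  rows <- lapply(cohort$patients, function(p) {
    df <- data.frame(patient_id = p$patient_id, visit_time = p$times,
                     stringsAsFactors = FALSE)
    obs <- as.data.frame(p$observations)
    names(obs) <- cohort$features
    df <- cbind(df, obs)
    if (!is.null(p$covariates)) df <- cbind(df, p$covariates)
    df
  })
  do.call(rbind, rows)
}

total_followup <- function(cohort) {
  sum(vapply(cohort$patients,
             function(p) max(p$times) - min(p$times), numeric(1)))
}
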