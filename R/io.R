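# Delimited-text cohort readers/writers and JSON model serialization.
# Numeric text output uses 17 significant digits so round trips are exact.

fmt17 <- function(x) {
  vapply(x, function(v) formatC(v, digits = 17, format = "g"), character(1))
}

#' Read a long-format cohort file
#'
#' Parses a delimited table with one row per patient-visit. Visits with any
#' missing feature value are dropped, then patients with fewer than
#' `min_visits` remaining visits are dropped; the counts are attached as an
#' exclusion report and emitted as a message. Unparseable numeric cells
#' (non-empty text that is not a number) are an error with row context.
#'
#' @param path file path.
#' @param feature_cols character vector of feature column names.
#' @param id_col,time_col patient-id and visit-time column names.
#' @param covariate_cols optional auxiliary columns carried along for
#'   reporting (never used in the likelihood).
#' @param min_visits minimum visits a patient must retain (2 keeps only
#'   patients with longitudinal information; 4 is typical for
#'   model-selection runs).
#' @param sep field separator (`","` default, `"\t"` accepted).
#' @param rebase_times if `TRUE`, shift each patient's times so the first
#'   visit is at 0 years.
#'
#' @return A [cthmm_cohort()] with attribute `"exclusion_report"`, a list
#'   with `visits_dropped_missing`, `patients_dropped_min_visits` and
#'   `patients_kept`.
#' @export
read_cohort <- function(path, feature_cols, id_col = "patient_id",
                        time_col = "visit_time", covariate_cols = NULL,
                        min_visits = 2L, sep = ",", rebase_times = FALSE) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  raw <- read.table(path, header = TRUE, sep = sep,
                    colClasses = "character", check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (!nrow(raw)) {
    stop("input file has no data rows: ", path, call. = FALSE)
  }
  need <- c(id_col, time_col, feature_cols, covariate_cols)
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop("missing declared columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }

  parse_num <- function(col, name) {
    blank <- is.na(col) | trimws(col) == "" | toupper(trimws(col)) == "NA"
    out <- suppressWarnings(as.numeric(col))
    bad <- which(!blank & is.na(out))
    if (length(bad)) {
      stop(sprintf("column '%s': unparseable numeric value '%s' at row %d",
                   name, col[bad[1]], bad[1]), call. = FALSE)
    }
    out
  }
  df <- data.frame(id = raw[[id_col]], stringsAsFactors = FALSE)
  df$time <- parse_num(raw[[time_col]], time_col)
  if (any(is.na(df$time))) {
    stop("missing visit times at row ", which(is.na(df$time))[1],
         call. = FALSE)
  }
  for (f in feature_cols) df[[f]] <- parse_num(raw[[f]], f)
  for (cv in covariate_cols) df[[cv]] <- raw[[cv]]

  key <- paste(df$id, df$time, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (patient, time) combination at row ",
         which(duplicated(key))[1], call. = FALSE)
  }

  complete <- !Reduce(`|`, lapply(feature_cols, function(f) is.na(df[[f]])))
  visits_dropped <- sum(!complete)
  df <- df[complete, , drop = FALSE]

  counts <- table(df$id)
  keep_ids <- names(counts)[counts >= min_visits]
  patients_dropped <- length(counts) - length(keep_ids)
  df <- df[df$id %in% keep_ids, , drop = FALSE]
  if (!nrow(df)) {
    stop("no patients left after filtering", call. = FALSE)
  }
  if (rebase_times) {
    df$time <- df$time - stats::ave(df$time, df$id, FUN = min)
  }

  names(df)[names(df) == "id"] <- "patient_id"
  names(df)[names(df) == "time"] <- "visit_time"
  cohort <- as_cohort(df, feature_cols = feature_cols,
                      covariate_cols = covariate_cols)
  report <- list(visits_dropped_missing = visits_dropped,
                 patients_dropped_min_visits = patients_dropped,
                 patients_kept = length(cohort$patients))
  message(sprintf(
    "read %d patients; dropped %d visit(s) with missing features and %d patient(s) below %d visits",
    report$patients_kept, visits_dropped, patients_dropped, min_visits))
  attr(cohort, "exclusion_report") <- report
  cohort
}

#' Write a cohort as a long-format delimited file
#'
#' @param cohort a [cthmm_cohort()].
#' @param path output file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, sep = ",") {
  df <- cohort_to_df(cohort)
  num <- vapply(df, is.numeric, logical(1))
  for (j in which(num)) df[[j]] <- fmt17(df[[j]])
  write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize CTHMM parameters to JSON
#'
#' Versioned layout with row-major matrices, the mask kind/order and the
#' explicit list of absorbing states, so models reload exactly.
#'
#' @param params a [cthmm_params()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_params_json <- function(params, path) {
  M <- num_states(params)
  obj <- list(
    schema = "cthmm-params/1",
    num_states = M,
    num_features = num_features(params),
    features = params$features,
    mask_kind = params$mask$kind,
    order = if (is.na(params$mask$order)) NULL else params$mask$order,
    absorbing = which(params$mask$absorbing),
    allowed = as.integer(t(params$mask$allowed)),
    Q = as.numeric(t(params$Q)),
    pi = params$pi,
    means = as.numeric(t(params$means)),
    variances = as.numeric(t(params$variances))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load CTHMM parameters from JSON
#'
#' @param path a file written by [write_params_json()].
#' @return A [cthmm_params()].
#' @export
read_params_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$schema) || obj$schema != "cthmm-params/1") {
    stop("unrecognized model file schema", call. = FALSE)
  }
  M <- obj$num_states
  K <- obj$num_features
  mask <- structure_mask(M, obj$mask_kind,
                         order = if (is.null(obj$order)) 2L else obj$order,
                         absorbing_last = M %in% obj$absorbing)
  cthmm_params(matrix(obj$Q, M, M, byrow = TRUE), obj$pi,
               matrix(obj$means, M, K, byrow = TRUE),
               matrix(obj$variances, M, K, byrow = TRUE),
               mask, features = obj$features)
}

#' Serialize a fit result to JSON
#'
#' Stores parameters, the per-iteration log-likelihood trace, convergence
#' state and the seed, enough to reload or audit a fit.
#'
#' @param fit a `cthmm_fit` from [fit_cthmm()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  p <- fit$params
  obj <- list(
    schema = "cthmm-fit/1",
    loglik = fit$loglik,
    loglik_trace = fit$loglik_trace,
    converged = fit$converged,
    iterations = fit$iterations,
    seed_used = fit$seed_used,
    restarts = fit$restarts,
    params = jsonlite::parse_json(jsonlite::toJSON(list(
      schema = "cthmm-params/1",
      num_states = num_states(p),
      num_features = num_features(p),
      features = p$features,
      mask_kind = p$mask$kind,
      order = if (is.na(p$mask$order)) NULL else p$mask$order,
      absorbing = which(p$mask$absorbing),
      Q = as.numeric(t(p$Q)),
      pi = p$pi,
      means = as.numeric(t(p$means)),
      variances = as.numeric(t(p$variances))
    ), auto_unbox = TRUE, digits = NA))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export a selection result
#'
#' Writes the two-column held-out likelihood curve (the data behind a
#' states-versus-likelihood plot) as delimited text, and optionally full
#' provenance as JSON.
#'
#' @param selection a `cthmm_selection`.
#' @param path output path for the curve table.
#' @param json_path optional path for a JSON record with the chosen model
#'   size, split seed and curve.
#' @return `path`, invisibly.
#' @export
write_selection <- function(selection, path, json_path = NULL) {
  tab <- selection$table
  tab$test_loglik <- fmt17(tab$test_loglik)
  write.table(tab, path, sep = ",", row.names = FALSE, quote = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(schema = "cthmm-selection/1",
           grid = selection$table$M,
           test_loglik = selection$table$test_loglik,
           chosen_M = selection$chosen_M,
           split_seed = selection$split_seed,
           per_visit = selection$per_visit),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
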