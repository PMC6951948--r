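# Machine-readable state-profile reporting: per-state feature summaries,
# covariate distributions, expected durations, transition probabilities,
# and decoded sequences.

#' Summarize a fitted progression model over a decoded cohort
#'
#' Produces the standard descriptive outputs of a staging model as plain
#' data frames:
#'
#' * `state_profiles`: per-state mean and SD of each feature among visits
#'   decoded to that state, with the state's expected duration and a
#'   cumulative `x_position` (states laid out along the disease course with
#'   spacing proportional to expected duration);
#' * `covariate_summary`: per-state distribution of each requested
#'   auxiliary covariate (counts per value), e.g. a clinical staging or
#'   diagnostic-confidence column;
#' * `durations`: expected state durations in years (absorbing states
#'   `NA`);
#' * `transition_matrix`: `A(delta)` for the requested horizon (under a
#'   forward-type structure its lower triangle is zero);
#' * `state_sequences`: the decoded per-patient sequences, one row per
#'   visit.
#'
#' @param params a fitted [cthmm_params()].
#' @param cohort the [cthmm_cohort()] the model describes.
#' @param decoded optional decoded sequences from [decode_cohort()];
#'   computed if missing.
#' @param delta horizon in years for the transition-probability export.
#' @param covariate_cols covariate columns to summarize; absent columns are
#'   skipped with a warning.
#' @return A list of class `cthmm_report` with the components above.
#' @export
report_state_profiles <- function(params, cohort, decoded = NULL,
                                  delta = 1, covariate_cols = NULL) {
  if (is.null(decoded)) {
    decoded <- decode_cohort(params, cohort)
  }
  M <- num_states(params)
  K <- num_features(params)
  obs <- do.call(rbind, lapply(cohort$patients,
                               function(p) p$observations))
  state <- decoded$state
  if (nrow(obs) != length(state)) {
    stop("decoded sequences are not aligned with the cohort", call. = FALSE)
  }

  dur <- expected_durations(params$Q)
  spacing <- ifelse(is.na(dur), 0, dur)
  x_pos <- cumsum(c(0, spacing[-M])) + spacing / 2

  prof <- do.call(rbind, lapply(seq_len(M), function(m) {
    rows <- obs[state == m, , drop = FALSE]
    data.frame(
      state = m,
      feature = cohort$features,
      mean = if (nrow(rows)) colMeans(rows) else NA_real_,
      sd = if (nrow(rows) > 1) apply(rows, 2, stats::sd) else NA_real_,
      n_visits = nrow(rows),
      expected_duration = dur[m],
      x_position = x_pos[m],
      row.names = NULL)
  }))

  cov_summary <- NULL
  if (!is.null(covariate_cols)) {
    covs <- do.call(rbind, lapply(cohort$patients, function(p) {
      if (is.null(p$covariates)) {
        as.data.frame(matrix(NA, length(p$times), 0))
      } else {
        p$covariates
      }
    }))
    present <- intersect(covariate_cols, names(covs))
    absent <- setdiff(covariate_cols, names(covs))
    if (length(absent)) {
      warning("covariate column(s) not in cohort, skipped: ",
              paste(absent, collapse = ", "), call. = FALSE)
    }
    if (length(present)) {
      cov_summary <- do.call(rbind, lapply(present, function(cv) {
        tab <- as.data.frame(table(state = state, value = covs[[cv]]),
                             stringsAsFactors = FALSE)
        tab$covariate <- cv
        tab$state <- as.integer(tab$state)
        tab[, c("covariate", "state", "value", "Freq")]
      }))
      names(cov_summary)[names(cov_summary) == "Freq"] <- "count"
    }
  }

  A <- transition_matrix(params$Q, delta)
  structure(list(state_profiles = prof,
                 covariate_summary = cov_summary,
                 durations = data.frame(state = seq_len(M),
                                        expected_duration_years = dur,
                                        row.names = NULL),
                 transition_matrix = A,
                 delta = delta,
                 state_sequences = decoded),
            class = "cthmm_report")
}

#' Write report tables to a directory
#'
#' @param report a `cthmm_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wt <- function(df, name) {
    num <- vapply(df, is.numeric, logical(1))
    for (j in which(num)) df[[j]] <- fmt17(df[[j]])
    write.table(df, file.path(dir, name), sep = ",", row.names = FALSE,
                quote = FALSE)
  }
  wt(report$state_profiles, "state_profiles.csv")
  wt(report$durations, "durations.csv")
  wt(report$state_sequences, "state_sequences.csv")
  if (!is.null(report$covariate_summary)) {
    wt(report$covariate_summary, "covariate_summary.csv")
  }
  A <- report$transition_matrix
  adf <- as.data.frame(A)
  names(adf) <- paste0("to_state", seq_len(ncol(A)))
  adf <- cbind(from_state = seq_len(nrow(A)), adf)
  wt(adf, sprintf("transition_matrix_delta_%s.csv",
                  format(report$delta)))
  invisible(dir)
}
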