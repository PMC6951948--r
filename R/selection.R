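# Data-driven choice of the number of hidden states by held-out
# log-likelihood over a candidate grid.

#' Split a cohort into training and testing sets by patient
#'
#' All visits of a patient land on the same side, so held-out evaluation
#' never sees training patients. Deterministic given the seed.
#'
#' @param cohort a [cthmm_cohort()] with at least two patients.
#' @param train_fraction proportion of patients assigned to training,
#'   strictly between 0 and 1.
#' @param seed integer seed for the random assignment.
#' @return A list with `train` and `test` cohorts.
#' @export
split_cohort <- function(cohort, train_fraction = 0.8, seed = 1L) {
  if (!is.numeric(train_fraction) || train_fraction <= 0 ||
      train_fraction >= 1) {
    stop("'train_fraction' must be strictly between 0 and 1", call. = FALSE)
  }
  N <- length(cohort$patients)
  if (N < 2) {
    stop("need at least two patients to split", call. = FALSE)
  }
  n_train <- round(train_fraction * N)
  if (n_train < 1 || n_train > N - 1) {
    stop("degenerate split: one side would be empty", call. = FALSE)
  }
  set.seed(seed)
  idx <- sample.int(N, n_train)
  list(train = cthmm_cohort(cohort$patients[sort(idx)], cohort$features),
       test = cthmm_cohort(cohort$patients[sort(setdiff(seq_len(N), idx))],
                           cohort$features))
}

#' Select the number of disease states by held-out log-likelihood
#'
#' Splits the cohort once by patient, fits one model per candidate number
#' of states on the training side, evaluates each fitted model's
#' log-likelihood on the held-out side, and picks the candidate with the
#' highest held-out log-likelihood (ties broken toward the smaller, more
#' parsimonious model). A failing candidate is recorded with `NA` rather
#' than aborting the grid.
#'
#' @param cohort a [cthmm_cohort()].
#' @param grid strictly increasing integer candidates for the number of
#'   states, each at least 2.
#' @param kind,order,absorbing_last structure settings passed to
#'   [structure_mask()] for every candidate.
#' @param control a [fit_control()].
#' @param train_fraction,seed split settings for [split_cohort()].
#' @param per_visit if `TRUE`, normalize held-out log-likelihood by the
#'   number of test visits (useful for unbalanced cohorts); the default
#'   uses the total, so larger test patients weigh more.
#'
#' @return A list of class `cthmm_selection` with `table` (columns `M`,
#'   `test_loglik`), `chosen_M`, `fits` (per-candidate `cthmm_fit` or
#'   `NULL`), `split_seed` and the split itself.
#' @export
select_num_states <- function(cohort, grid,
                              kind = "forward_chain", order = 2L,
                              absorbing_last = TRUE,
                              control = fit_control(),
                              train_fraction = 0.8, seed = 1L,
                              per_visit = FALSE) {
  grid <- as.integer(grid)
  if (!length(grid) || any(grid < 2) || is.unsorted(grid, strictly = TRUE)) {
    stop("'grid' must be strictly increasing integers >= 2", call. = FALSE)
  }
  halves <- split_cohort(cohort, train_fraction, seed)
  n_test_visits <- sum(vapply(halves$test$patients,
                              function(p) length(p$times), integer(1)))

  fits <- vector("list", length(grid))
  test_ll <- rep(NA_real_, length(grid))
  for (g in seq_along(grid)) {
    M <- grid[g]
    res <- tryCatch({
      mask <- structure_mask(M, kind,
                             order = min(order, M - 1L),
                             absorbing_last = absorbing_last)
      fit <- fit_cthmm(halves$train, mask, control)
      list(fit = fit, ll = cohort_loglik(fit$params, halves$test))
    }, error = function(e) {
      warning(sprintf("candidate M = %d failed: %s", M,
                      conditionMessage(e)), call. = FALSE)
      NULL
    })
    if (!is.null(res)) {
      fits[[g]] <- res$fit
      test_ll[g] <- if (per_visit) res$ll / n_test_visits else res$ll
    }
  }
  if (all(is.na(test_ll))) {
    stop("every candidate failed to fit", call. = FALSE)
  }
  chosen <- grid[which.max(test_ll)]   # first max: smaller M wins ties

  structure(list(table = data.frame(M = grid, test_loglik = test_ll),
                 chosen_M = chosen, fits = fits, split_seed = seed,
                 train = halves$train, test = halves$test,
                 per_visit = per_visit),
            class = "cthmm_selection")
}

#' @export
print.cthmm_selection <- function(x, ...) {
  cat("Held-out selection of the number of states\n")
  print(x$table, row.names = FALSE)
  cat("chosen M:", x$chosen_M, "\n")
  invisible(x)
}
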