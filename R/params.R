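#' Bundle CTHMM parameters
#'
#' Collects the full parameter set of a continuous-time hidden Markov model
#' with independent Gaussian emissions: the transition generator `Q`
#' (rates per year), the initial state distribution `pi` over the state at
#' each patient's first observed visit, and per-state per-feature emission
#' means and variances.
#'
#' `pi` refers to the state at the first *observed* visit, not at biological
#' disease onset: observational cohorts are left-truncated, so patients
#' enter the data partway through the disease course.
#'
#' @param Q numeric `M x M` generator matrix.
#' @param pi numeric length-`M` probability vector (sums to 1).
#' @param means numeric `M x K` matrix of emission means.
#' @param variances numeric `M x K` matrix of emission variances
#'   (floored at `1e-6`).
#' @param mask a [structure_mask()] consistent with `Q`.
#' @param features optional character vector of `K` feature names.
#'
#' @return An object of class `cthmm_params`.
#' @export
cthmm_params <- function(Q, pi, means, variances, mask, features = NULL) {
  stopifnot_mask(mask)
  Q <- as.matrix(Q)
  means <- as.matrix(means)
  variances <- as.matrix(variances)
  M <- mask$num_states
  assert_generator(Q, mask)
  if (length(pi) != M || any(pi < -1e-12) || abs(sum(pi) - 1) > 1e-10) {
    stop("'pi' must be a length-M probability vector summing to 1",
         call. = FALSE)
  }
  pi <- pmax(pi, 0)
  pi <- pi / sum(pi)
  if (!all(dim(means) == dim(variances)) || nrow(means) != M) {
    stop("'means' and 'variances' must both be M x K", call. = FALSE)
  }
  if (any(!is.finite(means)) || any(!is.finite(variances))) {
    stop("emission parameters must be finite", call. = FALSE)
  }
  variances <- pmax(variances, 1e-6)
  K <- ncol(means)
  if (is.null(features)) {
    features <- paste0("feature", seq_len(K))
  }
  if (length(features) != K) {
    stop("'features' must have one name per feature column", call. = FALSE)
  }
  structure(
    list(Q = Q, pi = as.numeric(pi), means = means, variances = variances,
         mask = mask, features = as.character(features)),
    class = "cthmm_params"
  )
}

#' @export
print.cthmm_params <- function(x, ...) {
  M <- x$mask$num_states
  K <- ncol(x$means)
  cat(sprintf("CTHMM parameters: %d states, %d features (%s mask)\n",
              M, K, x$mask$kind))
  dur <- expected_durations(x$Q)
  cat("  expected durations (years):",
      paste(ifelse(is.na(dur), "-", sprintf("%.2f", dur)), collapse = " "),
      "\n")
  invisible(x)
}

num_states <- function(params) params$mask$num_states
num_features <- function(params) ncol(params$means)
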