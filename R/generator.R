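# Continuous-time Markov chain mathematics: generator validation, transition
# probabilities, endpoint-conditioned expectations, expected durations.

#' Validate a transition generator matrix against a structure mask
#'
#' Checks the defining properties of a CTMC generator: non-negative
#' off-diagonal rates, zero row sums (tolerance 1e-10), zeros wherever the
#' mask disallows a transition, and all-zero rows for absorbing states.
#' Validation never throws; it reports every violation so callers can decide.
#'
#' @param Q numeric `M x M` generator matrix, rates per year.
#' @param mask a [structure_mask()] object with matching `num_states`.
#'
#' @return A data frame with columns `type`, `i`, `j`, `value` describing
#'   each violation; zero rows means `Q` is valid.
#' @export
validate_generator <- function(Q, mask) {
  stopifnot_mask(mask)
  M <- mask$num_states
  bad <- function(type, i, j, value) {
    data.frame(type = type, i = i, j = j, value = value)
  }
  out <- list()
  if (!is.matrix(Q) || !is.numeric(Q) || nrow(Q) != M || ncol(Q) != M) {
    return(bad("shape", NA_integer_, NA_integer_, NA_real_))
  }
  off <- Q
  diag(off) <- 0
  neg <- which(off < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    out <- c(out, list(bad("negative_rate", neg[, 1], neg[, 2],
                           off[neg])))
  }
  rs <- rowSums(Q)
  bad_rows <- which(abs(rs) > 1e-10)
  if (length(bad_rows)) {
    out <- c(out, list(bad("row_sum", bad_rows, NA_integer_, rs[bad_rows])))
  }
  masked <- which(!mask$allowed & off != 0, arr.ind = TRUE)
  if (nrow(masked)) {
    out <- c(out, list(bad("masked_entry", masked[, 1], masked[, 2],
                           off[masked])))
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(type = character(), i = integer(), j = integer(),
               value = numeric())
}

assert_generator <- function(Q, mask) {
  rep <- validate_generator(Q, mask)
  if (nrow(rep)) {
    stop("invalid generator matrix: ",
         paste(unique(rep$type), collapse = ", "), call. = FALSE)
  }
  invisible(Q)
}

#' Transition probability matrix over an elapsed time
#'
#' Computes `A(delta) = expm(delta * Q)`, the matrix of probabilities that a
#' chain in state `i` is found in state `j` after `delta` years.
#'
#' @param Q numeric generator matrix (rates per year).
#' @param delta elapsed time in years, `delta >= 0`.
#'
#' @return `M x M` row-stochastic matrix with attribute `"delta"`.
#' @examples
#' Q <- matrix(c(-1, 1, 0, 0), 2, 2, byrow = TRUE)
#' transition_matrix(Q, log(2))  # [[0.5, 0.5], [0, 1]]
#' @export
transition_matrix <- function(Q, delta) {
  if (!is.numeric(delta) || length(delta) != 1L || is.na(delta) ||
      delta < 0) {
    stop("'delta' must be a single non-negative number of years",
         call. = FALSE)
  }
  Q <- as.matrix(Q)
  A <- expm_cpp(delta * Q)
  # clamp round-off outside [0, 1]
  A[A < 0] <- 0
  A[A > 1] <- 1
  attr(A, "delta") <- delta
  A
}

#' Endpoint-conditioned expected transition counts and sojourn times
#'
#' For a CTMC with generator `Q` observed only at the two ends of an
#' interval of length `delta`, computes for every endpoint pair `(i, j)`
#' the conditional expectations
#' `EN[i, j, k, l] = E[# jumps k -> l | S(0) = i, S(delta) = j]` and
#' `ER[i, j, k] = E[time spent in k | S(0) = i, S(delta) = j]`.
#' These are the interval-level sufficient statistics of the EM E-step.
#'
#' The integrals are evaluated through the exponential of an auxiliary
#' `2M x 2M` block matrix `[[Q, B], [0, Q]]` with a one-hot block `B`, one
#' exponential per needed `(k, l)`; this is robust to non-diagonalizable
#' generators, which arise routinely from tied rates in forward chains.
#'
#' @param Q numeric generator matrix.
#' @param delta interval length in years, strictly positive.
#'
#' @return A list with `EN` (`M x M x M x M` array), `ER` (`M x M x M`
#'   array), `A` (the transition matrix) and `delta`. Entries for endpoint
#'   pairs with `A(delta)[i, j] = 0` are zero.
#' @export
conditioned_expectations <- function(Q, delta) {
  if (!is.numeric(delta) || length(delta) != 1L || is.na(delta) ||
      delta <= 0) {
    stop("'delta' must be a single positive number of years", call. = FALSE)
  }
  Q <- as.matrix(Q)
  M <- nrow(Q)
  off <- Q
  diag(off) <- 0
  pairs <- which(off > 0, arr.ind = TRUE)
  ce <- cond_expect_cpp(Q, delta, pairs - 1L)
  EN <- array(0, dim = c(M, M, M, M))
  if (nrow(pairs)) {
    for (p in seq_len(nrow(pairs))) {
      EN[, , pairs[p, 1], pairs[p, 2]] <- ce$EN[, , p]
    }
  }
  list(EN = EN, ER = ce$ER, A = ce$A, delta = delta)
}

#' Expected state durations
#'
#' The mean sojourn time per entry into each state: `-1 / Q[i, i]` years.
#' Absorbing states (zero row) have no finite duration and are reported as
#' `NA`.
#'
#' @param Q numeric generator matrix.
#' @return Named numeric vector of durations in years, `NA` for absorbing
#'   states.
#' @export
expected_durations <- function(Q) {
  Q <- as.matrix(Q)
  d <- diag(Q)
  out <- ifelse(d < 0, -1 / d, NA_real_)
  names(out) <- paste0("state", seq_along(out))
  out
}
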