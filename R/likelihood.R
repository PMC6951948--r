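# Observation model and exact inference for one series: Gaussian emission
# log-densities, scaled forward-backward over irregular visit gaps, Viterbi
# decoding, and forward prediction.

#' Per-state Gaussian emission log-density of one observation
#'
#' Features are conditionally independent given the state, so the log
#' density under state `m` is the sum over features of univariate normal
#' log densities with that state's mean and variance.
#'
#' @param observation numeric length-`K` feature vector.
#' @param params a [cthmm_params()] object (or any list with `means` and
#'   `variances` matrices).
#'
#' @return Numeric length-`M` vector of log densities.
#' @export
emission_loglik <- function(observation, params) {
  if (any(!is.finite(observation))) {
    stop("observation contains non-finite values", call. = FALSE)
  }
  if (length(observation) != ncol(params$means)) {
    stop("observation length does not match the number of features",
         call. = FALSE)
  }
  series_emission_loglik(matrix(observation, nrow = 1), params)[1, ]
}

# T x M matrix of emission log-densities for a whole series.
series_emission_loglik <- function(obs, params) {
  M <- nrow(params$means)
  Tn <- nrow(obs)
  out <- matrix(0, Tn, M)
  sds <- sqrt(params$variances)
  for (m in seq_len(M)) {
    mu <- matrix(params$means[m, ], Tn, ncol(obs), byrow = TRUE)
    sd <- matrix(sds[m, ], Tn, ncol(obs), byrow = TRUE)
    out[, m] <- rowSums(dnorm(obs, mu, sd, log = TRUE))
  }
  out
}

# Interval transition matrices for one series: list of length Tn - 1.
# Gaps are canonicalized to 1e-6 years (a no-op at data precision) so that
# repeated intervals share one matrix exponential.
series_transition_matrices <- function(params, times, cache = NULL) {
  gaps <- round(diff(times), 6)
  lapply(gaps, function(d) {
    if (!is.null(cache)) {
      key <- sprintf("%.6f", d)
      A <- cache[[key]]
      if (is.null(A)) {
        A <- transition_matrix(params$Q, d)
        cache[[key]] <- A
      }
      A
    } else {
      transition_matrix(params$Q, d)
    }
  })
}

#' Posterior state distributions and likelihood for one patient
#'
#' Runs the scaled forward-backward algorithm over a patient's visits,
#' using interval-specific transition matrices `A(tau_t - tau_{t-1})` from
#' the matrix exponential of the generator. Per-visit scaling constants are
#' log-accumulated, so long series and many states do not underflow.
#'
#' @param params a [cthmm_params()] object.
#' @param patient a [patient_series()].
#' @param cache optional environment memoizing interval transition matrices
#'   across patients (gaps are canonicalized to 1e-6 years for the lookup).
#'
#' @return A list of class `cthmm_posterior` with `gamma` (`T x M` per-visit
#'   state posteriors), `xi` (`(T-1) x M x M` per-interval pairwise
#'   posteriors, each slice summing to 1) and `loglik` (the observed-data
#'   log-likelihood of the series).
#' @export
forward_backward <- function(params, patient, cache = NULL) {
  M <- num_states(params)
  times <- patient$times
  Tn <- length(times)
  if (Tn > 1 && any(diff(times) <= 0)) {
    stop(sprintf("patient '%s': visit times must be strictly increasing",
                 patient$patient_id), call. = FALSE)
  }
  logb <- series_emission_loglik(patient$observations, params)
  bmax <- apply(logb, 1, max)
  b <- exp(logb - bmax)                      # scaled densities, max 1
  Amats <- series_transition_matrices(params, times, cache)

  alpha <- matrix(0, Tn, M)
  cvec <- numeric(Tn)
  a <- params$pi * b[1, ]
  cvec[1] <- sum(a)
  if (cvec[1] <= 0) {
    stop(sprintf("patient '%s': zero likelihood at visit 1",
                 patient$patient_id), call. = FALSE)
  }
  alpha[1, ] <- a / cvec[1]
  if (Tn > 1) {
    for (t in 2:Tn) {
      a <- as.numeric(alpha[t - 1, ] %*% Amats[[t - 1]]) * b[t, ]
      cvec[t] <- sum(a)
      if (cvec[t] <= 0) {
        stop(sprintf("patient '%s': zero likelihood at visit %d",
                     patient$patient_id, t), call. = FALSE)
      }
      alpha[t, ] <- a / cvec[t]
    }
  }
  loglik <- sum(log(cvec)) + sum(bmax)

  beta <- matrix(0, Tn, M)
  beta[Tn, ] <- 1
  if (Tn > 1) {
    for (t in (Tn - 1):1) {
      beta[t, ] <- as.numeric(
        Amats[[t]] %*% (b[t + 1, ] * beta[t + 1, ])) / cvec[t + 1]
    }
  }
  gamma <- alpha * beta
  gamma <- gamma / rowSums(gamma)

  xi <- NULL
  if (Tn > 1) {
    xi <- array(0, dim = c(Tn - 1, M, M))
    for (t in 2:Tn) {
      s <- outer(alpha[t - 1, ], b[t, ] * beta[t, ]) * Amats[[t - 1]]
      xi[t - 1, , ] <- s / sum(s)
    }
  }
  structure(list(gamma = gamma, xi = xi, loglik = loglik),
            class = "cthmm_posterior")
}

#' Total cohort log-likelihood
#'
#' Patients are independent, so the cohort observed-data log-likelihood is
#' the sum of per-patient forward-backward log-likelihoods.
#'
#' @param params a [cthmm_params()].
#' @param cohort a [cthmm_cohort()].
#' @return A single number.
#' @export
cohort_loglik <- function(params, cohort) {
  if (length(cohort$features) != ncol(params$means)) {
    stop("cohort and parameters disagree on the number of features",
         call. = FALSE)
  }
  sum(vapply(cohort$patients,
             function(p) forward_backward(params, p)$loglik, numeric(1)))
}

#' Most probable state sequence for one patient (Viterbi)
#'
#' Log-space dynamic programming over the interval transition matrices.
#' Ties are broken deterministically toward the lower state index. Under a
#' forward-type mask the decoded sequence is non-decreasing.
#'
#' @param params a [cthmm_params()].
#' @param patient a [patient_series()].
#' @return A list of class `cthmm_state_sequence` with `patient_id`,
#'   `times` and `states` (1-based labels).
#' @export
viterbi <- function(params, patient) {
  M <- num_states(params)
  Tn <- length(patient$times)
  logb <- series_emission_loglik(patient$observations, params)
  Amats <- series_transition_matrices(params, patient$times)
  logA <- lapply(Amats, function(A) {
    L <- suppressWarnings(log(A))
    L[A <= 0] <- -Inf
    L
  })
  logpi <- ifelse(params$pi > 0, log(params$pi), -Inf)

  delta <- matrix(-Inf, Tn, M)
  psi <- matrix(1L, Tn, M)
  delta[1, ] <- logpi + logb[1, ]
  if (Tn > 1) {
    for (t in 2:Tn) {
      for (j in seq_len(M)) {
        cand <- delta[t - 1, ] + logA[[t - 1]][, j]
        best <- which.max(cand)          # first max: lowest index wins ties
        psi[t, j] <- best
        delta[t, j] <- cand[best] + logb[t, j]
      }
    }
  }
  states <- integer(Tn)
  states[Tn] <- which.max(delta[Tn, ])
  if (Tn > 1) {
    for (t in (Tn - 1):1) {
      states[t] <- psi[t + 1, states[t + 1]]
    }
  }
  structure(list(patient_id = patient$patient_id, times = patient$times,
                 states = states, logprob = max(delta[Tn, ])),
            class = "cthmm_state_sequence")
}

#' Decode every patient in a cohort
#'
#' @param params a [cthmm_params()].
#' @param cohort a [cthmm_cohort()].
#' @return A data frame with columns `patient_id`, `visit_time`, `state` —
#'   one row per visit.
#' @export
decode_cohort <- function(params, cohort) {
  rows <- lapply(cohort$patients, function(p) {
    v <- viterbi(params, p)
    data.frame(patient_id = p$patient_id, visit_time = p$times,
               state = v$states, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Predict the state distribution and expected features at a future time
#'
#' Propagates the posterior state distribution at the patient's last visit
#' forward by `horizon` years through `A(horizon)`, and returns the implied
#' mixture-of-states expected feature vector.
#'
#' @param params a [cthmm_params()].
#' @param patient a [patient_series()].
#' @param horizon years beyond the last visit, `>= 0`.
#' @return A list with `state_probs` (length `M`) and `expected_features`
#'   (length `K`, named).
#' @export
predict_future <- function(params, patient, horizon) {
  if (!is.numeric(horizon) || length(horizon) != 1L || is.na(horizon) ||
      horizon < 0) {
    stop("'horizon' must be a single non-negative number of years",
         call. = FALSE)
  }
  fb <- forward_backward(params, patient)
  g <- fb$gamma[nrow(fb$gamma), ]
  p <- if (horizon == 0) g else
    as.numeric(g %*% transition_matrix(params$Q, horizon))
  p <- pmax(p, 0)
  p <- p / sum(p)
  feats <- as.numeric(p %*% params$means)
  names(feats) <- params$features
  list(state_probs = p, expected_features = feats)
}
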