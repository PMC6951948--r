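# Shared test fixtures, built in code.

# Random valid generator respecting a mask: positive rates on allowed
# entries, diagonal from the row-sum constraint.
random_generator <- function(mask, rate_scale = 0.5) {
  M <- mask$num_states
  Q <- matrix(0, M, M)
  for (i in seq_len(M)) {
    cols <- which(mask$allowed[i, ])
    if (!length(cols)) next
    Q[i, cols] <- runif(length(cols), 0.1, 1) * rate_scale
    Q[i, i] <- -sum(Q[i, cols])
  }
  Q
}

# Random full parameter set for likelihood oracles.
random_params <- function(M, K, kind = "full", order = 2,
                          absorbing_last = FALSE) {
  mask <- structure_mask(M, kind, order = min(order, M - 1),
                         absorbing_last = absorbing_last)
  Q <- random_generator(mask)
  pi0 <- runif(M, 0.2, 1)
  pi0 <- pi0 / sum(pi0)
  means <- matrix(rnorm(M * K, sd = 2), M, K)
  variances <- matrix(runif(M * K, 0.5, 2), M, K)
  cthmm_params(Q, pi0, means, variances, mask)
}

random_patient <- function(params, Tn, id = "p1") {
  K <- ncol(params$means)
  # date-level time precision, so gap canonicalization is an exact no-op
  times <- round(cumsum(c(0, runif(Tn - 1, 0.3, 2))), 3)
  obs <- matrix(rnorm(Tn * K, sd = 2), Tn, K)
  patient_series(id, times, obs)
}

# A well-separated 3-state second-order forward-chain truth used by the
# recovery studies: K = 3 unit-variance features, ~2 sd between adjacent
# state means.
recovery_truth <- function() {
  mask <- structure_mask(3, "forward_chain", order = 2,
                         absorbing_last = FALSE)
  Q <- matrix(0, 3, 3)
  Q[1, 2] <- 0.40; Q[1, 3] <- 0.10
  Q[2, 3] <- 0.50
  diag(Q) <- -rowSums(Q)
  means <- rbind(c(0, 0, 0), c(2, -2, 2), c(4, -4, 4))
  cthmm_params(Q, c(0.6, 0.3, 0.1), means, matrix(1, 3, 3), mask)
}

# Truth for the model-size selection study: same chain, but with the nine
# features (three factors in each of three clinical domains) of the
# progression preset, i.e. a 3-state scaled-down version of the data shape
# the selection procedure targets. The per-state parameter count matters
# for selection: a redundant extra state costs ~2K + 2 held-out parameters,
# so the study is run at the cohort's real dimensionality.
selection_truth <- function() {
  mask <- structure_mask(3, "forward_chain", order = 2,
                         absorbing_last = FALSE)
  Q <- matrix(0, 3, 3)
  Q[1, 2] <- 0.40; Q[1, 3] <- 0.10
  Q[2, 3] <- 0.50
  diag(Q) <- -rowSums(Q)
  m_idx <- 0:2
  means <- cbind(2.0 * m_idx,  1.8 * m_idx + 0.2,  2.2 * m_idx - 0.2,
                 -2.0 * m_idx, -1.9 * m_idx + 0.1, -2.1 * m_idx - 0.1,
                 -1.8 * m_idx, -2.0 * m_idx + 0.15, -2.2 * m_idx - 0.15)
  cthmm_params(Q, c(0.6, 0.3, 0.1), means, matrix(1, 3, 9), mask)
}
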