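# Independent oracles used by the test suite. These deliberately avoid the
# package's own computational paths: truncated power series instead of the
# compiled matrix exponential, brute-force enumeration instead of
# forward-backward, a plain discrete-time HMM recursion, and a direct
# Gillespie Monte-Carlo simulator for endpoint-conditioned expectations.

# Truncated series expm: sum_{n} (X)^n / n!  with enough terms for 1e-12.
expm_series <- function(X, nterms = 60) {
  M <- nrow(X)
  out <- diag(M)
  term <- diag(M)
  for (n in seq_len(nterms)) {
    term <- term %*% X / n
    out <- out + term
  }
  out
}

# Observed-data log-likelihood by explicit summation over all M^T hidden
# sequences.
enumeration_loglik <- function(params, patient) {
  M <- nrow(params$means)
  Tn <- length(patient$times)
  Amats <- lapply(diff(patient$times),
                  function(d) expm_series(d * params$Q))
  logb <- sapply(seq_len(M), function(m) {
    rowSums(dnorm(patient$observations,
                  matrix(params$means[m, ], Tn, ncol(params$means),
                         byrow = TRUE),
                  matrix(sqrt(params$variances[m, ]), Tn,
                         ncol(params$means), byrow = TRUE),
                  log = TRUE))
  })
  logb <- matrix(logb, nrow = Tn)
  seqs <- as.matrix(expand.grid(rep(list(seq_len(M)), Tn)))
  logp <- apply(seqs, 1, function(s) {
    lp <- log(params$pi[s[1]]) + logb[1, s[1]]
    if (Tn > 1) {
      for (t in 2:Tn) {
        lp <- lp + log(Amats[[t - 1]][s[t - 1], s[t]]) + logb[t, s[t]]
      }
    }
    lp
  })
  mx <- max(logp)
  mx + log(sum(exp(logp - mx)))
}

# Joint log-probability of one specific hidden sequence (for Viterbi
# optimality checks).
sequence_logprob <- function(params, patient, states) {
  Tn <- length(patient$times)
  Amats <- lapply(diff(patient$times),
                  function(d) expm_series(d * params$Q))
  lp <- log(params$pi[states[1]])
  for (t in seq_len(Tn)) {
    lp <- lp + sum(dnorm(patient$observations[t, ], params$means[states[t], ],
                         sqrt(params$variances[states[t], ]), log = TRUE))
    if (t > 1) {
      a <- Amats[[t - 1]][states[t - 1], states[t]]
      lp <- lp + if (a > 0) log(a) else -Inf
    }
  }
  lp
}

# Plain discrete-time Gaussian HMM: scaled forward log-likelihood.
discrete_hmm_loglik <- function(A, pi0, means, variances, obs) {
  M <- nrow(means)
  Tn <- nrow(obs)
  logb <- sapply(seq_len(M), function(m) {
    rowSums(dnorm(obs, matrix(means[m, ], Tn, ncol(obs), byrow = TRUE),
                  matrix(sqrt(variances[m, ]), Tn, ncol(obs), byrow = TRUE),
                  log = TRUE))
  })
  logb <- matrix(logb, nrow = Tn)
  bmax <- apply(logb, 1, max)
  b <- exp(logb - bmax)
  a <- pi0 * b[1, ]
  ll <- log(sum(a)) + bmax[1]
  a <- a / sum(a)
  if (Tn > 1) {
    for (t in 2:Tn) {
      a <- as.numeric(a %*% A) * b[t, ]
      ll <- ll + log(sum(a)) + bmax[t]
      a <- a / sum(a)
    }
  }
  ll
}

# Discrete-time Gaussian HMM EM (Baum-Welch) with an unconstrained
# transition matrix, run on a list of observation matrices. Independent of
# the package's CTHMM code; used for the equal-gap reduction check.
discrete_hmm_em <- function(A, pi0, means, variances, obs_list,
                            max_iters = 200, rel_tol = 1e-8) {
  M <- nrow(means)
  K <- ncol(means)
  ll_old <- -Inf
  trace <- numeric(0)
  for (iter in seq_len(max_iters)) {
    ll <- 0
    expN <- matrix(0, M, M)
    g0 <- numeric(M)
    m0 <- numeric(M); m1 <- matrix(0, M, K); m2 <- matrix(0, M, K)
    for (obs in obs_list) {
      Tn <- nrow(obs)
      logb <- sapply(seq_len(M), function(m) {
        rowSums(dnorm(obs, matrix(means[m, ], Tn, K, byrow = TRUE),
                      matrix(sqrt(variances[m, ]), Tn, K, byrow = TRUE),
                      log = TRUE))
      })
      logb <- matrix(logb, nrow = Tn)
      bmax <- apply(logb, 1, max)
      b <- exp(logb - bmax)
      alpha <- matrix(0, Tn, M); cv <- numeric(Tn)
      a <- pi0 * b[1, ]; cv[1] <- sum(a); alpha[1, ] <- a / cv[1]
      if (Tn > 1) {
        for (t in 2:Tn) {
          a <- as.numeric(alpha[t - 1, ] %*% A) * b[t, ]
          cv[t] <- sum(a); alpha[t, ] <- a / cv[t]
        }
      }
      ll <- ll + sum(log(cv)) + sum(bmax)
      beta <- matrix(0, Tn, M); beta[Tn, ] <- 1
      if (Tn > 1) {
        for (t in (Tn - 1):1) {
          beta[t, ] <- as.numeric(A %*% (b[t + 1, ] * beta[t + 1, ])) /
            cv[t + 1]
        }
      }
      g <- alpha * beta; g <- g / rowSums(g)
      g0 <- g0 + g[1, ]
      m0 <- m0 + colSums(g)
      m1 <- m1 + t(g) %*% obs
      m2 <- m2 + t(g) %*% obs^2
      if (Tn > 1) {
        for (t in 2:Tn) {
          x <- outer(alpha[t - 1, ], b[t, ] * beta[t, ]) * A
          expN <- expN + x / sum(x)
        }
      }
    }
    trace <- c(trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) <= rel_tol * abs(ll_old)) break
    ll_old <- ll
    rs <- rowSums(expN)
    for (i in seq_len(M)) {
      A[i, ] <- if (rs[i] > 0) expN[i, ] / rs[i] else A[i, ]
    }
    pi0 <- g0 / sum(g0)
    w <- pmax(m0, 1e-12)
    means <- m1 / w
    variances <- pmax(m2 / w - means^2, 1e-6)
  }
  list(A = A, pi = pi0, means = means, variances = variances,
       loglik = trace[length(trace)], trace = trace)
}

# Vectorized Gillespie simulation of n CTMC paths over [0, delta] from a
# common start state. Returns the end state, the per-state occupancy time
# and the per-pair jump count of every path — the raw material for
# endpoint-conditioned Monte-Carlo expectations.
mc_ctmc_paths <- function(Q, start, delta, n) {
  M <- nrow(Q)
  state <- rep.int(start, n)
  tnow <- numeric(n)
  R <- matrix(0, n, M)
  N <- matrix(0, n, M * M)          # column (l - 1) * M + k counts k -> l
  active <- rep(TRUE, n)
  while (any(active)) {
    idx <- which(active)
    s <- state[idx]
    rate <- -diag(Q)[s]
    done <- rate <= 0
    if (any(done)) {
      di <- idx[done]
      R[cbind(di, state[di])] <- R[cbind(di, state[di])] + delta - tnow[di]
      active[di] <- FALSE
      idx <- idx[!done]
      if (!length(idx)) next
      s <- state[idx]
      rate <- -diag(Q)[s]
    }
    dt <- rexp(length(idx), rate)
    over <- tnow[idx] + dt >= delta
    if (any(over)) {
      oi <- idx[over]
      R[cbind(oi, state[oi])] <- R[cbind(oi, state[oi])] +
        delta - tnow[oi]
      active[oi] <- FALSE
    }
    mv <- idx[!over]
    if (length(mv)) {
      sfrom <- state[mv]
      R[cbind(mv, sfrom)] <- R[cbind(mv, sfrom)] + dt[!over]
      tnow[mv] <- tnow[mv] + dt[!over]
      # sample next state per path
      u <- runif(length(mv))
      P <- Q[sfrom, , drop = FALSE]
      P[cbind(seq_along(mv), sfrom)] <- 0
      P <- P / rowSums(P)
      cum <- t(apply(P, 1, cumsum))
      sto <- max.col(u < cum, ties.method = "first")
      N[cbind(mv, (sto - 1) * M + sfrom)] <-
        N[cbind(mv, (sto - 1) * M + sfrom)] + 1
      state[mv] <- sto
    }
  }
  list(end = state, R = R, N = N)
}

# Best state relabeling (over all permutations, feasible for small M) that
# minimizes the squared distance between estimated and true mean matrices.
match_states <- function(est_means, true_means) {
  M <- nrow(true_means)
  perms <- as.matrix(expand.grid(rep(list(seq_len(M)), M)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == M), ,
                 drop = FALSE]
  costs <- apply(perms, 1, function(p) {
    sum((est_means[p, , drop = FALSE] - true_means)^2)
  })
  perms[which.min(costs), ]
}
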