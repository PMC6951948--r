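# Initialization, E-step sufficient statistics, M-step updates, full EM.

test_that("initialization finds cluster structure and is deterministic", {
  set.seed(30)
  mask <- structure_mask(2, "forward_chain", order = 1)
  # two well-separated 1-D blobs spread over patients
  patients <- lapply(1:40, function(i) {
    v <- c(rnorm(2, 0), rnorm(2, 8))
    patient_series(paste0("p", i), 0:3, matrix(v, 4, 1))
  })
  cohort <- cthmm_cohort(patients, "f1")
  p1 <- initialize_params(cohort, mask, seed = 5)
  expect_lt(abs(p1$means[1, 1] - 0), 0.5)
  expect_lt(abs(p1$means[2, 1] - 8), 0.5)
  expect_true(p1$means[1, 1] < p1$means[2, 1])  # severity-ordered

  p2 <- initialize_params(cohort, mask, seed = 5)
  expect_identical(p1$Q, p2$Q)
  expect_identical(p1$means, p2$means)
  expect_identical(p1$pi, p2$pi)

  # structure of the starting generator under the 9-state preset mask
  preset <- hd_preset(60, seed = 2)
  sim <- simulate_cohort(preset)
  mask9 <- preset$params$mask
  p9 <- initialize_params(sim$cohort, mask9, seed = 1)
  off <- p9$Q; diag(off) <- 0
  expect_true(all(off[!mask9$allowed] == 0))
  expect_true(all(p9$Q[9, ] == 0))
  for (i in 1:7) {
    expect_setequal(which(off[i, ] != 0), c(i + 1, i + 2))
  }
})

test_that("E-step accumulation matches a direct forward-backward reference", {
  # reference path: public forward_backward + conditioned_expectations,
  # accumulated in plain R; the E-step itself runs in compiled code
  set.seed(35)
  params <- random_params(3, 2, kind = "forward_chain")
  sim <- simulate_cohort(scenario_config(params, 15, mean_visits = 4,
                                         seed = 35))
  stats <- e_step(params, sim$cohort)

  M <- 3
  exp_N <- matrix(0, M, M)
  exp_R <- numeric(M)
  loglik <- 0
  for (p in sim$cohort$patients) {
    fb <- forward_backward(params, p)
    loglik <- loglik + fb$loglik
    Tn <- length(p$times)
    if (Tn < 2) next
    gaps <- round(diff(p$times), 6)
    for (t in seq_len(Tn - 1)) {
      ce <- conditioned_expectations(params$Q, gaps[t])
      xi <- fb$xi[t, , ]
      for (k in 1:M) {
        exp_R[k] <- exp_R[k] + sum(xi * ce$ER[, , k])
        for (l in 1:M) {
          exp_N[k, l] <- exp_N[k, l] + sum(xi * ce$EN[, , k, l])
        }
      }
    }
  }
  expect_equal(stats$exp_N, exp_N, tolerance = 1e-10)
  expect_equal(stats$exp_R, exp_R, tolerance = 1e-10)
  expect_equal(stats$loglik, loglik, tolerance = 1e-10)
})

test_that("E-step statistics respect the conservation laws", {
  set.seed(31)
  params <- random_params(3, 2, kind = "forward_chain")
  sim <- simulate_cohort(scenario_config(params, 40, mean_visits = 4,
                                         seed = 31))
  stats <- e_step(params, sim$cohort)
  followup <- sum(sapply(sim$cohort$patients,
                         function(p) max(p$times) - min(p$times)))
  expect_equal(sum(stats$exp_R), followup, tolerance = 1e-6 * followup)
  off <- params$Q; diag(off) <- 0
  expect_true(all(stats$exp_N[off == 0] == 0))
  expect_true(all(stats$exp_N >= 0) && all(stats$exp_R >= 0))
  expect_equal(rowSums(stats$first_visit_gamma),
               rep(1, length(sim$cohort$patients)), tolerance = 1e-10)
  # loglik reported by the E-step matches the cohort likelihood
  expect_equal(stats$loglik, cohort_loglik(params, sim$cohort),
               tolerance = 1e-10)
})

test_that("single-visit patients contribute no transition statistics", {
  set.seed(32)
  params <- random_params(2, 1, kind = "full")
  patients <- lapply(1:5, function(i) {
    patient_series(paste0("s", i), 0, matrix(rnorm(1), 1, 1))
  })
  cohort <- cthmm_cohort(patients, params$features)
  stats <- e_step(params, cohort)
  expect_true(all(stats$exp_N == 0))
  expect_true(all(stats$exp_R == 0))
  g <- do.call(rbind, lapply(cohort$patients, function(p) {
    forward_backward(params, p)$gamma
  }))
  obs <- do.call(rbind, lapply(cohort$patients, `[[`, "observations"))
  expect_equal(stats$moment1, t(g) %*% obs, tolerance = 1e-12)
})

test_that("two-visit pinned endpoints reproduce one conditioned expectation", {
  # near-degenerate emissions force the posterior onto endpoints (1, 2)
  mask <- structure_mask(2, "full")
  Q <- matrix(c(-0.6, 0.6, 0.3, -0.3), 2, 2, byrow = TRUE)
  params <- cthmm_params(Q, c(0.5, 0.5), matrix(c(0, 50), 2, 1),
                         matrix(1e-4, 2, 1), mask)
  patient <- patient_series("p", c(0, 1.5), matrix(c(0, 50), 2, 1))
  stats <- e_step(params, cthmm_cohort(list(patient), params$features))
  ce <- conditioned_expectations(Q, 1.5)
  expect_equal(stats$exp_R, ce$ER[1, 2, ], tolerance = 1e-6)
  expect_equal(stats$exp_N[1, 2], ce$EN[1, 2, 1, 2], tolerance = 1e-6)
  expect_equal(stats$exp_N[2, 1], ce$EN[1, 2, 2, 1], tolerance = 1e-6)
})

test_that("M-step reproduces closed-form updates from hard posteriors", {
  mask <- structure_mask(2, "full")
  ctrl <- fit_control()
  # two patients surely starting in states 1 and 2
  stats <- structure(list(
    exp_N = matrix(c(0, 2, 1, 0), 2, 2, byrow = TRUE),
    exp_R = c(4, 2),
    first_visit_gamma = rbind(c(1, 0), c(0, 1)),
    moment0 = c(2, 2),
    moment1 = matrix(c(4, 0), 2, 1),    # state 1 saw {1, 3}
    moment2 = matrix(c(10, 0), 2, 1),
    loglik = 0), class = "cthmm_esuffstats")
  params <- m_step(stats, mask, ctrl)
  expect_equal(params$pi, c(0.5, 0.5))
  expect_equal(params$means[1, 1], 2.0)
  expect_equal(params$variances[1, 1], 1.0)
  expect_equal(params$Q[1, 2], 2 / 4)
  expect_equal(params$Q[2, 1], 1 / 2)
  expect_equal(rowSums(params$Q), c(0, 0))

  # masked entries stay zero regardless of the statistics
  fwd <- structure_mask(3, "forward")
  stats3 <- structure(list(
    exp_N = matrix(1, 3, 3), exp_R = c(1, 1, 1),
    first_visit_gamma = rbind(c(1, 0, 0)),
    moment0 = rep(1, 3), moment1 = matrix(0, 3, 1),
    moment2 = matrix(1, 3, 1), loglik = 0), class = "cthmm_esuffstats")
  p3 <- m_step(stats3, fwd, ctrl)
  expect_equal(p3$Q[3, 1], 0)
  expect_equal(p3$Q[2, 1], 0)

  # degenerate state: transitions out but no sojourn time
  statsd <- stats3
  statsd$exp_R <- c(1, 0, 1)
  expect_error(m_step(statsd, fwd, ctrl), "degenerate state 2")
})

test_that("EM increases the likelihood and recovers known parameters", {
  truth <- recovery_truth()
  sim <- simulate_cohort(scenario_config(truth, 300, mean_visits = 5,
                                         seed = 41))
  fit <- fit_cthmm(sim$cohort, truth$mask,
                   fit_control(num_restarts = 2, max_iters = 200, seed = 4))
  tr <- fit$loglik_trace
  expect_true(all(diff(tr) >= -1e-8 * abs(tr[-length(tr)])))

  perm <- match_states(fit$params$means, truth$means)
  expect_lt(max(abs(fit$params$means[perm, ] - truth$means)), 0.15)

  # masked entries stay exactly zero through the whole fit
  off <- fit$params$Q; diag(off) <- 0
  expect_true(all(off[!truth$mask$allowed] == 0))
})

test_that("patient order does not change the fitted statistics", {
  set.seed(43)
  params <- random_params(3, 2, kind = "forward_chain")
  sim <- simulate_cohort(scenario_config(params, 30, mean_visits = 4,
                                         seed = 43))
  s1 <- e_step(params, sim$cohort)
  rev_cohort <- cthmm_cohort(rev(sim$cohort$patients),
                             sim$cohort$features)
  s2 <- e_step(params, rev_cohort)
  expect_equal(s1$exp_N, s2$exp_N, tolerance = 1e-10)
  expect_equal(s1$exp_R, s2$exp_R, tolerance = 1e-10)
  expect_equal(s1$moment1, s2$moment1, tolerance = 1e-10)
  expect_equal(s1$loglik, s2$loglik, tolerance = 1e-10)
})

test_that("equal annual gaps give an EM stationary point matching a discrete HMM", {
  truth <- recovery_truth()
  # annual visits exactly: gamma gaps replaced by constant 1-year spacing
  set.seed(44)
  patients <- lapply(1:150, function(n) {
    Tn <- 4
    start <- sample(1:3, 1, prob = truth$pi)
    path <- sample_ctmc_path(truth$Q, start, t_max = Tn + 1)
    st <- path$states[findInterval(0:(Tn - 1), path$times)]
    obs <- matrix(rnorm(Tn * 3, truth$means[st, ], 1), Tn, 3)
    patient_series(paste0("p", n), 0:(Tn - 1), obs)
  })
  cohort <- cthmm_cohort(patients, truth$features)
  fit <- fit_cthmm(cohort, truth$mask,
                   fit_control(num_restarts = 1, max_iters = 300,
                               rel_tol = 1e-9, seed = 3))
  # likelihood agreement at matched parameters
  A <- unclass(transition_matrix(fit$params$Q, 1))
  ll_disc <- sum(sapply(patients, function(p) {
    discrete_hmm_loglik(A, fit$params$pi, fit$params$means,
                        fit$params$variances, p$observations)
  }))
  expect_equal(fit$loglik, ll_disc, tolerance = 1e-8)

  # an independent discrete-time EM started at the matched point should not
  # find a meaningfully better optimum
  obs_list <- lapply(patients, `[[`, "observations")
  dem <- discrete_hmm_em(A, fit$params$pi, fit$params$means,
                         fit$params$variances, obs_list,
                         max_iters = 300, rel_tol = 1e-10)
  expect_lt(abs(dem$loglik - fit$loglik), 1e-4 * abs(fit$loglik))
})
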