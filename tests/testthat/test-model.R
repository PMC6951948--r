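# Gaussian emissions, forward-backward posteriors, Viterbi decoding,
# prediction.

test_that("emission log-density matches the product of univariate normals", {
  set.seed(1)
  params <- random_params(4, 3)
  z <- rnorm(3)
  got <- emission_loglik(z, params)
  want <- sapply(1:4, function(m) {
    sum(dnorm(z, params$means[m, ], sqrt(params$variances[m, ]), log = TRUE))
  })
  expect_equal(got, want, tolerance = 1e-12)

  # density 1 at the mean when sigma^2 = 1/(2*pi)
  p1 <- cthmm_params(matrix(0, 2, 2), c(0.5, 0.5),
                     means = matrix(c(1, 5), 2, 1),
                     variances = matrix(1 / (2 * pi), 2, 1),
                     mask = structure_mask(2, "full"))
  expect_equal(emission_loglik(1, p1)[1], 0, tolerance = 1e-12)

  # identical parameters across states give identical entries
  peq <- cthmm_params(matrix(0, 3, 3), rep(1 / 3, 3),
                      means = matrix(1, 3, 2), variances = matrix(2, 3, 2),
                      mask = structure_mask(3, "full"))
  expect_equal(diff(emission_loglik(c(0.3, -1), peq)), c(0, 0))

  expect_error(emission_loglik(c(1, NA, 2), params), "non-finite")
})

test_that("forward-backward log-likelihood equals brute-force enumeration", {
  set.seed(2)
  for (rep in 1:10) {
    M <- sample(2:3, 1)
    params <- random_params(M, K = 2,
                            kind = sample(c("full", "forward_chain"), 1))
    patient <- random_patient(params, Tn = sample(2:5, 1))
    fb <- forward_backward(params, patient)
    expect_equal(fb$loglik, enumeration_loglik(params, patient),
                 tolerance = 1e-10)
    expect_equal(rowSums(fb$gamma), rep(1, length(patient$times)),
                 tolerance = 1e-12)
  }
})

test_that("posteriors are internally consistent", {
  set.seed(3)
  params <- random_params(4, 3, kind = "forward_chain")
  patient <- random_patient(params, Tn = 6)
  fb <- forward_backward(params, patient)
  for (t in 1:5) {
    xi <- fb$xi[t, , ]
    expect_equal(sum(xi), 1, tolerance = 1e-10)
    expect_equal(rowSums(xi), fb$gamma[t, ], tolerance = 1e-8)
    expect_equal(colSums(xi), fb$gamma[t + 1, ], tolerance = 1e-8)
  }
})

test_that("a single-visit series reduces to the prior-weighted density", {
  set.seed(4)
  params <- random_params(3, 2)
  patient <- patient_series("s", 0, matrix(rnorm(2), 1, 2))
  fb <- forward_backward(params, patient)
  lb <- emission_loglik(patient$observations[1, ], params)
  expect_equal(fb$loglik, log(sum(params$pi * exp(lb))), tolerance = 1e-12)
  expect_equal(fb$gamma[1, ], params$pi * exp(lb) / sum(params$pi * exp(lb)),
               tolerance = 1e-12)
})

test_that("likelihood is invariant to shifting all visit times", {
  set.seed(5)
  params <- random_params(3, 2)
  patient <- random_patient(params, Tn = 4)
  shifted <- patient_series("s2", patient$times + 13.7,
                            patient$observations)
  expect_equal(forward_backward(params, patient)$loglik,
               forward_backward(params, shifted)$loglik, tolerance = 1e-12)
  expect_equal(viterbi(params, patient)$states,
               viterbi(params, shifted)$states)
})

test_that("cohort log-likelihood adds independent patients", {
  set.seed(6)
  params <- random_params(3, 2)
  p1 <- random_patient(params, 3, id = "a")
  p2 <- random_patient(params, 4, id = "b")
  ll1 <- forward_backward(params, p1)$loglik
  ll2 <- forward_backward(params, p2)$loglik
  cohort <- cthmm_cohort(list(p1, p2), params$features)
  expect_equal(cohort_loglik(params, cohort), ll1 + ll2, tolerance = 1e-12)

  dup <- cthmm_cohort(list(p1, patient_series("a2", p1$times,
                                              p1$observations)),
                      params$features)
  expect_equal(cohort_loglik(params, dup), 2 * ll1, tolerance = 1e-12)
})

test_that("Viterbi recovers well-separated generating sequences", {
  set.seed(7)
  mask <- structure_mask(3, "forward_chain", order = 2)
  Q <- random_generator(mask)
  means <- matrix(c(0, 10, 20), 3, 2)
  params <- cthmm_params(Q, c(1, 0, 0), means, matrix(1, 3, 2), mask)
  sim <- simulate_cohort(scenario_config(params, 100, mean_visits = 5,
                                         seed = 70))
  decoded <- decode_cohort(params, sim$cohort)
  acc <- mean(decoded$state == sim$states$state)
  expect_gte(acc, 0.99)
  # monotone under a forward-chain structure
  for (p in split(decoded$state, decoded$patient_id)) {
    expect_true(all(diff(p) >= 0))
  }
})

test_that("Viterbi beats random valid sequences and degenerates sanely", {
  set.seed(8)
  params <- random_params(3, 2, kind = "full")
  patient <- random_patient(params, 5)
  v <- viterbi(params, patient)
  best <- sequence_logprob(params, patient, v$states)
  for (i in 1:200) {
    rand <- sample(1:3, 5, replace = TRUE)
    expect_gte(best + 1e-10, sequence_logprob(params, patient, rand))
  }

  # M = 1: the only sequence
  p1 <- cthmm_params(matrix(0, 2, 2), c(1, 0), matrix(0, 2, 1),
                     matrix(1, 2, 1), structure_mask(2, "full"))
  # with pi = (1, 0) and zero rates everything stays in state 1
  pt <- patient_series("x", c(0, 1, 2), matrix(rnorm(3), 3, 1))
  expect_equal(viterbi(p1, pt)$states, rep(1L, 3))
})

test_that("prediction propagates the last posterior through A(horizon)", {
  set.seed(9)
  params <- random_params(3, 2, kind = "forward_chain",
                          absorbing_last = TRUE)
  patient <- random_patient(params, 3)
  fb <- forward_backward(params, patient)

  pr0 <- predict_future(params, patient, 0)
  expect_equal(pr0$state_probs, fb$gamma[3, ], tolerance = 1e-12)

  pr <- predict_future(params, patient, 2.5)
  direct <- as.numeric(fb$gamma[3, ] %*% transition_matrix(params$Q, 2.5))
  expect_equal(pr$state_probs, direct, tolerance = 1e-10)
  expect_equal(unname(pr$expected_features),
               as.numeric(direct %*% params$means), tolerance = 1e-10)

  # absorbing chain swallows all mass in the long run
  prl <- predict_future(params, patient, 1e6)
  expect_gte(prl$state_probs[3], 1 - 1e-6)

  expect_error(predict_future(params, patient, -1), "horizon")
})

test_that("equal gaps reduce the CTHMM to a discrete-time HMM", {
  set.seed(10)
  params <- random_params(3, 2, kind = "forward_chain")
  A <- transition_matrix(params$Q, 1)
  for (rep in 1:5) {
    Tn <- sample(3:6, 1)
    obs <- matrix(rnorm(Tn * 2, sd = 2), Tn, 2)
    patient <- patient_series("p", 0:(Tn - 1), obs)
    expect_equal(forward_backward(params, patient)$loglik,
                 discrete_hmm_loglik(unclass(A), params$pi, params$means,
                                     params$variances, obs),
                 tolerance = 1e-8)
  }
})
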