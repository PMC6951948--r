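# Cohort simulator: Gillespie paths through the hidden chain, irregular
# visit schedules with left-truncated entry, Gaussian observations.
# Provides ground truth for estimation and selection studies.

#' Simulation scenario configuration
#'
#' Describes a generative cohort: ground-truth parameters, the number of
#' patients, the visit schedule (a shifted-Poisson visit count and
#' gamma-distributed gaps around one year, emulating roughly annual study
#' visits), and a random entry time into the disease course that emulates
#' left truncation — observational records cover only a window of each
#' patient's trajectory.
#'
#' @param params ground-truth [cthmm_params()].
#' @param num_patients number of patients to simulate.
#' @param mean_visits mean number of visits per patient; the count is
#'   `1 + Poisson(mean_visits - 1)`, truncated at `max_visits`.
#' @param max_visits upper bound on visits per patient.
#' @param gap_shape,gap_rate gamma parameters of inter-visit gaps in years
#'   (defaults give mean 1 year, sd about 0.29).
#' @param entry_max patients enter observation at a time drawn uniformly
#'   from `[0, entry_max]` years into the disease course; 0 disables left
#'   truncation.
#' @param time_digits visit times are rounded to this many decimals of a
#'   year (2 digits is about date-level precision).
#' @param seed integer seed.
#' @return A list of class `cthmm_scenario`.
#' @export
scenario_config <- function(params, num_patients,
                            mean_visits = 2.9, max_visits = 25L,
                            gap_shape = 12, gap_rate = 12,
                            entry_max = 0, time_digits = 2L, seed = 1L) {
  stopifnot(inherits(params, "cthmm_params"), num_patients >= 1,
            mean_visits >= 1, max_visits >= 1, gap_shape > 0, gap_rate > 0,
            entry_max >= 0)
  structure(list(params = params, num_patients = as.integer(num_patients),
                 mean_visits = mean_visits,
                 max_visits = as.integer(max_visits),
                 gap_shape = gap_shape, gap_rate = gap_rate,
                 entry_max = entry_max, time_digits = as.integer(time_digits),
                 seed = as.integer(seed)),
            class = "cthmm_scenario")
}

#' Simulate one trajectory of the hidden chain
#'
#' Gillespie-style simulation: exponential holding time with rate
#' `-Q[i, i]`, next state drawn proportionally to `Q[i, j]`. The path ends
#' at `t_max` or on entering an absorbing state.
#'
#' @param Q generator matrix.
#' @param start_state initial state (1-based).
#' @param t_max simulation horizon in years.
#' @return A list with `times` (jump epochs, starting at 0) and `states`
#'   (state entered at each epoch).
#' @export
sample_ctmc_path <- function(Q, start_state, t_max) {
  M <- nrow(Q)
  if (!is.numeric(start_state) || length(start_state) != 1L ||
      start_state < 1 || start_state > M) {
    stop("'start_state' must be a state index in 1..M", call. = FALSE)
  }
  if (t_max <= 0) stop("'t_max' must be positive", call. = FALSE)
  t <- 0
  s <- as.integer(start_state)
  times <- t
  states <- s
  repeat {
    rate <- -Q[s, s]
    if (rate <= 0) break                     # absorbing
    t <- t + rexp(1, rate)
    if (t >= t_max) break
    probs <- Q[s, ]
    probs[s] <- 0
    s <- sample.int(M, 1L, prob = probs)
    times <- c(times, t)
    states <- c(states, s)
  }
  list(times = times, states = states)
}

state_at_times <- function(path, at) {
  path$states[findInterval(at, path$times)]
}

#' Simulate a cohort from a scenario
#'
#' Per patient: draw an entry time into the disease course, simulate the
#' hidden trajectory, lay down a visit schedule, read off the state at each
#' visit, and emit Gaussian observations with that state's means and
#' variances. Visit times in the returned cohort are rebased to the first
#' visit. Deterministic given the scenario seed.
#'
#' @param config a [scenario_config()].
#' @return A list of class `cthmm_simulation` with `cohort` (a
#'   [cthmm_cohort()]) and `states` (a data frame `patient_id`,
#'   `visit_time`, `state` of ground-truth states aligned with the cohort).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cthmm_scenario"))
  params <- config$params
  M <- num_states(params)
  K <- num_features(params)
  sds <- sqrt(params$variances)
  set.seed(config$seed)

  patients <- vector("list", config$num_patients)
  truth <- vector("list", config$num_patients)
  min_gap <- 10^(-config$time_digits)
  for (n in seq_len(config$num_patients)) {
    Tn <- min(1L + rpois(1, config$mean_visits - 1), config$max_visits)
    entry <- if (config$entry_max > 0) runif(1, 0, config$entry_max) else 0
    gaps <- pmax(rgamma(max(Tn - 1, 0), config$gap_shape, config$gap_rate),
                 min_gap)
    visit_abs <- entry + cumsum(c(0, gaps))
    visit_abs <- round(visit_abs, config$time_digits)
    # rounding can merge very close visits; push apart by the grid step
    while (any(diff(visit_abs) <= 0)) {
      i <- which(diff(visit_abs) <= 0)[1] + 1
      visit_abs[i:Tn] <- visit_abs[i:Tn] + min_gap
    }
    start <- sample.int(M, 1L, prob = params$pi)
    path <- sample_ctmc_path(params$Q, start,
                             t_max = max(visit_abs) + 1)
    st <- state_at_times(path, visit_abs)
    obs <- matrix(rnorm(Tn * K, mean = params$means[st, ],
                        sd = sds[st, ]), Tn, K)
    id <- sprintf("P%05d", n)
    times <- round(visit_abs - visit_abs[1], config$time_digits)
    patients[[n]] <- patient_series(id, times, obs)
    truth[[n]] <- data.frame(patient_id = id, visit_time = times,
                             state = st, stringsAsFactors = FALSE)
  }
  structure(list(cohort = cthmm_cohort(patients, params$features),
                 states = do.call(rbind, truth)),
            class = "cthmm_simulation")
}

#' Preset scenario: a nine-state progressive disease cohort
#'
#' A second-order forward-chain progression model with an absorbing ninth
#' state, mimicking the structure of large integrated observational cohorts
#' of a slowly progressing neurodegenerative disease. Diagonal rates are
#' set so the expected state durations are 9.7, 9.2, 3.8, 2.9, 5.8, 3.5,
#' 3.0 and 3.2 years; the outgoing rate of each state is split 80/20
#' between the one-step and two-step jumps, except out of states 3 and 4
#' where the two-step ("skipping") mass is enlarged to 45%, reflecting
#' alternative progression pathways through the transition period. Nine
#' features in three clinical domains (three motor factors trending up,
#' three functional and three cognitive factors trending down) have unit
#' variances and adjacent-state mean separation of about 2 standard
#' deviations; the mean values are illustrative, not estimates. Patients
#' enter observation uniformly over the first 30 years of the disease
#' course and average 2.9 roughly annual visits.
#'
#' @param num_patients cohort size.
#' @param seed scenario seed.
#' @return A [scenario_config()].
#' @export
hd_preset <- function(num_patients = 1000L, seed = 1L) {
  M <- 9L
  durations <- c(9.7, 9.2, 3.8, 2.9, 5.8, 3.5, 3.0, 3.2)
  mask <- structure_mask(M, "forward_chain", order = 2L,
                         absorbing_last = TRUE)
  Q <- matrix(0, M, M)
  for (i in 1:8) {
    rate <- 1 / durations[i]
    skip <- if (i %in% c(3, 4)) 0.45 else 0.20
    if (i <= 7) {
      Q[i, i + 1] <- (1 - skip) * rate
      Q[i, i + 2] <- skip * rate
    } else {
      Q[i, i + 1] <- rate                  # state 8 can only step to 9
    }
    Q[i, i] <- -rate
  }

  step <- 2                                # ~2 sd between adjacent states
  m_idx <- seq_len(M) - 1
  means <- cbind(
    motor1      =  step * m_idx,
    motor2      =  step * m_idx * 0.9 + 0.2,
    motor3      =  step * m_idx * 1.1 - 0.2,
    functional1 = -step * m_idx,
    functional2 = -step * m_idx * 0.95 + 0.1,
    functional3 = -step * m_idx * 1.05 - 0.1,
    cognitive1  = -step * m_idx * 0.9,
    cognitive2  = -step * m_idx * 1.0 + 0.15,
    cognitive3  = -step * m_idx * 1.1 - 0.15
  )
  variances <- matrix(1, M, ncol(means))
  pi0 <- c(1, rep(0, M - 1))               # disease course starts in state 1
  params <- cthmm_params(Q, pi0, means, variances, mask,
                         features = colnames(means))
  scenario_config(params, num_patients = num_patients,
                  mean_visits = 2.9, max_visits = 25L,
                  entry_max = 30, seed = seed)
}
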