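# EM estimation: initialization, E-step sufficient statistics with
# endpoint-conditioned expectations, M-step closed-form updates,
# convergence control with random restarts.

#' Control settings for EM fitting
#'
#' @param max_iters maximum EM iterations per restart.
#' @param rel_tol stop when the relative change in log-likelihood between
#'   iterations falls below this.
#' @param num_restarts number of random restarts; the restart with the
#'   highest final log-likelihood wins.
#' @param seed base seed; restart `r` uses `seed + r - 1`.
#' @param variance_floor lower bound on emission variances, preventing
#'   collapse of a state onto single observations.
#' @param rate_min,rate_max bounds on estimated transition rates (per
#'   year), keeping the matrix exponentials well conditioned; sojourns of
#'   clinical interest span days to decades.
#'
#' @return A list of class `cthmm_fit_control`.
#' @export
fit_control <- function(max_iters = 500L, rel_tol = 1e-6,
                        num_restarts = 3L, seed = 1L,
                        variance_floor = 1e-6,
                        rate_min = 1e-6, rate_max = 1e3) {
  stopifnot(max_iters >= 1, rel_tol > 0, num_restarts >= 1,
            variance_floor > 0, rate_min > 0, rate_max > rate_min)
  structure(list(max_iters = as.integer(max_iters), rel_tol = rel_tol,
                 num_restarts = as.integer(num_restarts),
                 seed = as.integer(seed), variance_floor = variance_floor,
                 rate_min = rate_min, rate_max = rate_max),
            class = "cthmm_fit_control")
}

#' Data-driven starting parameters
#'
#' K-means with `M` clusters on the pooled visit features supplies starting
#' emission means and within-cluster variances. Clusters are relabeled in
#' ascending order of a severity score: the projection of the cluster
#' center onto the first principal direction of the pooled features, with
#' the sign chosen so that the score increases over within-patient time.
#' The initial distribution is the (smoothed) cluster frequency among first
#' visits; starting rates put most mass on the first allowed jump per row.
#' Deterministic given the seed.
#'
#' @param cohort a [cthmm_cohort()].
#' @param mask a [structure_mask()].
#' @param seed integer seed for k-means.
#' @return A [cthmm_params()] object.
#' @export
initialize_params <- function(cohort, mask, seed = 1L) {
  stopifnot_mask(mask)
  M <- mask$num_states
  pooled <- do.call(rbind, lapply(cohort$patients,
                                  function(p) p$observations))
  if (nrow(unique(pooled)) < M) {
    stop(sprintf("need at least %d distinct observation vectors for %d states",
                 M, M), call. = FALSE)
  }
  set.seed(seed)
  km <- kmeans(pooled, centers = M, nstart = 5, iter.max = 50)

  # severity direction: first principal axis, signed to increase with time
  pc1 <- prcomp(pooled, center = TRUE, scale. = FALSE)$rotation[, 1]
  proj <- as.numeric(scale(pooled, scale = FALSE) %*% pc1)
  tcent <- unlist(lapply(cohort$patients,
                         function(p) p$times - mean(p$times)))
  if (sum(proj * tcent) < 0) {
    proj <- -proj
    pc1 <- -pc1
  }
  center_score <- vapply(seq_len(M), function(m) {
    mean(proj[km$cluster == m])
  }, numeric(1))
  ord <- order(center_score)
  relabel <- match(seq_len(M), ord)        # old label -> severity rank
  cl <- relabel[km$cluster]

  K <- ncol(pooled)
  means <- km$centers[ord, , drop = FALSE]
  variances <- matrix(1, M, K)
  for (m in seq_len(M)) {
    pts <- pooled[cl == m, , drop = FALSE]
    v <- if (nrow(pts) > 1) apply(pts, 2, var) else rep(1, K)
    variances[m, ] <- pmax(v, 1e-4)
  }

  first_idx <- cumsum(c(1, head(vapply(cohort$patients,
                                       function(p) length(p$times),
                                       integer(1)), -1)))
  first_cl <- cl[first_idx]
  pi0 <- (tabulate(first_cl, M) + 1 / M)
  pi0 <- pi0 / sum(pi0)

  Q <- matrix(0, M, M)
  init_rates <- c(0.3, 0.05)
  for (i in seq_len(M)) {
    cols <- which(mask$allowed[i, ])
    if (!length(cols)) next
    r <- init_rates[seq_along(cols)]
    r[is.na(r)] <- 0.02                    # further allowed jumps, if any
    Q[i, cols] <- r
    Q[i, i] <- -sum(r)
  }
  rownames(means) <- rownames(variances) <- NULL
  cthmm_params(Q, pi0, means, variances, mask, features = cohort$features)
}

#' E-step: expected sufficient statistics over a cohort
#'
#' Runs forward-backward per patient, then converts the pairwise posterior
#' weights of each inter-visit interval into expected transition counts and
#' sojourn times through the endpoint-conditioned expectations of the
#' generator (one set of block-matrix exponentials per distinct gap length,
#' cached; gaps are canonicalized to 1e-6 years first). Emission moments
#' are accumulated with the per-visit posteriors.
#'
#' @param params current [cthmm_params()].
#' @param cohort a [cthmm_cohort()].
#' @return A list of class `cthmm_esuffstats` with `exp_N` (`M x M`
#'   expected transition counts, zero on masked entries), `exp_R` (length
#'   `M` expected sojourn times; their sum equals the total observed
#'   follow-up time), `first_visit_gamma` (`N x M`), emission moment tables
#'   `moment0`, `moment1`, `moment2`, and `loglik` (the cohort
#'   log-likelihood at `params`).
#' @export
e_step <- function(params, cohort) {
  off <- params$Q
  diag(off) <- 0
  pairs <- which(off > 0, arr.ind = TRUE)
  storage.mode(pairs) <- "integer"
  if (!nrow(pairs)) {
    pairs <- matrix(integer(0), 0, 2)
  }
  lens <- vapply(cohort$patients, function(p) length(p$times), integer(1))
  offsets <- cumsum(c(0L, lens[-length(lens)]))
  times <- unlist(lapply(cohort$patients, `[[`, "times"), use.names = FALSE)
  obs <- do.call(rbind, lapply(cohort$patients, `[[`, "observations"))

  res <- estep_cohort_cpp(params$Q, params$pi, params$means,
                          params$variances, pairs - 1L,
                          times, obs, offsets, lens)
  structure(list(exp_N = res$exp_N,
                 exp_R = as.numeric(res$exp_R),
                 first_visit_gamma = res$first_visit_gamma,
                 moment0 = as.numeric(res$moment0),
                 moment1 = res$moment1, moment2 = res$moment2,
                 loglik = res$loglik),
            class = "cthmm_esuffstats")
}

#' M-step: closed-form parameter updates
#'
#' Rates are ratios of expected transition counts to expected sojourn
#' times, `Q[i, j] = exp_N[i, j] / exp_R[i]` on allowed entries (clipped to
#' the configured rate bounds); diagonals restore the zero row sums and
#' absorbing rows stay zero. The initial distribution is the average
#' first-visit posterior; emission means and variances are
#' posterior-weighted moments, variances floored.
#'
#' @param stats a `cthmm_esuffstats` from [e_step()].
#' @param mask a [structure_mask()].
#' @param control a [fit_control()].
#' @param features optional feature names to carry into the result.
#' @return A [cthmm_params()] object.
#' @export
m_step <- function(stats, mask, control = fit_control(), features = NULL) {
  stopifnot_mask(mask)
  M <- mask$num_states
  Q <- matrix(0, M, M)
  for (i in seq_len(M)) {
    cols <- which(mask$allowed[i, ])
    if (!length(cols)) next
    if (stats$exp_R[i] <= 0) {
      if (sum(stats$exp_N[i, cols]) > 1e-12) {
        stop(sprintf(
          "degenerate state %d: expected transitions out but zero expected sojourn time",
          i), call. = FALSE)
      }
      # state effectively unvisited: keep minimal outgoing rates
      Q[i, cols] <- control$rate_min
    } else {
      Q[i, cols] <- pmin(pmax(stats$exp_N[i, cols] / stats$exp_R[i],
                              control$rate_min), control$rate_max)
    }
    Q[i, i] <- -sum(Q[i, cols])
  }

  pi_new <- colMeans(stats$first_visit_gamma)
  pi_new <- pi_new / sum(pi_new)

  w <- pmax(stats$moment0, 1e-12)
  means <- stats$moment1 / w
  variances <- stats$moment2 / w - means^2
  variances <- pmax(variances, control$variance_floor)
  # states with essentially no posterior mass: neutral emissions
  dead <- stats$moment0 < 1e-10
  if (any(dead)) {
    means[dead, ] <- 0
    variances[dead, ] <- 1
  }
  cthmm_params(Q, pi_new, means, variances, mask, features = features)
}

#' Fit a CTHMM to a cohort by EM
#'
#' Alternates [e_step()] and [m_step()] from each restart's k-means
#' initialization until the relative log-likelihood change drops below
#' `control$rel_tol` or `control$max_iters` is reached, and returns the
#' restart with the highest final log-likelihood. Patients with fewer than
#' two visits carry no transition information and are dropped with a
#' message.
#'
#' @param cohort a [cthmm_cohort()]; each patient should have at least two
#'   visits.
#' @param mask a [structure_mask()].
#' @param control a [fit_control()].
#' @return A list of class `cthmm_fit` with `params`, `loglik` (final),
#'   `loglik_trace` (per iteration, non-decreasing up to numerical slack),
#'   `converged`, `iterations`, `seed_used`, `restarts` (per-restart
#'   summary data frame) and `all_traces` (per-restart likelihood traces).
#' @export
fit_cthmm <- function(cohort, mask, control = fit_control()) {
  stopifnot_mask(mask)
  nv <- vapply(cohort$patients, function(p) length(p$times), integer(1))
  if (any(nv < 2)) {
    message(sum(nv < 2),
            " patient(s) with a single visit dropped before fitting")
    cohort <- cthmm_cohort(cohort$patients[nv >= 2], cohort$features)
  }
  if (!length(cohort$patients)) {
    stop("no patients with at least two visits", call. = FALSE)
  }

  run_one <- function(seed_r) {
    params <- initialize_params(cohort, mask, seed = seed_r)
    trace <- numeric(0)
    converged <- FALSE
    for (iter in seq_len(control$max_iters)) {
      stats <- e_step(params, cohort)
      trace <- c(trace, stats$loglik)
      if (iter > 1) {
        prev <- trace[iter - 1]
        if (abs(stats$loglik - prev) <= control$rel_tol * abs(prev)) {
          converged <- TRUE
          break
        }
      }
      params <- m_step(stats, mask, control, features = cohort$features)
    }
    list(params = params, trace = trace, converged = converged,
         iterations = length(trace), seed = seed_r)
  }

  runs <- vector("list", control$num_restarts)
  for (r in seq_len(control$num_restarts)) {
    seed_r <- control$seed + r - 1L
    runs[[r]] <- tryCatch(run_one(seed_r), error = function(e) {
      warning(sprintf("restart %d (seed %d) failed: %s",
                      r, seed_r, conditionMessage(e)), call. = FALSE)
      NULL
    })
  }
  ok <- !vapply(runs, is.null, logical(1))
  if (!any(ok)) {
    stop("all EM restarts failed", call. = FALSE)
  }
  finals <- vapply(runs[ok], function(r) r$trace[length(r$trace)],
                   numeric(1))
  best <- runs[ok][[which.max(finals)]]
  restarts <- data.frame(
    seed = vapply(runs[ok], `[[`, integer(1), "seed"),
    final_loglik = finals,
    iterations = vapply(runs[ok], `[[`, integer(1), "iterations"),
    converged = vapply(runs[ok], `[[`, logical(1), "converged"))
  all_traces <- lapply(runs[ok], `[[`, "trace")

  structure(list(params = best$params,
                 loglik = best$trace[length(best$trace)],
                 loglik_trace = best$trace,
                 converged = best$converged,
                 iterations = best$iterations,
                 seed_used = best$seed,
                 restarts = restarts,
                 all_traces = all_traces),
            class = "cthmm_fit")
}

#' @export
print.cthmm_fit <- function(x, ...) {
  cat(sprintf("CTHMM fit: loglik %.4f after %d iterations (%s)\n",
              x$loglik, x$iterations,
              if (x$converged) "converged" else "max iterations"))
  print(x$params)
  invisible(x)
}
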