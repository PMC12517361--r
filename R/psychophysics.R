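#' Random left/right direction sequence with bounded runs
#'
#' Offset directions are randomized, but no more than `max_run` consecutive
#' trials may share a direction: after a maximal run the next direction is
#' forced to flip. The sequence is balanced in expectation.
#'
#' @param n_trials number of trials.
#' @param max_run maximum run length (default 4).
#' @return character vector of "left"/"right".
#' @export
generate_direction_sequence <- function(n_trials, max_run = 4) {
  stopifnot(n_trials >= 1)
  dirs <- character(n_trials)
  run <- 0L
  for (i in seq_len(n_trials)) {
    d <- if (run >= max_run) {
      if (dirs[i - 1] == "left") "right" else "left"
    } else if (stats::runif(1) < 0.5) "left" else "right"
    run <- if (i > 1 && d == dirs[i - 1]) run + 1L else 1L
    dirs[i] <- d
  }
  dirs
}

#' Initialise a PEST staircase
#'
#' Classical PEST: a Wald sequential test at the target probability decides
#' when to change the offset level; step sizes follow the halving/doubling
#' rules (halve on reversal; the second step in a direction equals the
#' first; later same-direction steps double, except that the step after a
#' reversal that followed a doubling does not double until the third).
#'
#' @param start_offset starting offset (arcsec), default 800.
#' @param max_offset hard cap, default 1600 (twice the start).
#' @param init_step initial step (arcsec).
#' @param min_step smallest step / smallest presentable offset (arcsec).
#' @param target_p tracked proportion correct.
#' @param wald_limit Wald deviation limit W (trials).
#' @return `pest_state` list.
#' @export
pest_init <- function(start_offset = 800, max_offset = 1600,
                      init_step = 400, min_step = 5,
                      target_p = 0.75, wald_limit = 1) {
  stopifnot(start_offset > 0, start_offset <= max_offset)
  structure(list(current_offset = start_offset,
                 step = init_step,
                 max_offset = max_offset, min_step = min_step,
                 target_p = target_p, wald_limit = wald_limit,
                 n_level = 0, c_level = 0,
                 last_direction = 0,       # -1 down (easier->harder), +1 up
                 same_count = 0,
                 last_step_doubled = FALSE,
                 doubled_before_reversal = FALSE,
                 n_hist = 0L,
                 hist_offset = numeric(64),
                 hist_correct = logical(64)),
            class = "pest_state")
}

#' Trial history of a PEST staircase
#' @param state pest_state.
#' @return data.frame with columns offset, correct (one row per trial).
#' @export
pest_history <- function(state) {
  i <- seq_len(state$n_hist)
  data.frame(offset = state$hist_offset[i], correct = state$hist_correct[i])
}

#' Update the PEST staircase with one response
#'
#' @param state a [pest_init()] state.
#' @param response_correct logical.
#' @return updated state; `state$current_offset` is the next offset to
#'   present, never exceeding `max_offset`.
#' @export
pest_update <- function(state, response_correct) {
  k <- state$n_hist + 1L
  if (k > length(state$hist_offset)) {        # amortized growth
    state$hist_offset <- c(state$hist_offset,
                           numeric(length(state$hist_offset)))
    state$hist_correct <- c(state$hist_correct,
                            logical(length(state$hist_correct)))
  }
  state$hist_offset[k] <- state$current_offset
  state$hist_correct[k] <- response_correct
  state$n_hist <- k
  state$n_level <- state$n_level + 1
  state$c_level <- state$c_level + as.integer(response_correct)
  expected <- state$target_p * state$n_level
  dir <- 0
  if (state$c_level - expected >= state$wald_limit) dir <- -1   # too easy
  else if (expected - state$c_level >= state$wald_limit) dir <- 1  # too hard
  if (dir == 0) return(state)
  if (state$last_direction == 0) {            # first level change
    state$same_count <- 1
    state$last_step_doubled <- FALSE
  } else if (dir != state$last_direction) {   # reversal: halve
    state$doubled_before_reversal <- state$last_step_doubled
    state$step <- max(state$min_step, state$step / 2)
    state$same_count <- 1
    state$last_step_doubled <- FALSE
  } else {                                    # same direction
    state$same_count <- state$same_count + 1
    dbl <- (state$same_count >= 4) ||
           (state$same_count == 3 && !state$doubled_before_reversal)
    if (dbl) state$step <- state$step * 2
    state$last_step_doubled <- dbl
  }
  off <- state$current_offset + dir * state$step
  state$current_offset <- min(state$max_offset, max(state$min_step, off))
  state$last_direction <- dir
  state$n_level <- 0
  state$c_level <- 0
  state
}

#' A simulated observer
#'
#' Probability correct is a cumulative Gaussian in log offset with a 0.5
#' guess rate (2-AFC) and a small lapse rate:
#' `P(correct | d) = 0.5 + (0.5 - lapse/2) * pnorm((log d - mu) / sigma)`.
#'
#' @param mu_log location on the natural-log offset axis.
#' @param sigma_log spread.
#' @param lapse lapse rate (default 0.02).
#' @return `sim_observer` list.
#' @export
sim_observer <- function(mu_log, sigma_log, lapse = 0.02) {
  stopifnot(sigma_log >= 0, lapse >= 0, lapse < 1)
  structure(list(mu_log = mu_log, sigma_log = sigma_log, lapse = lapse),
            class = "sim_observer")
}

#' Probability of a correct response
#' @param observer sim_observer.
#' @param offset_arcsec presented offset (> 0).
#' @return probability in [0.5, 1 - lapse/2].
#' @export
p_correct <- function(observer, offset_arcsec) {
  z <- if (observer$sigma_log == 0)
    ifelse(log(offset_arcsec) >= observer$mu_log, 1, 0)
  else stats::pnorm((log(offset_arcsec) - observer$mu_log) / observer$sigma_log)
  0.5 + (0.5 - observer$lapse / 2) * z
}

#' Simulate one 80-trial block
#'
#' Runs the PEST staircase against a simulated observer with the
#' randomized direction sequence (runs capped at 4).
#'
#' @param observer sim_observer.
#' @param n_trials trials per block (default 80).
#' @param state optional pest_state to continue from (a second block of the
#'   same condition continues the staircase).
#' @return list: `trials` data.frame (trial, direction, offset_arcsec,
#'   response_correct), `state` (final pest_state).
#' @export
simulate_block <- function(observer, n_trials = 80, state = pest_init()) {
  dirs <- generate_direction_sequence(n_trials)
  offs <- numeric(n_trials); resp <- logical(n_trials)
  for (i in seq_len(n_trials)) {
    offs[i] <- state$current_offset
    resp[i] <- stats::runif(1) < p_correct(observer, offs[i])
    state <- pest_update(state, resp[i])
  }
  list(trials = data.frame(trial = seq_len(n_trials), direction = dirs,
                           offset_arcsec = offs, response_correct = resp),
       state = state)
}

#' Simulate a full condition measurement (two 80-trial blocks)
#'
#' @param observer sim_observer.
#' @param n_blocks number of 80-trial blocks (default 2, i.e. 160 trials).
#' @param block_trials trials per block.
#' @return data.frame of 160 trials (block column added).
#' @export
simulate_condition_trials <- function(observer, n_blocks = 2,
                                      block_trials = 80) {
  out <- lapply(seq_len(n_blocks), function(b) {
    bl <- simulate_block(observer, block_trials)   # fresh staircase per block
    cbind(block = b, bl$trials)
  })
  do.call(rbind, out)
}

#' Fit a cumulative-Gaussian psychometric function
#'
#' Binomial maximum-likelihood fit of
#' `P(correct) = 0.5 + (0.5 - lapse/2) * pnorm((log d - mu) / sigma)` to
#' the trial table; the threshold is the offset where the fitted function
#' crosses the criterion (default 75% correct). Degenerate data (fewer than
#' two distinct offsets with both outcomes overall, all-correct or
#' all-incorrect responding, or a fitted threshold beyond the 1600''
#' staircase bound) are flagged non-converged with the threshold censored
#' at the bound.
#'
#' @param trials data.frame with columns offset_arcsec, response_correct.
#' @param lapse fixed lapse rate used during fitting.
#' @param criterion threshold criterion (default 0.75).
#' @param max_offset censoring bound (default 1600).
#' @return `psychometric_fit` list: mu_log, sigma_log, threshold_arcsec,
#'   converged, n_trials.
#' @export
fit_psychometric <- function(trials, lapse = 0.02, criterion = 0.75,
                             max_offset = 1600) {
  d <- trials$offset_arcsec
  r <- as.logical(trials$response_correct)
  n <- length(d)
  out <- function(mu, sigma, thr, conv)
    structure(list(mu_log = mu, sigma_log = sigma, threshold_arcsec = thr,
                   converged = conv, n_trials = n),
              class = "psychometric_fit")
  if (length(unique(d)) < 2 || all(r) || !any(r))
    return(out(NA_real_, NA_real_, max_offset, FALSE))
  amp <- 0.5 - lapse / 2
  nll <- function(par) {
    mu <- par[1]; sigma <- exp(par[2])
    p <- 0.5 + amp * stats::pnorm((log(d) - mu) / sigma)
    p <- pmin(pmax(p, 1e-10), 1 - 1e-10)
    -sum(ifelse(r, log(p), log(1 - p)))
  }
  init <- c(mean(log(d)), log(max(stats::sd(log(d)), 0.1)))
  fit <- stats::optim(init, nll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  mu <- fit$par[1]; sigma <- exp(fit$par[2])
  zc <- stats::qnorm((criterion - 0.5) / amp)
  thr <- exp(mu + sigma * zc)
  if (fit$convergence != 0 || !is.finite(thr) || thr > max_offset)
    return(out(mu, sigma, max_offset, FALSE))
  out(mu, sigma, thr, TRUE)
}

#' Map model evidence to a predicted behavioural threshold
#'
#' The link is a strictly decreasing affine map on the log-offset axis:
#' `mu_log(E) = alpha - beta * E` with `beta > 0`, so larger model evidence
#' yields a lower threshold. The full pipeline simulates the standard
#' two-block PEST measurement with that observer and fits the psychometric
#' function post hoc.
#'
#' @param evidence condition-level model evidence E.
#' @param alpha intercept of the link (log-arcsec); default log(800).
#' @param beta slope of the link (>= 0) per unit evidence; 0 collapses all
#'   conditions onto one threshold.
#' @param sigma_log observer spread (default 0.25).
#' @param lapse observer lapse rate.
#' @param simulate if FALSE, return the closed-form threshold of the linked
#'   observer instead of simulating the staircase measurement.
#' @return predicted threshold in arcsec.
#' @export
evidence_to_threshold <- function(evidence, alpha = log(800), beta = 4,
                                  sigma_log = 0.25, lapse = 0.02,
                                  simulate = TRUE) {
  stopifnot(beta >= 0)
  obs <- sim_observer(alpha - beta * evidence, sigma_log, lapse)
  if (!simulate) {
    amp <- 0.5 - lapse / 2
    return(exp(obs$mu_log + sigma_log * stats::qnorm(0.25 / amp)))
  }
  tr <- simulate_condition_trials(obs)
  fit_psychometric(tr, lapse = lapse)$threshold_arcsec
}

#' Predicted thresholds for a table of condition results
#'
#' @param results data.frame from [run_experiment()].
#' @param alpha,beta,sigma_log,lapse link/observer parameters
#'   (see [evidence_to_threshold()]).
#' @param seed RNG seed for the simulated measurements.
#' @return results with a threshold_arcsec column appended.
#' @export
predict_thresholds <- function(results, alpha = log(800), beta = 4,
                               sigma_log = 0.25, lapse = 0.02, seed = 1) {
  set.seed(seed)
  results$threshold_arcsec <- vapply(results$mean_evidence, function(e)
    evidence_to_threshold(e, alpha, beta, sigma_log, lapse), numeric(1))
  results
}
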