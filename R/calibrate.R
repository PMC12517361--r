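#' Coarse grid-search calibration of the segmentation dynamics
#'
#' The spreading speed, its activity dependence, the seed radius and
#' jitter, the transfer rate and the selection decay jointly form the
#' model's calibration vector. This helper evaluates candidate vectors
#' against the qualitative pattern suite ([pattern_assertions()]) of the
#' selected experiments and reports the number of passing assertions per
#' candidate; the shipped defaults in [model_params()] are the smallest
#' grid point that passes the full suite.
#'
#' @param grid data.frame whose columns are [model_params()] argument
#'   names; one row per candidate.
#' @param experiments experiments to evaluate (default 1:4).
#' @param n_trials Monte-Carlo trials per condition during calibration
#'   (small by design; the final check uses the full trial count).
#' @param seed RNG seed.
#' @return `grid` with columns n_pass and n_assert appended, ordered as
#'   given.
#' @export
calibrate_model <- function(grid, experiments = 1:4, n_trials = 20,
                            seed = 1) {
  stopifnot(is.data.frame(grid), nrow(grid) >= 1)
  n_pass <- n_assert <- integer(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    par <- do.call(model_params, as.list(grid[i, , drop = FALSE]))
    res <- do.call(rbind, lapply(experiments, function(e)
      run_experiment(e, n_trials, seed + 1000 * e, par)))
    rep <- do.call(rbind, lapply(experiments, function(e)
      check_patterns(res, pattern_assertions(e))))
    n_pass[i] <- sum(rep$pass)
    n_assert[i] <- nrow(rep)
  }
  grid$n_pass <- n_pass
  grid$n_assert <- n_assert
  grid
}
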