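#' Condition inventory of an experiment
#'
#' @param experiment integer 1-4.
#' @return list of condition descriptors (as taken by [build_sequence()]),
#'   named by condition label.
#' @export
experiment_conditions <- function(experiment) {
  conds <- switch(as.character(experiment),
    "1" = {
      c(lapply(c("Lines", "Rectangles", "Cubes"), function(f)
          list(flanker = f, duration_ms = 20)),
        lapply(c("Lines", "Rectangles", "Cubes"), function(f)
          list(flanker = f, duration_ms = 160)),
        list(list(flanker = "unflanked", duration_ms = 20)))
    },
    "2" = {
      unlist(lapply(c("Cubes", "Lines"), function(f)
        lapply(c("baseline", "preview", "postview"), function(d)
          list(flanker = f, design = d))), recursive = FALSE)
    },
    "3" = {
      c(list(list(design = "baseline")),
        lapply(c(20, 120, 260, 600, 1000, 1500, 2000), function(i)
          list(isi_ms = i)))
    },
    "4" = {
      c(list(list(design = "baseline")),
        lapply(c("Cubes", "Rectangles", "Triangles", "CentralRectangle",
                 "ScrambledCubes", "Lines"), function(f)
          list(intermediate = f)))
    },
    stop("experiment must be 1, 2, 3 or 4")
  )
  names(conds) <- vapply(conds, function(cd)
    build_sequence(experiment, cd, seed = 1L)$label, character(1))
  conds
}

#' Run Monte-Carlo model trials for one condition
#'
#' Trial-to-trial variability comes solely from the Gaussian jitter on the
#' selection-signal placement and (for ScrambledCubes) the per-trial
#' shuffle; there is no neural noise.
#'
#' @param experiment experiment id (1-4).
#' @param condition condition descriptor (see [build_sequence()]).
#' @param n_trials number of trials (>= 1).
#' @param seed integer seed; results are reproducible given the seed.
#' @param params model params.
#' @param rg raster geometry.
#' @param geom geometry spec.
#' @return one-row data.frame: experiment, condition, n_trials,
#'   mean_evidence, sd_evidence, seed.
#' @export
run_condition <- function(experiment, condition, n_trials = 100,
                          seed = 1, params = model_params(),
                          rg = raster_geometry(), geom = geometry_spec()) {
  stopifnot(n_trials >= 1)
  set.seed(seed)
  templates <- build_templates(params, rg, geom)
  ev <- numeric(n_trials)
  for (i in seq_len(n_trials)) {
    scr_seed <- sample.int(.Machine$integer.max, 1)
    sq <- build_sequence(experiment, condition,
                         offset_arcsec = params$ref_offset_arcmin * 60,
                         seed = scr_seed, geom = geom)
    tr <- run_trial(sq, params, rg, geom, templates = templates)
    ev[i] <- attr(tr, "evidence")
  }
  data.frame(experiment = experiment,
             condition = build_sequence(experiment, condition, seed = 1L)$label,
             n_trials = n_trials,
             mean_evidence = mean(ev),
             sd_evidence = stats::sd(ev),
             seed = seed,
             stringsAsFactors = FALSE)
}

#' Run every condition of an experiment
#'
#' @inheritParams run_condition
#' @return data.frame with one row per condition (see [run_condition()]).
#' @export
run_experiment <- function(experiment, n_trials = 100, seed = 1,
                           params = model_params(), rg = raster_geometry(),
                           geom = geometry_spec()) {
  conds <- experiment_conditions(experiment)
  out <- lapply(seq_along(conds), function(i)
    run_condition(experiment, conds[[i]], n_trials, seed + i - 1,
                  params, rg, geom))
  do.call(rbind, out)
}

#' Qualitative pattern assertions for the model-evidence panels
#'
#' Machine-readable form of the qualitative model predictions: which
#' condition means must exceed which (uncrowding), which must be
#' indistinguishable (no effect), and the one bound (the central rectangle
#' predicted at or below the intermediate Lines).
#'
#' @param experiment experiment id (1-4).
#' @return data.frame: lhs, rhs, relation (greater / approx_equal /
#'   not_greater), tolerance (in pooled-SE units).
#' @export
pattern_assertions <- function(experiment) {
  A <- function(lhs, rhs, relation, tolerance)
    data.frame(lhs = lhs, rhs = rhs, relation = relation,
               tolerance = tolerance, stringsAsFactors = FALSE)
  switch(as.character(experiment),
    "1" = rbind(
      A("unflanked-20", "Lines-20", "greater", 3),
      A("unflanked-20", "Rectangles-20", "greater", 3),
      A("unflanked-20", "Cubes-20", "greater", 3),
      A("Cubes-160", "Cubes-20", "greater", 3),
      A("Rectangles-160", "Rectangles-20", "greater", 3),
      A("Lines-160", "Lines-20", "approx_equal", 2),
      A("Cubes-160", "Rectangles-160", "approx_equal", 2)),
    "2" = rbind(
      A("Cubes-preview", "Cubes-baseline", "greater", 3),
      A("Lines-preview", "Lines-baseline", "approx_equal", 2),
      A("Cubes-postview", "Cubes-baseline", "approx_equal", 2),
      A("Lines-postview", "Lines-baseline", "approx_equal", 2)),
    "3" = rbind(
      A("Cubes-isi20", "Cubes-baseline", "greater", 3),
      A("Cubes-isi120", "Cubes-baseline", "greater", 3),
      A("Cubes-isi260", "Cubes-baseline", "approx_equal", 2),
      A("Cubes-isi600", "Cubes-baseline", "approx_equal", 2),
      A("Cubes-isi1000", "Cubes-baseline", "approx_equal", 2),
      A("Cubes-isi1500", "Cubes-baseline", "approx_equal", 2),
      A("Cubes-isi2000", "Cubes-baseline", "approx_equal", 2)),
    "4" = rbind(
      A("intermediate-Cubes", "Cubes-baseline", "greater", 3),
      A("intermediate-Rectangles", "Cubes-baseline", "greater", 3),
      A("intermediate-Triangles", "Cubes-baseline", "greater", 3),
      A("intermediate-Lines", "Cubes-baseline", "approx_equal", 2),
      A("intermediate-ScrambledCubes", "Cubes-baseline", "approx_equal", 2),
      A("intermediate-CentralRectangle", "intermediate-Lines", "not_greater", 2)),
    stop("experiment must be 1, 2, 3 or 4")
  )
}

#' Run the full qualitative pattern suite
#'
#' Runs every condition of the requested experiments and evaluates all
#' pattern assertions.
#'
#' @param experiments experiments to include.
#' @param n_trials Monte-Carlo trials per condition.
#' @param seed master seed (per-experiment seeds are derived from it).
#' @param params model params.
#' @return list with `results` (condition table) and `report` (assertion
#'   table with z and pass columns).
#' @export
run_pattern_suite <- function(experiments = 1:4, n_trials = 100, seed = 1,
                              params = model_params()) {
  results <- do.call(rbind, lapply(experiments, function(e)
    run_experiment(e, n_trials, seed + 1000 * e, params)))
  report <- do.call(rbind, lapply(experiments, function(e)
    cbind(experiment = e, check_patterns(results, pattern_assertions(e)))))
  list(results = results, report = report)
}

#' Evaluate pattern assertions against condition results
#'
#' Each assertion is scored as z = (mean_lhs - mean_rhs) / pooled SE.
#' `greater` passes when z >= tolerance, `approx_equal` when |z| <
#' tolerance, `not_greater` when z <= tolerance. A zero pooled SE with a
#' zero mean difference scores z = 0.
#'
#' @param results data.frame from [run_experiment()] (or rbind of several).
#' @param assertions data.frame from [pattern_assertions()].
#' @return the assertions with columns z and pass added.
#' @export
check_patterns <- function(results, assertions) {
  need <- unique(c(assertions$lhs, assertions$rhs))
  missing <- setdiff(need, results$condition)
  if (length(missing))
    stop("results are missing condition(s): ", paste(missing, collapse = ", "))
  z <- numeric(nrow(assertions))
  for (i in seq_len(nrow(assertions))) {
    a <- results[match(assertions$lhs[i], results$condition), ]
    b <- results[match(assertions$rhs[i], results$condition), ]
    d <- a$mean_evidence - b$mean_evidence
    se <- sqrt(a$sd_evidence^2 / a$n_trials + b$sd_evidence^2 / b$n_trials)
    z[i] <- if (se == 0) { if (d == 0) 0 else sign(d) * Inf } else d / se
  }
  assertions$z <- z
  assertions$pass <- ifelse(assertions$relation == "greater",
                            z >= assertions$tolerance,
                     ifelse(assertions$relation == "approx_equal",
                            abs(z) < assertions$tolerance,
                            z <= assertions$tolerance))
  assertions
}
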