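#' Default run configuration
#'
#' A fully serializable description of a pipeline run: geometry overrides,
#' model parameters, experiment selection, trial counts and seeds. Given
#' equal configs and seeds, all CSV outputs are byte-identical.
#'
#' @param geometry named list of [geometry_spec()] overrides.
#' @param params named list of [model_params()] overrides.
#' @param experiments experiments to run.
#' @param n_trials Monte-Carlo trials per condition.
#' @param seed master seed.
#' @param out_dir output directory.
#' @return `run_config` list.
#' @export
run_config <- function(geometry = list(), params = list(),
                       experiments = 1:4, n_trials = 100, seed = 1,
                       out_dir = "uncrowdr-out") {
  if ("evidence_offset_const" %in% names(params))
    stop("evidence_offset_const is a fixed constant and cannot be overridden")
  structure(list(geometry = geometry, params = params,
                 experiments = experiments, n_trials = n_trials,
                 seed = seed, out_dir = out_dir),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Absent keys take their defaults; unknown keys are rejected (a silent
#' typo in a calibration key would otherwise go unnoticed).
#'
#' @param path YAML file path (an empty file yields all defaults).
#' @return `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(run_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  if (!is.null(raw$params)) {
    badp <- setdiff(names(raw$params),
                    setdiff(names(formals(model_params)), "..."))
    if ("evidence_offset_const" %in% names(raw$params))
      stop("evidence_offset_const is a fixed constant and cannot be overridden")
    if (length(badp)) stop("unknown params key(s): ", paste(badp, collapse = ", "))
  }
  if (!is.null(raw$geometry)) {
    badg <- setdiff(names(raw$geometry), names(unclass(geometry_spec())))
    if (length(badg)) stop("unknown geometry key(s): ",
                           paste(badg, collapse = ", "))
  }
  do.call(run_config, raw)
}

#' Save a run configuration to YAML
#' @param config run_config.
#' @param path output path.
#' @return invisibly, path.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# Materialize geometry_spec / model_params from a config
config_geometry <- function(config) do.call(geometry_spec, config$geometry)
config_params <- function(config) do.call(model_params, config$params)

#' Command-line entry point
#'
#' Thin dispatcher used by the `inst/cli/uncrowd.R` script. Subcommands:
#' \describe{
#'   \item{render}{write one PNG and one segment CSV per flanker
#'     configuration.}
#'   \item{run}{run the Monte-Carlo model for the configured experiments
#'     and write a results CSV.}
#'   \item{patterns}{run the experiments and write the pattern report CSV.}
#'   \item{thresholds}{append predicted thresholds to the results.}
#' }
#'
#' @param argv character vector of arguments
#'   (`subcommand --config FILE --out DIR [--experiment N] [--trials T]
#'   [--seed S]`).
#' @return integer exit code (0 on success).
#' @export
uncrowd_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: uncrowd <render|run|patterns|thresholds> [--config FILE]",
    "[--out DIR] [--experiment N|all] [--trials T] [--seed S]")
  if (length(argv) < 1) { message(usage); return(1L) }
  cmd <- argv[1]
  opt <- function(name, default) {
    i <- which(argv == paste0("--", name))
    if (length(i) == 1 && i < length(argv)) argv[i + 1] else default
  }
  if (!cmd %in% c("render", "run", "patterns", "thresholds")) {
    message("unknown subcommand: ", cmd, "\n", usage)
    return(1L)
  }
  cfg <- if (!is.null(p <- opt("config", NULL))) load_config(p) else run_config()
  cfg$out_dir <- opt("out", cfg$out_dir)
  cfg$n_trials <- as.integer(opt("trials", cfg$n_trials))
  cfg$seed <- as.integer(opt("seed", cfg$seed))
  exp_arg <- opt("experiment", "all")
  cfg$experiments <- if (identical(exp_arg, "all")) cfg$experiments
                     else as.integer(exp_arg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  geom <- config_geometry(cfg); par <- config_params(cfg)
  log_lines <- c(paste("seed:", cfg$seed), paste("trials:", cfg$n_trials),
                 paste("R:", R.version.string))
  if (cmd == "render") {
    rg <- raster_geometry()
    cfgs <- c("Lines", "Rectangles", "Cubes", "Triangles",
              "CentralRectangle", "ScrambledCubes")
    for (cf in cfgs) {
      f <- make_frame(cf, 0, seed = cfg$seed, geom = geom, with_vernier = TRUE)
      write_raster_png(rasterize(f, rg),
                       file.path(cfg$out_dir, paste0(cf, ".png")))
      write_segment_csv(list(f), file.path(cfg$out_dir, paste0(cf, ".csv")))
    }
  } else {
    set.seed(cfg$seed)
    res <- do.call(rbind, lapply(cfg$experiments, function(e)
      run_experiment(e, cfg$n_trials, cfg$seed + 1000 * e, par,
                     geom = geom)))
    utils::write.csv(res, file.path(cfg$out_dir, "results.csv"),
                     row.names = FALSE)
    if (cmd == "patterns") {
      rep <- do.call(rbind, lapply(cfg$experiments, function(e)
        check_patterns(res, pattern_assertions(e))))
      utils::write.csv(rep, file.path(cfg$out_dir, "patterns.csv"),
                       row.names = FALSE)
    } else if (cmd == "thresholds") {
      thr <- predict_thresholds(res, seed = cfg$seed)
      utils::write.csv(thr, file.path(cfg$out_dir, "thresholds.csv"),
                       row.names = FALSE)
    }
  }
  writeLines(log_lines, file.path(cfg$out_dir, "run.log"))
  0L
}
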