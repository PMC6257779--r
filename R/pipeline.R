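#' Run the full analysis pipeline from a configuration
#'
#' End-to-end composition of the package's stages: obtain a series (simulate
#' one with a known ground truth, or load one from file), run the
#' time-point-deletion experiment, compute the statistics table, compare
#' every network with the reference, and aggregate edge overlap. All outputs
#' are written as diffable text files; two runs with the same configuration
#' are byte-identical.
#'
#' @param config a named list, or the path of a YAML file holding one.
#'   Recognised fields (defaults in parentheses):
#'   \describe{
#'     \item{seed}{integer driving all randomness (1).}
#'     \item{alpha1, alpha2}{inference thresholds (0.5, 0.05).}
#'     \item{allow_self}{allow self-regulation (FALSE).}
#'     \item{estimator}{only `"ols"` is available.}
#'     \item{series}{path of a series TSV/CSV to load; when absent, a series
#'       is simulated.}
#'     \item{simulate}{list with `p` (30), `expected_edges`
#'       (`round(0.56 * p)`), `noise_sd` (0.5), `coeff_range` (c(0.5, 1)),
#'       `timepoints` (the 11-point diurnal design).}
#'     \item{design}{`"standard"` (the only design).}
#'     \item{pairs}{list of 2-vectors of time indices deleted together
#'       (none).}
#'     \item{outdir}{output directory, created if needed (required).}
#'   }
#' @return Invisibly, a list with `experiment`, `comparison`, `overlap`,
#'   `series` and (for simulated input) `truth`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("`config` must be a list or a YAML path",
                             call. = FALSE)
  cfg <- resolve_config(config)

  log <- character()
  say <- function(...) {
    line <- sprintf(...)
    message(line)
    log <<- c(log, line)
  }

  if (!dir.exists(cfg$outdir)) dir.create(cfg$outdir, recursive = TRUE)

  truth <- NULL
  if (!is.null(cfg$series)) {
    series <- read_series(cfg$series)
    say("loaded series %s: %d genes x %d time points", cfg$series,
        nrow(series$values), ncol(series$values))
  } else {
    sim <- cfg$simulate
    truth <- generate_ground_truth(p = sim$p,
                                   expected_edges = sim$expected_edges,
                                   coeff_range = sim$coeff_range,
                                   noise_sd = sim$noise_sd,
                                   seed = cfg$seed)
    series <- simulate_expression(truth, time_labels_h = sim$timepoints,
                                  seed = cfg$seed + 1L)
    write_series(series, file.path(cfg$outdir, "series.tsv"))
    write_truth(truth, file.path(cfg$outdir, "truth.tsv"))
    say("simulated series: %d genes x %d time points, %d true regulations",
        sim$p, length(sim$timepoints), sum(truth$coefficients != 0))
  }

  design <- standard_design(length(series$time_labels_h), pairs = cfg$pairs)
  result <- run_experiment(series, design, alpha1 = cfg$alpha1,
                           alpha2 = cfg$alpha2, allow_self = cfg$allow_self)
  say("experiment: %d entries fitted, %d failed",
      sum(!vapply(result$networks, is.null, logical(1))),
      length(result$failed))

  for (lab in names(result$networks)) {
    if (!is.null(result$networks[[lab]])) {
      write_edges(result$networks[[lab]],
                  file.path(cfg$outdir, paste0(lab, ".tsv")))
    }
  }
  utils::write.csv(result$stats_table,
                   file.path(cfg$outdir, "stats_table.csv"),
                   row.names = FALSE)

  cmp <- compare_collection(result, include_self = cfg$allow_self)
  utils::write.csv(cmp, file.path(cfg$outdir, "comparison.csv"),
                   row.names = FALSE)
  say("comparison: mean F-measure %.4f over %d networks",
      mean(cmp$f_measure[cmp$label != design$reference_label]),
      nrow(cmp) - 1)

  fitted <- Filter(Negate(is.null), result$networks)
  ov <- edge_overlap(fitted)
  utils::write.csv(ov$aggregate, file.path(cfg$outdir, "overlap.csv"),
                   row.names = FALSE)
  say("overlap: %d distinct edges across %d networks",
      nrow(ov$edges), length(fitted))

  cfg$version <- as.character(utils::packageVersion("lagnet"))
  yaml::write_yaml(cfg, file.path(cfg$outdir, "config.yaml"))
  writeLines(log, file.path(cfg$outdir, "log.txt"))

  invisible(list(experiment = result, comparison = cmp, overlap = ov,
                 series = series, truth = truth))
}

resolve_config <- function(config) {
  bad <- setdiff(names(config),
                 c("seed", "alpha1", "alpha2", "allow_self", "estimator",
                   "series", "simulate", "design", "pairs", "outdir"))
  if (length(bad)) stop("unknown config field(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  cfg <- list(
    seed = as.integer(config$seed %||% 1L),
    alpha1 = check_alpha(config$alpha1 %||% 0.5, "alpha1"),
    alpha2 = check_alpha(config$alpha2 %||% 0.05, "alpha2"),
    allow_self = isTRUE(config$allow_self),
    estimator = config$estimator %||% "ols",
    series = config$series,
    design = config$design %||% "standard",
    pairs = config$pairs,
    outdir = config$outdir)
  if (!identical(cfg$estimator, "ols")) {
    stop("only `estimator: ols` is available", call. = FALSE)
  }
  if (!identical(cfg$design, "standard")) {
    stop("only `design: standard` is available", call. = FALSE)
  }
  if (is.null(cfg$outdir)) stop("config needs an `outdir`", call. = FALSE)
  if (is.null(cfg$series)) {
    sim <- config$simulate %||% list()
    sim$p <- as.integer(sim$p %||% 30L)
    sim$expected_edges <- as.integer(sim$expected_edges %||%
                                       max(1L, round(0.56 * sim$p)))
    sim$noise_sd <- as.numeric(sim$noise_sd %||% 0.5)
    sim$coeff_range <- as.numeric(sim$coeff_range %||% c(0.5, 1.0))
    sim$timepoints <- as.numeric(sim$timepoints %||% default_timepoints())
    cfg$simulate <- sim
  }
  if (!is.null(cfg$pairs)) cfg$pairs <- lapply(cfg$pairs, as.integer)
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a
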