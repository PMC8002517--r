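#' Self-relative evaluation of an EEG identification pipeline
#'
#' The central fitting routine. For every cell of the (filter order,
#' frequency sub-band) grid it builds the identity-information distribution
#' (the labeled Burg AR feature space), carries the openness condition over
#' it (gradual enrollment with repetitive batch learning and cross-validated
#' per-step accuracy, averaged over the simulated label sequences), and
#' derives the self-relative degradation metrics. The returned object
#' identifies the configuration carrying the most robust identity
#' information (maximum last-step decision-making metric).
#'
#' @param cohort A [generate_cohort()] result or list of [eeg_recording()]
#'   objects with subject labels `1..E`.
#' @param config A [pipeline_config()] supplying every non-swept parameter.
#' @param sweep A [sweep_spec()]; defaults to the single cell of `config`.
#' @param openness An [openness_config()] (its `n_subjects` must match the
#'   cohort) or a list of arguments for one, `n_subjects` filled in from the
#'   cohort.
#' @param seed Master seed for the enrollment simulation and all fold
#'   shuffles.
#' @param verbose Print one progress line per grid cell.
#' @param keep_features Keep the per-cell feature spaces in the returned
#'   object (memory permitting).
#' @return An object of class `selfrel`: list with `report`
#'   (a [grid_report()] result), `accuracy` (per-cell [run_openness()]
#'   results), `simulation`, `configs`, `seed`, `call`.
#' @seealso [print.selfrel()], [summary.selfrel()], [plot.selfrel()]
#' @export
#' @examples
#' \donttest{
#' cohort <- generate_cohort(synthetic_cohort_spec(
#'   n_subjects = 8, n_channels = 4, duration = 20, identity_band = c(30, 50),
#'   seed = 1))
#' cfg <- pipeline_config(channel_set = cohort$recordings[[1]]$channel_labels,
#'                        duration = 20, ar_order = 6)
#' fit <- self_relative_eval(cohort, cfg,
#'   sweep = sweep_spec(orders = 2, bands = list(c(8, 13), c(30, 50))),
#'   openness = list(t1 = 2, tr = 6, steps = 3, sequences = 2), seed = 1)
#' fit
#' }
self_relative_eval <- function(cohort, config, sweep = NULL, openness,
                               seed = 1L, verbose = FALSE,
                               keep_features = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  recs <- if (inherits(cohort, "synthetic_cohort")) cohort$recordings else cohort
  E <- length(recs)
  if (is.null(sweep))
    sweep <- sweep_spec(orders = config$filter_order, bands = list(config$band))
  if (!inherits(openness, "openness_config")) {
    openness$n_subjects <- openness$n_subjects %||% E
    openness$seed <- openness$seed %||% sub_seed(seed, 1L)
    openness <- do.call(openness_config, openness)
  }
  configs <- expand_sweep(config, sweep)
  sim <- simulate_openness(openness)
  results <- list()
  spaces <- if (keep_features) list() else NULL
  for (k in seq_along(configs)) {
    id <- names(configs)[k]
    if (verbose) message(sprintf("[%d/%d] %s", k, length(configs), id))
    space <- build_feature_space(cohort, configs[[k]])
    if (keep_features) spaces[[id]] <- space
    results[[id]] <- run_openness(space, sim, seed = sub_seed(seed, 100L + k))
  }
  structure(list(report = grid_report(results, configs),
                 accuracy = results,
                 simulation = sim,
                 configs = configs,
                 features = spaces,
                 seed = as.integer(seed),
                 call = match.call()),
            class = "selfrel")
}

#' @export
print.selfrel <- function(x, ...) {
  cat("Self-relative evaluation\n")
  cat(sprintf("  grid: %d configuration(s); openness %d -> %d subjects over %d steps, %d sequence(s)\n",
              length(x$configs), x$simulation$config$t1, x$simulation$config$tr,
              x$simulation$config$steps, x$simulation$config$sequences))
  if (!is.null(x$report$best)) {
    b <- x$report$best
    cat(sprintf("  best configuration: order %d, band [%g, %g] Hz (DMM = %.3g, GRL = %.3g%%)\n",
                b$filter_order, b$band_low, b$band_high, b$dmm_last, b$grl))
  } else {
    cat("  best configuration: undefined (no configuration degrades)\n")
  }
  invisible(x)
}

#' Summarize a self-relative evaluation
#'
#' Prints the per-cell metric table and the marginal GRL tables with their
#' power ratios, and returns the report invisibly.
#'
#' @param object A [self_relative_eval()] result.
#' @param digits Rounding for display.
#' @param ... Unused.
#' @return The `selfrel_report`, invisibly.
#' @export
summary.selfrel <- function(object, digits = 3, ...) {
  print(object)
  cat("\nPer-configuration metrics:\n")
  cells <- object$report$cells
  num <- vapply(cells, is.numeric, logical(1))
  cells[num] <- lapply(cells[num], round, digits = digits)
  print(cells, row.names = FALSE)
  cat("\n")
  print(object$report, digits = digits)
  invisible(object$report)
}

#' Plot mean openness-accuracy curves
#'
#' One curve per configuration: mean identification accuracy against the
#' number of enrolled subjects. The configuration with maximal last-step
#' DMM is drawn with a heavier line.
#'
#' @param x A [self_relative_eval()] result.
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.selfrel <- function(x, ...) {
  oam <- sapply(x$accuracy, function(a) a$mean)
  sizes <- x$simulation$sizes
  best_id <- if (is.null(x$report$best)) NA_character_ else x$report$best$config_id
  lwd <- ifelse(colnames(oam) == best_id, 3, 1)
  cols <- grDevices::hcl.colors(ncol(oam), "Dark 3")
  graphics::matplot(sizes, oam, type = "b", pch = 16, lty = 1, lwd = lwd,
                    col = cols, xlab = "Enrolled subjects",
                    ylab = "Mean identification accuracy", ...)
  graphics::legend("bottomleft", legend = colnames(oam), col = cols,
                   lwd = lwd, cex = 0.7, bty = "n")
  invisible(x)
}

#' Run a full evaluation from a configuration file
#'
#' End-to-end orchestration: loads a run configuration ([load_run_config()]),
#' obtains the cohort (from the `input` block: a synthetic cohort spec or a
#' directory of EDF files), runs [self_relative_eval()] over the sweep, and
#' persists every intermediate (per-cell feature CSVs, the openness
#' simulation JSON, per-cell accuracy CSVs, the metric report and a run
#' manifest) so any stage can be replayed bit-exactly.
#'
#' @param config_path Path to the run configuration YAML.
#' @param out_dir Output directory (created if needed).
#' @param verbose Print progress.
#' @return The run manifest (named list), invisibly; written as
#'   `manifest.json`.
#' @export
run_all <- function(config_path, out_dir, verbose = FALSE) {
  rc <- load_run_config(config_path)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(rc$input))
    stop("run config has no 'input' block (synthetic spec or edf_dir)", call. = FALSE)
  cohort <- if (!is.null(rc$input$synthetic)) {
    sy <- rc$input$synthetic
    generate_cohort(synthetic_cohort_spec(
      n_subjects = sy$n_subjects,
      n_channels = sy$n_channels %||% length(rc$pipeline$channel_set),
      sampling_rate = sy$sampling_rate_hz %||% rc$pipeline$sampling_rate,
      duration = sy$duration_s %||% rc$pipeline$duration,
      identity_band = unlist(sy$identity_band) %||% c(30, 50),
      separability = sy$separability %||% 1,
      noise_sd = sy$noise_sd %||% 1,
      generator_ar_order = sy$generator_ar_order %||% 2L,
      seed = sub_seed(rc$seed, 7L)))
  } else {
    read_cohort_edf(rc$input$edf_dir)
  }
  # channel set must match the cohort; synthetic channels are Ch01..ChH
  recs <- if (inherits(cohort, "synthetic_cohort")) cohort$recordings else cohort
  if (!all(rc$pipeline$channel_set %in% recs[[1]]$channel_labels)) {
    pl <- rc$pipeline
    pl$channel_set <- recs[[1]]$channel_labels
    rc$pipeline <- do.call(pipeline_config, pl[setdiff(names(pl), character(0))])
  }
  op <- rc$openness
  openness <- openness_config(t1 = op$t1, tr = op$tr, steps = op$steps,
                              n_subjects = length(recs),
                              step_trials = op$step_trials,
                              step_prob = op$step_prob,
                              sequences = op$sequences,
                              seed = sub_seed(rc$seed, 1L))
  fit <- self_relative_eval(cohort, rc$pipeline, rc$sweep, openness,
                            seed = rc$seed, verbose = verbose,
                            keep_features = TRUE)
  # persist intermediates
  feat_dir <- file.path(out_dir, "features")
  acc_dir <- file.path(out_dir, "accuracy")
  dir.create(feat_dir, showWarnings = FALSE)
  dir.create(acc_dir, showWarnings = FALSE)
  for (id in names(fit$configs)) {
    write_feature_space(fit$features[[id]], file.path(feat_dir, paste0(id, ".csv")))
    write_openness_accuracy(fit$accuracy[[id]], file.path(acc_dir, paste0(id, ".csv")))
  }
  write_openness(fit$simulation, file.path(out_dir, "openness.json"))
  write_report(fit$report, file.path(out_dir, "report"))
  write_run_config(rc, file.path(out_dir, "config.yaml"))
  manifest <- list(
    tool = "selfrelEEG",
    version = as.character(utils::packageVersion("selfrelEEG")),
    seed = rc$seed,
    config = file.path(out_dir, "config.yaml"),
    openness = file.path(out_dir, "openness.json"),
    features = file.path(feat_dir, paste0(names(fit$configs), ".csv")),
    accuracy = file.path(acc_dir, paste0(names(fit$configs), ".csv")),
    report = file.path(out_dir, "report"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Rebuild a metric report from persisted accuracies
#'
#' Metric-only rerun: reads the per-cell accuracy CSVs and the run
#' configuration persisted by [run_all()] and recomputes the self-relative
#' report without touching the signals.
#'
#' @param results_dir A [run_all()] output directory.
#' @return A [grid_report()] result.
#' @export
report_from_results <- function(results_dir) {
  cfg_path <- file.path(results_dir, "config.yaml")
  if (!file.exists(cfg_path))
    stop("no config.yaml in ", results_dir, call. = FALSE)
  rc <- load_run_config(cfg_path)
  configs <- expand_sweep(rc$pipeline, rc$sweep)
  acc_dir <- file.path(results_dir, "accuracy")
  results <- lapply(names(configs), function(id) {
    path <- file.path(acc_dir, paste0(id, ".csv"))
    if (!file.exists(path)) stop("missing accuracy file: ", path, call. = FALSE)
    read_openness_accuracy(path)
  })
  names(results) <- names(configs)
  grid_report(results, configs)
}
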