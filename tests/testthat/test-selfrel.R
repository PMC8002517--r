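fit_small <- function(seed = 1) {
  cohort <- small_cohort(n_subjects = 8, n_channels = 3, duration = 15)
  cfg <- small_config(n_channels = 3, duration = 15)
  self_relative_eval(cohort, cfg,
                     sweep = sweep_spec(orders = 4,
                                        bands = list(c(8, 13), c(30, 50))),
                     openness = list(t1 = 2, tr = 6, steps = 3,
                                     step_trials = 100, step_prob = 0.02,
                                     sequences = 2),
                     seed = seed)
}

test_that("self_relative_eval returns a classed fit covering the grid", {
  fit <- fit_small()
  expect_s3_class(fit, "selfrel")
  expect_identical(names(fit$configs), c("o4_b8-13", "o4_b30-50"))
  expect_identical(names(fit$accuracy), names(fit$configs))
  expect_identical(dim(fit$accuracy[[1]]$per_sequence), c(2L, 3L))
  expect_identical(nrow(fit$report$cells), 2L)
  expect_s3_class(fit$simulation, "openness_sim")
  # refitting with the same seed reproduces every number
  fit2 <- fit_small()
  expect_identical(fit2$accuracy[[2]]$per_sequence, fit$accuracy[[2]]$per_sequence)
  expect_equal(fit2$report$cells, fit$report$cells, tolerance = 1e-12)
})

test_that("print, summary and plot methods work on a fit", {
  fit <- fit_small()
  expect_output(print(fit), "grid: 2 configuration")
  expect_output(out <- summary(fit), "Per-configuration metrics")
  expect_s3_class(out, "selfrel_report")
  pdf(NULL)
  on.exit(dev.off())
  expect_invisible(plot(fit))
})

test_that("run_all persists a replayable artifact tree", {
  cfg_path <- tempfile(fileext = ".yaml")
  writeLines(c(
    "seed: 11",
    "pipeline:",
    "  channels: [Ch01, Ch02, Ch03]",
    "  duration_s: 15",
    "  ar_order: 2",
    "sweep:",
    "  orders: [4]",
    "  bands: [[8, 13], [30, 50]]",
    "openness:",
    "  t1: 2",
    "  tr: 6",
    "  steps: 3",
    "  step_trials: 100",
    "  step_prob: 0.02",
    "  sequences: 2",
    "input:",
    "  synthetic:",
    "    n_subjects: 8",
    "    n_channels: 3",
    "    duration_s: 15"), cfg_path)
  out1 <- tempfile("run1")
  manifest <- run_all(cfg_path, out1)
  expect_identical(manifest$seed, 11L)
  expect_true(all(file.exists(file.path(out1, c(
    "config.yaml", "openness.json", "manifest.json",
    "features/o4_b8-13.csv", "features/o4_b30-50.csv",
    "accuracy/o4_b8-13.csv", "accuracy/o4_b30-50.csv",
    "report/cells.csv", "report/summary.json")))))
  # idempotence: the same config and seed give byte-identical reports
  out2 <- tempfile("run2")
  run_all(cfg_path, out2)
  expect_identical(readLines(file.path(out1, "report", "cells.csv")),
                   readLines(file.path(out2, "report", "cells.csv")))
  expect_identical(readLines(file.path(out1, "accuracy", "o4_b30-50.csv")),
                   readLines(file.path(out2, "accuracy", "o4_b30-50.csv")))
  # every report number is recomputable from the persisted intermediates
  rep <- report_from_results(out1)
  direct <- utils::read.csv(file.path(out1, "report", "cells.csv"))
  expect_equal(rep$cells$grl, direct$grl, tolerance = 1e-12)
  expect_equal(rep$cells$dmm_last, direct$dmm_last, tolerance = 1e-12)
})

test_that("run_all and report_from_results fail cleanly on bad inputs", {
  cfg_path <- tempfile(fileext = ".yaml")
  writeLines(c(
    "seed: 1",
    "pipeline: {duration_s: 15}",
    "sweep: {orders: [2], bands: [[8, 13]]}",
    "openness: {t1: 2, tr: 6, steps: 3}",
    "input: {edf_dir: /nonexistent/path}"), cfg_path)
  expect_error(run_all(cfg_path, tempfile()), "not found")
  writeLines(c(
    "seed: 1",
    "pipeline: {duration_s: 15}",
    "sweep: {orders: [2], bands: [[8, 13]]}",
    "openness: {t1: 2, tr: 6, steps: 3}"), cfg_path)
  expect_error(run_all(cfg_path, tempfile()), "input")
  expect_error(report_from_results(tempfile()), "config.yaml")
})

test_that("the command-line front end is shipped and wired to the package", {
  cli <- system.file("cli", "selfrelEEG", package = "selfrelEEG")
  expect_true(nzchar(cli))
  lines <- readLines(cli)
  expect_true(any(grepl("run-all", lines)))
  expect_true(any(grepl("library\\(selfrelEEG\\)", lines)))
})
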