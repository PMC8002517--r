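test_that("LRL matches hand-worked examples with a moving reference", {
  # transitions: (1.0 - 0.9)/1.0 = 0.1 and (0.9 - 0.9)/0.9 = 0 -> mean 5%
  expect_equal(lrl(c(1.0, 0.9, 0.9)), 5)
  # monotone: (0.96-0.90)/0.96, (0.90-0.80)/0.90 -> mean * 100
  expect_equal(lrl(c(0.96, 0.90, 0.80)),
               100 * mean(c(0.06 / 0.96, 0.10 / 0.90)))
  expect_equal(lrl(c(0.5, 0.6, 0.7)), 0)  # never degrades
  # improving steps clamp to 0 but still count in the denominator
  expect_equal(lrl(c(1.0, 0.5, 1.0)), 25)
  expect_equal(lrl(c(1.0, 0.5, 1.0), degrading_only = TRUE), 50)
})

test_that("GRL compares every step to the first-step reference", {
  expect_equal(grl(c(1.0, 0.9, 0.8)), 15)
  expect_equal(grl(c(0.8, 0.6, 0.6)), 100 * mean(c(0.2, 0.2) / 0.8))
  expect_equal(grl(c(0.5, 0.6, 0.7)), 0)
  expect_equal(grl(c(1.0, 1.2, 0.8) / 1.2), 100 * mean(c(0, 0.2)))
  expect_equal(grl(c(0.9, 0.95, 0.45), degrading_only = TRUE), 50)
})

test_that("relative losses reject degenerate inputs", {
  expect_error(lrl(0.9), "2 steps")
  expect_error(lrl(c(0.9, 1.1)), "0, 1")
  expect_error(lrl(c(0, 0.5, 0.4)), "zero accuracy")
  expect_error(lrl(c(0.5, 0, 0.4)), "zero accuracy")
  expect_error(grl(c(0, 0.5)), "zero accuracy")
  expect_error(grl(c(0.5, NA)), "0, 1")
})

test_that("power is the max/min ratio of marginal GRL means", {
  expect_equal(power_ratio(c(4, 2, 8)), 4)
  expect_equal(power_ratio(5), 1)
  expect_error(power_ratio(c(3, 0)), "nonpositive")
  expect_error(power_ratio(c(3, Inf)), "finite")
})

test_that("DMM divides step accuracy by percent GRL, undefined at zero", {
  expect_equal(dmm(0.9, 1.0), 0.9)
  expect_equal(dmm(0.84, 2.5), 0.336)
  expect_warning(out <- dmm(0.9, 0), "undefined")
  expect_true(is.na(out))
  expect_error(dmm(1.2, 1), "acc_n")
  expect_error(dmm(0.9, -1), "grl")
})

test_that("grid_report assembles cells, marginals and the DMM-best cell", {
  mk <- function(oam) structure(list(per_sequence = rbind(oam), mean = oam,
                                     sizes = seq_along(oam), config_id = "x"),
                                class = "openness_accuracy")
  base <- pipeline_config(duration = 15)
  configs <- expand_sweep(base, sweep_spec(orders = c(1, 2),
                                           bands = list(c(4, 8), c(30, 50))))
  results <- list(
    "o1_b4-8" = mk(c(0.9, 0.8, 0.7)),    # grl = 100*mean(1/9, 2/9)
    "o1_b30-50" = mk(c(0.9, 0.88, 0.86)),
    "o2_b4-8" = mk(c(0.8, 0.6, 0.5)),
    "o2_b30-50" = mk(c(0.95, 0.94, 0.93)))
  rep <- grid_report(results, configs)
  expect_s3_class(rep, "selfrel_report")
  expect_identical(nrow(rep$cells), 4L)
  expect_equal(rep$cells$grl[rep$cells$config_id == "o1_b4-8"],
               100 * mean(c(0.1, 0.2) / 0.9))
  # marginals: mean GRL per order over bands, per band over orders
  expect_identical(names(rep$order_marginals), c("1", "2"))
  g <- rep$cells$grl
  expect_equal(as.numeric(rep$order_marginals), c(mean(g[1:2]), mean(g[3:4])))
  expect_equal(as.numeric(rep$band_marginals), c(mean(g[c(1, 3)]), mean(g[c(2, 4)])))
  expect_equal(attr(rep$order_marginals, "power"),
               max(as.numeric(rep$order_marginals)) / min(as.numeric(rep$order_marginals)))
  # the gently degrading high-accuracy cell wins the last-step DMM
  expect_identical(rep$best$config_id, "o2_b30-50")
  expect_error(grid_report(results[1:3], configs), "o2_b30-50")
})

test_that("reports persist to CSV/JSON and print without error", {
  mk <- function(oam) structure(list(per_sequence = rbind(oam), mean = oam,
                                     sizes = seq_along(oam), config_id = "x"),
                                class = "openness_accuracy")
  base <- pipeline_config(duration = 15)
  configs <- expand_sweep(base, sweep_spec(orders = 2, bands = list(c(4, 8), c(8, 13))))
  results <- list("o2_b4-8" = mk(c(0.9, 0.7)), "o2_b8-13" = mk(c(0.9, 0.8)))
  rep <- grid_report(results, configs)
  dir <- tempfile("report")
  write_report(rep, dir)
  expect_true(all(file.exists(file.path(dir, c("cells.csv", "grl_by_order.csv",
                                               "grl_by_band.csv", "summary.json")))))
  cells <- utils::read.csv(file.path(dir, "cells.csv"))
  expect_equal(cells$grl, rep$cells$grl, tolerance = 1e-12)
  js <- jsonlite::read_json(file.path(dir, "summary.json"))
  expect_identical(js$best$config_id, rep$best$config_id)
  expect_output(print(rep), "power")
})
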