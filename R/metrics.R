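.check_oam <- function(oam) {
  if (!is.numeric(oam) || length(oam) < 2L)
    stop("need an accuracy vector with at least 2 steps", call. = FALSE)
  if (any(!is.finite(oam)) || any(oam < 0) || any(oam > 1))
    stop("accuracies must lie in [0, 1]", call. = FALSE)
  oam
}

#' Local relative loss (LRL)
#'
#' Mean relative degradation in accuracy between every two successive steps
#' of the openness condition, measured against the moving reference
#' `acc[j - 1]`, in percent. A step only counts as degradation when
#' `acc[j - 1] > acc[j]`; by default non-degrading steps contribute 0 and the
#' mean runs over all `R - 1` transitions, keeping configurations with
#' different numbers of degrading steps comparable. Set
#' `degrading_only = TRUE` to average over degrading transitions only.
#'
#' @param oam Length-R mean openness-accuracy vector, entries in `(0, 1]`.
#' @param degrading_only Average over degrading steps only (default FALSE).
#' @return Percent degradation (>= 0); 0 when the vector never degrades.
#' @export
#' @examples
#' lrl(c(1.0, 0.9, 0.9))  # 5
lrl <- function(oam, degrading_only = FALSE) {
  oam <- .check_oam(oam)
  R <- length(oam)
  prev <- oam[-R]
  if (any(prev == 0))
    stop("zero accuracy at a reference step: relative loss undefined", call. = FALSE)
  terms <- pmax(0, (prev - oam[-1]) / prev)
  if (degrading_only) {
    if (!any(terms > 0)) return(0)
    terms <- terms[terms > 0]
  }
  100 * mean(terms)
}

#' Global relative loss (GRL)
#'
#' Mean relative degradation in accuracy of each step versus the first step
#' of the openness condition (fixed reference), in percent. As for [lrl()],
#' only steps with `acc[1] > acc[j]` count as degradation; the clamped mean
#' over all `R - 1` steps is the default.
#'
#' @inheritParams lrl
#' @return Percent degradation (>= 0).
#' @export
#' @examples
#' grl(c(1.0, 0.9, 0.8))  # 15
grl <- function(oam, degrading_only = FALSE) {
  oam <- .check_oam(oam)
  if (oam[1] == 0)
    stop("zero accuracy at the first step: relative loss undefined", call. = FALSE)
  terms <- pmax(0, (oam[1] - oam[-1]) / oam[1])
  if (degrading_only) {
    if (!any(terms > 0)) return(0)
    terms <- terms[terms > 0]
  }
  100 * mean(terms)
}

#' Power of a target parameter
#'
#' Ratio between the maximum and minimum marginal mean GRL over the values
#' of a target parameter. A large power means the parameter creates wide
#' diversity in the quality of identity information.
#'
#' @param grl_means Positive GRL means, one per parameter value.
#' @return `max(grl_means) / min(grl_means)` (>= 1).
#' @export
#' @examples
#' power_ratio(c(5.03, 3.19, 4.12, 3.65, 6.15))  # ~1.93
power_ratio <- function(grl_means) {
  if (length(grl_means) < 1L || any(!is.finite(grl_means)))
    stop("need finite GRL means", call. = FALSE)
  if (any(grl_means <= 0))
    stop("power undefined for nonpositive GRL means", call. = FALSE)
  max(grl_means) / min(grl_means)
}

#' Decision-making metric (DMM)
#'
#' Combines the static accuracy at a given step with the global relative
#' loss: `DMM_n = acc_n / GRL`, with GRL on the percent scale. Maximizing
#' DMM selects the configuration with high accuracy and low degradation.
#'
#' @param acc_n Accuracy at the step of interest, in `[0, 1]`.
#' @param grl GRL in percent (> 0).
#' @return `acc_n / grl`; `NA` with a warning when `grl` is 0 (no
#'   degradation: the metric is undefined, not infinite).
#' @export
#' @examples
#' dmm(0.9, 1.0)  # 0.9
dmm <- function(acc_n, grl) {
  if (!is.numeric(acc_n) || length(acc_n) != 1L || acc_n < 0 || acc_n > 1)
    stop_field("acc_n", "must be a single accuracy in [0, 1]")
  if (!is.numeric(grl) || length(grl) != 1L || !is.finite(grl) || grl < 0)
    stop_field("grl", "must be a single nonnegative percent value")
  if (grl == 0) {
    warning("no degradation (GRL = 0): DMM undefined", call. = FALSE)
    return(NA_real_)
  }
  acc_n / grl
}

#' Self-relative report over a configuration grid
#'
#' Computes LRL, GRL and last-step DMM for every grid cell, the marginal
#' mean GRL per filter order (over all sub-bands) and per sub-band (over all
#' orders) each with its power ratio, and identifies the configuration
#' maximizing the last-step DMM.
#'
#' @param results Named list mapping `config_id` to [run_openness()] results,
#'   one per grid cell.
#' @param configs The configuration list from [expand_sweep()] (names must
#'   match `results`).
#' @param degrading_only Passed to [lrl()] and [grl()].
#' @return An object of class `selfrel_report`: list with `cells` (data
#'   frame), `order_marginals`, `band_marginals` (each with a `power`
#'   attribute, `NA` for single-value margins), `best` (row of `cells`).
#' @export
grid_report <- function(results, configs, degrading_only = FALSE) {
  missing <- setdiff(names(configs), names(results))
  if (length(missing))
    stop("missing results for grid cell(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  cells <- do.call(rbind, lapply(names(configs), function(id) {
    cfg <- configs[[id]]
    oam <- results[[id]]$mean
    g <- grl(oam, degrading_only)
    data.frame(config_id = id,
               filter_order = cfg$filter_order,
               band_low = cfg$band[1], band_high = cfg$band[2],
               filter_variant = cfg$filter_variant,
               acc_first = oam[1], acc_last = oam[length(oam)],
               lrl = lrl(oam, degrading_only), grl = g,
               dmm_last = if (g > 0) oam[length(oam)] / g else NA_real_,
               stringsAsFactors = FALSE)
  }))
  band_id <- sprintf("[%g, %g]", cells$band_low, cells$band_high)
  order_marginals <- tapply(cells$grl, cells$filter_order, mean)
  band_lv <- unique(band_id)
  band_marginals <- vapply(band_lv, function(b) mean(cells$grl[band_id == b]), numeric(1))
  safe_power <- function(v) {
    if (length(v) < 2L || any(v <= 0)) NA_real_ else power_ratio(v)
  }
  attr(order_marginals, "power") <- safe_power(as.numeric(order_marginals))
  attr(band_marginals, "power") <- safe_power(as.numeric(band_marginals))
  best <- if (all(is.na(cells$dmm_last))) NULL else
    cells[which.max(cells$dmm_last), , drop = FALSE]
  structure(list(cells = cells,
                 order_marginals = order_marginals,
                 band_marginals = band_marginals,
                 best = best),
            class = "selfrel_report")
}

#' @export
print.selfrel_report <- function(x, digits = 3, ...) {
  cat(sprintf("Self-relative report: %d configuration(s)\n", nrow(x$cells)))
  cat("\nMean GRL (%) per filter order:\n")
  print(round(c(unclass(x$order_marginals)), digits))
  cat(sprintf("  power: %s\n", format(attr(x$order_marginals, "power"), digits = digits)))
  cat("\nMean GRL (%) per sub-band:\n")
  print(round(c(x$band_marginals), digits))
  cat(sprintf("  power: %s\n", format(attr(x$band_marginals, "power"), digits = digits)))
  if (!is.null(x$best))
    cat(sprintf("\nBest configuration (max last-step DMM): %s (DMM = %.3g, GRL = %.3g%%)\n",
                x$best$config_id, x$best$dmm_last, x$best$grl))
  invisible(x)
}

#' Write a self-relative report
#'
#' Writes the per-cell metric table, the two marginal-GRL tables (rows =
#' filter variant is constant per run, columns = parameter values, final
#' column = power) as CSV, and a JSON summary naming the best
#' (order, sub-band) configuration.
#'
#' @param report A [grid_report()] result.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "selfrel_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$cells, file.path(dir, "cells.csv"), row.names = FALSE)
  om <- c(as.numeric(report$order_marginals), attr(report$order_marginals, "power"))
  names(om) <- c(names(report$order_marginals), "power")
  utils::write.csv(as.data.frame(t(om)), file.path(dir, "grl_by_order.csv"),
                   row.names = FALSE)
  bm <- c(as.numeric(report$band_marginals), attr(report$band_marginals, "power"))
  names(bm) <- c(names(report$band_marginals), "power")
  utils::write.csv(as.data.frame(t(bm)), file.path(dir, "grl_by_band.csv"),
                   row.names = FALSE)
  best <- if (is.null(report$best)) NULL else as.list(report$best)
  jsonlite::write_json(list(best = best), file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
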