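#' Classifier specification
#'
#' Describes the classifier used in the identification step. Four kinds are
#' supported: `"knn"` (k-nearest neighbours on Euclidean distance, the
#' default), `"naive_bayes"`, `"decision_tree"` and `"lda"`.
#'
#' @param kind Classifier family, one of `"knn"`, `"naive_bayes"`,
#'   `"decision_tree"`, `"lda"`.
#' @param neighbors Number of neighbours `k` (KNN only, default 1).
#' @param distance Distance measure (KNN only; only `"euclidean"` is
#'   supported).
#' @return An object of class `classifier_spec`.
#' @export
#' @examples
#' classifier_spec("knn", neighbors = 1)
classifier_spec <- function(kind = c("knn", "naive_bayes", "decision_tree", "lda"),
                            neighbors = 1L, distance = "euclidean") {
  kind <- match.arg(kind)
  if (kind == "knn") {
    neighbors <- check_number(neighbors, "neighbors", lower = 1, integer = TRUE)
    if (!identical(distance, "euclidean"))
      stop_field("distance", "only 'euclidean' is supported")
  }
  structure(list(kind = kind,
                 neighbors = if (kind == "knn") neighbors else NULL,
                 distance = if (kind == "knn") distance else NULL),
            class = "classifier_spec")
}

#' Default 19-channel 10-20 electrode set
#'
#' The conventional 19-electrode subset of the international 10-20 system,
#' used as the default channel set of [pipeline_config()].
#'
#' @return Character vector of 19 channel labels.
#' @export
default_channel_set <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "T7", "C3", "Cz", "C4", "T8",
    "P7", "P3", "Pz", "P4", "P8", "O1", "O2")
}

#' Pipeline configuration (parametric representation)
#'
#' Collects every stage's input parameters for the EEG identification
#' pipeline into one validated object: channel selection, common average
#' referencing, Butterworth band-pass filtering, static overlapped
#' segmentation, Burg AR feature extraction, and classification.
#'
#' @param channel_set Ordered character vector of channel labels (H >= 2).
#' @param filter_order Butterworth filter order O (>= 1).
#' @param band Numeric pair `c(low, high)` in Hz; must satisfy
#'   `0 < low < high < sampling_rate / 2`.
#' @param filter_variant `"causal"` (single forward pass) or `"zero_phase"`
#'   (forward-backward application of the same design).
#' @param sampling_rate Sampling rate fs in Hz.
#' @param segment_length Segment duration v in seconds.
#' @param overlap Overlap fraction alpha in `[0, 1)`.
#' @param ar_order AR model order Q (>= 1); the feature dimension is
#'   `d = H * Q`.
#' @param classifier A [classifier_spec()].
#' @param kfold Number of cross-validation folds (>= 2).
#' @param duration Recording duration V in seconds (`segment_length <= duration`).
#' @param car_scope Whether common average referencing is computed over the
#'   `"selected"` channel set (default) or `"all"` channels of the incoming
#'   recording before subsetting.
#' @return An object of class `pipeline_config`.
#' @export
#' @examples
#' cfg <- pipeline_config(filter_order = 2, band = c(30, 50))
#' cfg$ar_order
pipeline_config <- function(channel_set = default_channel_set(),
                            filter_order = 2L,
                            band = c(8, 13),
                            filter_variant = c("causal", "zero_phase"),
                            sampling_rate = 160,
                            segment_length = 5,
                            overlap = 0.4,
                            ar_order = 12L,
                            classifier = classifier_spec("knn"),
                            kfold = 3L,
                            duration = 60,
                            car_scope = c("selected", "all")) {
  filter_variant <- match.arg(filter_variant)
  car_scope <- match.arg(car_scope)
  if (!is.character(channel_set) || length(channel_set) < 2L)
    stop_field("channel_set", "needs at least 2 channel labels (CAR undefined otherwise)")
  if (anyDuplicated(channel_set))
    stop_field("channel_set", "contains duplicated labels")
  filter_order <- check_number(filter_order, "filter_order", lower = 1, integer = TRUE)
  sampling_rate <- check_number(sampling_rate, "sampling_rate", lower = 0, strict_lower = TRUE)
  if (!is.numeric(band) || length(band) != 2L || any(!is.finite(band)))
    stop_field("band", "must be a numeric pair c(low, high)")
  if (band[1] <= 0)
    stop_field("band", "low edge must be > 0 Hz")
  if (band[1] >= band[2])
    stop_field("band", sprintf("low edge (%g) must be below high edge (%g)", band[1], band[2]))
  if (band[2] >= sampling_rate / 2)
    stop_field("band", sprintf("high edge (%g) must be below the Nyquist frequency (%g)",
                               band[2], sampling_rate / 2))
  duration <- check_number(duration, "duration", lower = 0, strict_lower = TRUE)
  segment_length <- check_number(segment_length, "segment_length",
                                 lower = 0, upper = duration, strict_lower = TRUE)
  overlap <- check_number(overlap, "overlap", lower = 0)
  if (overlap >= 1) stop_field("overlap", "must be in [0, 1)")
  ar_order <- check_number(ar_order, "ar_order", lower = 1, integer = TRUE)
  kfold <- check_number(kfold, "kfold", lower = 2, integer = TRUE)
  if (!inherits(classifier, "classifier_spec"))
    stop_field("classifier", "must be a classifier_spec object")
  structure(list(channel_set = channel_set,
                 filter_order = filter_order,
                 band = as.numeric(band),
                 filter_variant = filter_variant,
                 sampling_rate = sampling_rate,
                 segment_length = segment_length,
                 overlap = overlap,
                 ar_order = ar_order,
                 classifier = classifier,
                 kfold = kfold,
                 duration = duration,
                 car_scope = car_scope),
            class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("EEG identification pipeline configuration\n")
  cat(sprintf("  channels:     H = %d\n", length(x$channel_set)))
  cat(sprintf("  band-pass:    [%g, %g] Hz, Butterworth order %d (%s)\n",
              x$band[1], x$band[2], x$filter_order, x$filter_variant))
  cat(sprintf("  segmentation: v = %g s, overlap = %g, fs = %g Hz, V = %g s\n",
              x$segment_length, x$overlap, x$sampling_rate, x$duration))
  cat(sprintf("  features:     Burg AR order Q = %d (d = %d)\n",
              x$ar_order, length(x$channel_set) * x$ar_order))
  cat(sprintf("  classifier:   %s, %d-fold CV\n", x$classifier$kind, x$kfold))
  invisible(x)
}

#' Sweep specification over filter orders and frequency sub-bands
#'
#' The two target parameters whose grid defines the identity-information
#' distributions: a set S1 of Butterworth orders and a set S2 of frequency
#' sub-bands. The grid has `length(orders) * length(bands)` cells.
#'
#' @param orders Integer vector of filter orders (S1).
#' @param bands List of numeric pairs `c(low, high)` in Hz (S2).
#' @return An object of class `sweep_spec`.
#' @export
#' @examples
#' sweep_spec(orders = 1:5,
#'            bands = list(c(0.5, 4), c(4, 8), c(8, 13), c(13, 30), c(30, 50)))
sweep_spec <- function(orders, bands) {
  if (length(orders) < 1L) stop_field("orders", "must be non-empty")
  orders <- vapply(orders, check_number, numeric(1),
                   field = "orders", lower = 1, integer = TRUE)
  if (anyDuplicated(orders)) stop_field("orders", "contains duplicates")
  if (!is.list(bands) || length(bands) < 1L)
    stop_field("bands", "must be a non-empty list of c(low, high) pairs")
  for (b in bands) {
    if (!is.numeric(b) || length(b) != 2L || b[1] <= 0 || b[1] >= b[2])
      stop_field("bands", "each band must be a numeric pair with 0 < low < high")
  }
  key <- vapply(bands, function(b) paste(b, collapse = "-"), character(1))
  if (anyDuplicated(key)) stop_field("bands", "contains duplicates")
  structure(list(orders = as.integer(orders), bands = lapply(bands, as.numeric)),
            class = "sweep_spec")
}

#' Expand a sweep into the full configuration grid
#'
#' Produces one [pipeline_config()] per (filter order, sub-band) pair, in
#' order-major order, each differing from `base` only in those two fields and
#' carrying a stable `config_id` attribute of the form `"o<order>_b<low>-<high>"`.
#'
#' @param base A [pipeline_config()] supplying every non-swept parameter.
#' @param sweep A [sweep_spec()].
#' @return Named list of `pipeline_config` objects of length
#'   `length(orders) * length(bands)`.
#' @export
expand_sweep <- function(base, sweep) {
  stopifnot(inherits(base, "pipeline_config"), inherits(sweep, "sweep_spec"))
  out <- list()
  for (o in sweep$orders) {
    for (b in sweep$bands) {
      cfg <- pipeline_config(channel_set = base$channel_set,
                             filter_order = o,
                             band = b,
                             filter_variant = base$filter_variant,
                             sampling_rate = base$sampling_rate,
                             segment_length = base$segment_length,
                             overlap = base$overlap,
                             ar_order = base$ar_order,
                             classifier = base$classifier,
                             kfold = base$kfold,
                             duration = base$duration,
                             car_scope = base$car_scope)
      id <- config_id(cfg)
      attr(cfg, "config_id") <- id
      out[[id]] <- cfg
    }
  }
  out
}

#' Stable identifier of a grid cell
#'
#' @param config A [pipeline_config()].
#' @return Character scalar `"o<order>_b<low>-<high>"`.
#' @export
config_id <- function(config) {
  sprintf("o%d_b%g-%g", config$filter_order, config$band[1], config$band[2])
}

# ---- run-config file (YAML) -------------------------------------------------

.known_keys <- list(
  top = c("seed", "pipeline", "sweep", "openness", "evaluation", "input"),
  pipeline = c("channels", "filter_order", "band_low_hz", "band_high_hz",
               "filter_variant", "sampling_rate_hz", "segment_length_s",
               "overlap_fraction", "duration_s", "ar_order", "car_scope"),
  evaluation = c("classifier", "neighbors", "distance", "kfold"),
  sweep = c("orders", "bands"),
  openness = c("t1", "tr", "steps", "step_trials", "step_prob", "sequences"),
  input = c("synthetic", "edf_dir"),
  synthetic = c("n_subjects", "n_channels", "sampling_rate_hz", "duration_s",
                "identity_band", "separability", "noise_sd",
                "generator_ar_order")
)

.check_keys <- function(block, what) {
  unknown <- setdiff(names(block), .known_keys[[what]])
  if (length(unknown))
    stop(sprintf("unknown key(s) in '%s' block: %s", what,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  missing <- setdiff(.known_keys[[what]], names(block))
  invisible(missing)
}

#' Load and validate a run configuration file
#'
#' Reads a flat YAML file describing one full run: a `pipeline` block (signal
#' parameters with explicit units in field names), an `evaluation` block
#' (classifier and cross-validation), a `sweep` block (S1 orders and S2
#' bands), an `openness` block (enrollment simulation), an optional `input`
#' block (a synthetic cohort spec or an EDF directory) and a `seed`. Unknown
#' keys are errors.
#'
#' @param path Path to the YAML file.
#' @return A list with elements `pipeline` ([pipeline_config()]), `sweep`
#'   ([sweep_spec()]), `openness` (a list of openness parameters), `input`
#'   (or `NULL`) and `seed`.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  .check_keys(raw, "top")
  for (blk in c("pipeline", "sweep", "openness"))
    if (is.null(raw[[blk]])) stop("missing '", blk, "' block", call. = FALSE)
  .check_keys(raw$pipeline, "pipeline")
  .check_keys(raw$sweep, "sweep")
  .check_keys(raw$openness, "openness")
  ev <- raw$evaluation %||% list()
  .check_keys(ev, "evaluation")

  clf <- classifier_spec(kind = ev$classifier %||% "knn",
                         neighbors = ev$neighbors %||% 1L,
                         distance = ev$distance %||% "euclidean")
  p <- raw$pipeline
  pipeline <- pipeline_config(
    channel_set = unlist(p$channels) %||% default_channel_set(),
    filter_order = p$filter_order %||% 2L,
    band = c(p$band_low_hz %||% 8, p$band_high_hz %||% 13),
    filter_variant = p$filter_variant %||% "causal",
    sampling_rate = p$sampling_rate_hz %||% 160,
    segment_length = p$segment_length_s %||% 5,
    overlap = p$overlap_fraction %||% 0.4,
    ar_order = p$ar_order %||% 12L,
    classifier = clf,
    kfold = ev$kfold %||% 3L,
    duration = p$duration_s %||% 60,
    car_scope = p$car_scope %||% "selected")

  sw <- raw$sweep
  sweep <- sweep_spec(orders = unlist(sw$orders),
                      bands = lapply(sw$bands, unlist))

  op <- raw$openness
  openness <- list(t1 = op$t1 %||% 5L, tr = op$tr %||% 97L,
                   steps = op$steps %||% 24L,
                   step_trials = op$step_trials %||% 100L,
                   step_prob = op$step_prob %||% 0.04,
                   sequences = op$sequences %||% 10L)

  input <- NULL
  if (!is.null(raw$input)) {
    .check_keys(raw$input, "input")
    if (!is.null(raw$input$synthetic)) .check_keys(raw$input$synthetic, "synthetic")
    input <- raw$input
  }
  list(pipeline = pipeline, sweep = sweep, openness = openness,
       input = input, seed = as.integer(raw$seed %||% 1L))
}

#' Write a run configuration file
#'
#' Inverse of [load_run_config()]; the round trip through the file format is
#' lossless for every validated field.
#'
#' @param config A list as returned by [load_run_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  p <- config$pipeline
  out <- list(
    seed = config$seed,
    pipeline = list(
      channels = as.list(p$channel_set),
      filter_order = p$filter_order,
      band_low_hz = p$band[1], band_high_hz = p$band[2],
      filter_variant = p$filter_variant,
      sampling_rate_hz = p$sampling_rate,
      segment_length_s = p$segment_length,
      overlap_fraction = p$overlap,
      duration_s = p$duration,
      ar_order = p$ar_order,
      car_scope = p$car_scope),
    evaluation = c(list(classifier = p$classifier$kind, kfold = p$kfold),
                   if (p$classifier$kind == "knn")
                     list(neighbors = p$classifier$neighbors,
                          distance = p$classifier$distance)),
    sweep = list(orders = as.list(config$sweep$orders),
                 bands = lapply(config$sweep$bands, as.list)),
    openness = config$openness)
  if (!is.null(config$input)) out$input <- config$input
  yaml::write_yaml(out, path)
  invisible(path)
}
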