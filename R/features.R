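#' Burg autoregressive coefficient estimation
#'
#' Estimates the coefficients of an AR(Q) model by Burg's method: the
#' reflection coefficient at each order minimizes the summed forward and
#' backward prediction-error energy, and the coefficient vector is updated
#' by the Levinson recursion. The series is mean-centered first; Burg's
#' method fits a zero-mean model with no intercept.
#'
#' Coefficients are returned in the convention where `x_t` is predicted from
#' `+ sum_i a_i * x_(t-i)` (the same convention as `stats::ar.burg`).
#'
#' @param x Numeric series of length `n > order`, not identically constant.
#' @param order AR order Q (>= 1).
#' @return Numeric vector of Q AR coefficients.
#' @export
#' @examples
#' set.seed(1)
#' x <- as.numeric(arima.sim(list(ar = c(0.5, -0.25)), 4000))
#' burg_ar(x, 2)
burg_ar <- function(x, order) {
  order <- check_number(order, "order", lower = 1, integer = TRUE)
  x <- as.numeric(x)
  n <- length(x)
  if (n <= order)
    stop(sprintf("series length (%d) must exceed the AR order (%d)", n, order),
         call. = FALSE)
  if (anyNA(x) || any(!is.finite(x)))
    stop("series contains non-finite values", call. = FALSE)
  x <- x - mean(x)
  if (sum(x^2) == 0)
    stop("zero-variance series: AR coefficients undefined", call. = FALSE)
  f <- x  # forward prediction errors
  b <- x  # backward prediction errors
  a <- numeric(0)
  for (m in seq_len(order)) {
    ff <- f[-1L]
    bb <- b[-length(b)]
    den <- sum(ff^2) + sum(bb^2)
    k <- if (den == 0) 0 else -2 * sum(ff * bb) / den
    a <- c(a + k * rev(a), k)
    f <- ff + k * bb
    b <- bb + k * ff
  }
  -a
}

#' Extract Burg AR feature vectors from a segment set
#'
#' Estimates an order-Q Burg AR model on every channel of every segment and
#' concatenates the per-channel coefficient blocks (in channel-label order)
#' into one identity vector of dimension `d = H * Q` per segment.
#'
#' @param segs A [segment_recording()] result.
#' @param ar_order AR order Q.
#' @return Numeric matrix, one row per segment, `H * Q` columns named
#'   `<channel>_a<i>`; attribute `subject_label` carries the segment set's
#'   label.
#' @export
extract_features <- function(segs, ar_order) {
  stopifnot(inherits(segs, "segment_set"))
  ar_order <- check_number(ar_order, "ar_order", lower = 1, integer = TRUE)
  H <- length(segs$channel_labels)
  out <- matrix(NA_real_, nrow = length(segs$segments), ncol = H * ar_order)
  colnames(out) <- as.vector(t(outer(segs$channel_labels,
                                     paste0("_a", seq_len(ar_order)), paste0)))
  for (i in seq_along(segs$segments)) {
    seg <- segs$segments[[i]]
    for (ch in seq_len(H)) {
      coefs <- tryCatch(burg_ar(seg[ch, ], ar_order), error = function(e)
        stop(sprintf("AR estimation failed (segment %d, channel %s): %s",
                     i, segs$channel_labels[ch], conditionMessage(e)), call. = FALSE))
      out[i, ((ch - 1L) * ar_order + 1L):(ch * ar_order)] <- coefs
    }
  }
  attr(out, "subject_label") <- segs$subject_label
  out
}

#' Build the labeled feature space for one configuration
#'
#' Runs the full pipeline (channel selection, common average referencing,
#' Butterworth band-pass, static overlapped segmentation, Burg AR feature
#' extraction) on every recording of a cohort and stacks the resulting
#' identity vectors into one `(E * N) x d` labeled matrix.
#'
#' @param cohort A [generate_cohort()] result or a plain list of
#'   [eeg_recording()] objects with distinct subject labels.
#' @param config A [pipeline_config()].
#' @return An object of class `feature_space`: list with `matrix`
#'   (`(E * N) x d`), `labels` (integer vector), `config_id`,
#'   `n_per_subject` and `config`.
#' @export
build_feature_space <- function(cohort, config) {
  stopifnot(inherits(config, "pipeline_config"))
  recs <- if (inherits(cohort, "synthetic_cohort")) cohort$recordings else cohort
  if (length(recs) == 0L) stop("empty cohort", call. = FALSE)
  blocks <- vector("list", length(recs))
  labels <- vector("list", length(recs))
  for (i in seq_along(recs)) {
    rec <- recs[[i]]
    step <- "channel selection"
    feats <- tryCatch({
      if (config$car_scope == "all") {
        rec <- car_filter(rec)
        rec <- if (all(config$channel_set %in% rec$channel_labels))
          select_channels(rec, config$channel_set) else rec
      } else {
        rec <- if (all(config$channel_set %in% rec$channel_labels))
          select_channels(rec, config$channel_set) else rec
        step <- "CAR"
        rec <- car_filter(rec)
      }
      step <- "band-pass"
      rec <- bandpass(rec, config$filter_order, config$band, config$filter_variant)
      step <- "segmentation"
      segs <- segment_recording(rec, config$segment_length, config$overlap)
      step <- "feature extraction"
      extract_features(segs, config$ar_order)
    }, error = function(e) {
      stop(sprintf("subject %s failed at %s: %s",
                   recs[[i]]$subject_label, step, conditionMessage(e)),
           call. = FALSE)
    })
    blocks[[i]] <- feats
    labels[[i]] <- rep(recs[[i]]$subject_label, nrow(feats))
  }
  structure(list(matrix = do.call(rbind, blocks),
                 labels = unlist(labels),
                 config_id = attr(config, "config_id") %||% config_id(config),
                 n_per_subject = nrow(blocks[[1]]),
                 config = config),
            class = "feature_space")
}

#' @export
print.feature_space <- function(x, ...) {
  cat(sprintf("Feature space [%s]: %d x %d (%d subjects x %d vectors, d = %d)\n",
              x$config_id, nrow(x$matrix), ncol(x$matrix),
              length(unique(x$labels)), x$n_per_subject, ncol(x$matrix)))
  invisible(x)
}

#' Write a feature space to CSV
#'
#' One row per identity vector: `label`, `config_id`, then the coefficient
#' columns. Enables metric-only reruns without touching the signals.
#'
#' @param space A [build_feature_space()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_space <- function(space, path) {
  stopifnot(inherits(space, "feature_space"))
  df <- data.frame(label = space$labels, config_id = space$config_id,
                   space$matrix, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature space written by [write_feature_space()]
#'
#' @param path CSV path.
#' @return A `feature_space` object (without the producing `config`).
#' @export
read_feature_space <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("label", "config_id") %in% names(df)))
    stop("not a feature-space CSV: ", path, call. = FALSE)
  m <- as.matrix(df[, setdiff(names(df), c("label", "config_id")), drop = FALSE])
  labels <- as.integer(df$label)
  structure(list(matrix = m, labels = labels,
                 config_id = as.character(df$config_id[1]),
                 n_per_subject = as.integer(table(labels))[1],
                 config = NULL),
            class = "feature_space")
}
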