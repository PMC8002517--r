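#' Multichannel EEG recording
#'
#' Container for one subject's multichannel signal: an `H x (fs * V)` sample
#' matrix (channels in rows), its sampling rate, channel labels and subject
#' label.
#'
#' @param samples Numeric matrix, channels in rows.
#' @param sampling_rate Sampling rate in Hz.
#' @param channel_labels Character vector, one label per row.
#' @param subject_label Integer subject label.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(samples, sampling_rate, channel_labels, subject_label = NA_integer_) {
  if (!is.matrix(samples) || !is.numeric(samples))
    stop_field("samples", "must be a numeric matrix (channels x samples)")
  sampling_rate <- check_number(sampling_rate, "sampling_rate", lower = 0, strict_lower = TRUE)
  if (length(channel_labels) != nrow(samples))
    stop_field("channel_labels", sprintf("%d labels for %d channel rows",
                                         length(channel_labels), nrow(samples)))
  rownames(samples) <- channel_labels
  structure(list(samples = samples,
                 sampling_rate = sampling_rate,
                 channel_labels = as.character(channel_labels),
                 subject_label = as.integer(subject_label),
                 duration = ncol(samples) / sampling_rate),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("EEG recording: subject %s, %d channels x %d samples (%g s @ %g Hz)\n",
              x$subject_label, nrow(x$samples), ncol(x$samples),
              x$duration, x$sampling_rate))
  invisible(x)
}

#' Select a subset of channels by label
#'
#' @param rec An [eeg_recording()].
#' @param channels Character vector of labels to keep, in the requested order.
#' @return An [eeg_recording()] restricted to `channels`.
#' @export
select_channels <- function(rec, channels) {
  stopifnot(inherits(rec, "eeg_recording"))
  missing <- setdiff(channels, rec$channel_labels)
  if (length(missing))
    stop("channel(s) not present in recording: ", paste(missing, collapse = ", "),
         call. = FALSE)
  idx <- match(channels, rec$channel_labels)
  eeg_recording(rec$samples[idx, , drop = FALSE], rec$sampling_rate,
                channels, rec$subject_label)
}

#' Common average reference (CAR) spatial filter
#'
#' Subtracts the instantaneous cross-channel mean from every channel, so that
#' at each time sample the column sum of the output is zero. Used to reduce
#' artifacts related to an unsuitable or drifting reference electrode. CAR is
#' a projection: applying it twice equals applying it once.
#'
#' @param rec An [eeg_recording()] with at least 2 channels.
#' @return The referenced [eeg_recording()], same shape.
#' @export
#' @examples
#' rec <- eeg_recording(rbind(c(1, 2, 3), c(3, 4, 5)), 100, c("C3", "C4"), 1L)
#' car_filter(rec)$samples
car_filter <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (nrow(rec$samples) < 2L)
    stop("CAR requires at least 2 channels", call. = FALSE)
  out <- sweep(rec$samples, 2L, colMeans(rec$samples), `-`)
  eeg_recording(out, rec$sampling_rate, rec$channel_labels, rec$subject_label)
}

#' Butterworth band-pass filter
#'
#' Designs a digital band-pass Butterworth filter of the given order and
#' applies it to every channel. The `"causal"` variant is a single forward
#' pass (one-dimensional digital filtering); the `"zero_phase"` variant
#' applies the same design forward and backward, cancelling the phase
#' distortion at the cost of non-causality. Causal transients are not
#' trimmed.
#'
#' @param rec An [eeg_recording()].
#' @param order Filter order (>= 1). Note the forward-backward variant
#'   doubles the effective magnitude order.
#' @param band Numeric pair `c(low, high)` in Hz, inside `(0, fs/2)`.
#' @param variant `"causal"` or `"zero_phase"`.
#' @return The filtered [eeg_recording()], same shape.
#' @export
bandpass <- function(rec, order, band, variant = c("causal", "zero_phase")) {
  stopifnot(inherits(rec, "eeg_recording"))
  variant <- match.arg(variant)
  order <- check_number(order, "order", lower = 1, integer = TRUE)
  fs <- rec$sampling_rate
  if (!is.numeric(band) || length(band) != 2L || band[1] <= 0 ||
      band[1] >= band[2] || band[2] >= fs / 2)
    stop_field("band", sprintf("must satisfy 0 < low < high < fs/2 = %g", fs / 2))
  filt <- signal::butter(order, band / (fs / 2), type = "pass")
  # denominator roots must be inside the unit circle; report, never clip
  r <- Mod(polyroot(rev(filt$a)))
  if (any(r >= 1 - 1e-10))
    stop(sprintf("unstable band-pass design (order %d, band [%g, %g] Hz at fs %g Hz): pole modulus %.6f",
                 order, band[1], band[2], fs, max(r)), call. = FALSE)
  apply_fn <- if (variant == "causal") {
    function(x) as.numeric(signal::filter(filt, x))
  } else {
    function(x) as.numeric(signal::filtfilt(filt, x))
  }
  out <- t(apply(rec$samples, 1L, apply_fn))
  eeg_recording(out, fs, rec$channel_labels, rec$subject_label)
}

#' Number of complete segments
#'
#' Closed-form count of full-length windows of duration `v` with overlap
#' fraction `alpha` inside a recording of duration `V`:
#' `N = floor((V - v) / (v * (1 - alpha))) + 1`. Only windows that fit
#' entirely within the signal are counted.
#'
#' @param duration Total duration V in seconds.
#' @param segment_length Window duration v in seconds.
#' @param overlap Overlap fraction alpha in `[0, 1)`.
#' @return Integer segment count N.
#' @export
#' @examples
#' n_segments(60, 5, 0.4)  # 19
n_segments <- function(duration, segment_length, overlap) {
  stopifnot(segment_length > 0, segment_length <= duration, overlap >= 0, overlap < 1)
  hop <- segment_length * (1 - overlap)
  as.integer(floor((duration - segment_length) / hop + 1e-9)) + 1L
}

#' Static overlapped segmentation
#'
#' Cuts the recording into windows of `segment_length` seconds starting at
#' offsets `0, hop, 2 * hop, ...` with `hop = segment_length * (1 - overlap)`,
#' keeping only complete windows. The hop must correspond to a whole number
#' of samples.
#'
#' @param rec An [eeg_recording()].
#' @param segment_length Window duration v in seconds.
#' @param overlap Overlap fraction alpha in `[0, 1)`.
#' @return An object of class `segment_set`: list with `segments` (list of
#'   `H x (v * fs)` matrices), `subject_label`, `channel_labels`,
#'   `sampling_rate`.
#' @export
#' @examples
#' rec <- eeg_recording(matrix(rnorm(2 * 1600), 2), 160, c("C3", "C4"), 1L)
#' length(segment_recording(rec, 5, 0.4)$segments)  # V = 10 s -> 2 segments
segment_recording <- function(rec, segment_length, overlap) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$sampling_rate
  V <- rec$duration
  segment_length <- check_number(segment_length, "segment_length",
                                 lower = 0, upper = V, strict_lower = TRUE)
  overlap <- check_number(overlap, "overlap", lower = 0)
  if (overlap >= 1) stop_field("overlap", "must be in [0, 1)")
  hop <- segment_length * (1 - overlap) * fs
  if (hop <= 0 || abs(hop - round(hop)) > 1e-8)
    stop(sprintf(paste0("hop v * (1 - alpha) * fs = %g is not a positive whole number of samples; ",
                        "choose v, alpha, fs so that the hop falls on a sample boundary"), hop),
         call. = FALSE)
  hop <- as.integer(round(hop))
  win <- as.integer(round(segment_length * fs))
  total <- ncol(rec$samples)
  starts <- seq.int(1L, total - win + 1L, by = hop)
  segs <- lapply(starts, function(s) rec$samples[, s:(s + win - 1L), drop = FALSE])
  structure(list(segments = segs,
                 subject_label = rec$subject_label,
                 channel_labels = rec$channel_labels,
                 sampling_rate = fs,
                 segment_length = segment_length,
                 overlap = overlap),
            class = "segment_set")
}
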