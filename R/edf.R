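# Minimal European Data Format (EDF) I/O: continuous recordings, 16-bit
# samples, one data record spanning the whole signal. Sufficient for reading
# resting-state archives and for persisting synthetic cohorts; EDF+
# annotations are not supported.

.edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1L, width)
  formatC(x, width = -width, flag = " ")
}

.edf_num <- function(x, width) {
  s <- formatC(x, format = "g", digits = 6)
  if (nchar(s) > width) s <- formatC(x, format = "g", digits = 4)
  .edf_pad(s, width)
}

#' Write a recording to an EDF file
#'
#' Writes one [eeg_recording()] as a continuous 16-bit EDF file (a single
#' data record). Each channel is scaled to its own symmetric physical range,
#' so the round trip is exact up to 16-bit quantization.
#'
#' @param rec An [eeg_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  H <- nrow(rec$samples)
  n <- ncol(rec$samples)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edf_pad("0", 8),
    .edf_pad(sprintf("S%d", rec$subject_label), 80),
    .edf_pad("selfrelEEG synthetic", 80),
    .edf_pad("01.01.00", 8), .edf_pad("00.00.00", 8),
    .edf_pad(256 * (1 + H), 8),
    .edf_pad("", 44),
    .edf_pad(1, 8),
    .edf_num(rec$duration, 8),
    .edf_pad(H, 4))
  writeChar(hdr, con, eos = NULL)
  # per-channel physical range: format first, then parse back, so the
  # quantization uses exactly the range stored in the header
  pm_str <- vapply(seq_len(H), function(ch) {
    pm <- max(abs(rec$samples[ch, ]), 1e-6)
    .edf_num(pm * 1.0001, 8)
  }, character(1))
  pm <- as.numeric(pm_str)
  field <- function(vals, width)
    writeChar(paste(vapply(vals, .edf_pad, character(1), width = width),
                    collapse = ""), con, eos = NULL)
  field(rec$channel_labels, 16)
  field(rep("", H), 80)
  field(rep("uV", H), 8)
  field(trimws(paste0("-", trimws(pm_str))), 8)
  field(trimws(pm_str), 8)
  field(rep(-32768L, H), 8)
  field(rep(32767L, H), 8)
  field(rep("", H), 80)
  field(rep(n, H), 8)
  field(rep("", H), 32)
  for (ch in seq_len(H)) {
    dig <- round((rec$samples[ch, ] + pm[ch]) / (2 * pm[ch]) * 65535 - 32768)
    writeBin(as.integer(pmin(pmax(dig, -32768), 32767)), con,
             size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file
#'
#' Reads a continuous 16-bit EDF file into an [eeg_recording()], optionally
#' restricted to a subset of channels by label. All signals must share one
#' sampling rate. A subject label of the form `S<integer>` in the patient
#' field is recovered if present.
#'
#' @param path EDF file path.
#' @param channels Optional character vector of channel labels to keep.
#' @return An [eeg_recording()].
#' @export
read_edf <- function(path, channels = NULL) {
  if (!file.exists(path)) stop("EDF file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  version <- rd(8)
  patient <- rd(80)
  rd(80); rd(8); rd(8)
  rd(8)  # header length, implied by ns
  rd(44)
  n_records <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  rdv <- function(width) vapply(seq_len(ns), function(i) rd(width), character(1))
  labels <- rdv(16)
  rdv(80); rdv(8)
  phys_min <- as.numeric(rdv(8))
  phys_max <- as.numeric(rdv(8))
  dig_min <- as.numeric(rdv(8))
  dig_max <- as.numeric(rdv(8))
  rdv(80)
  spr <- as.integer(rdv(8))
  rdv(32)
  if (length(unique(spr)) != 1L)
    stop("EDF signals with differing sampling rates are not supported", call. = FALSE)
  total <- spr[1] * n_records
  samples <- matrix(NA_real_, nrow = ns, ncol = total)
  for (r in seq_len(n_records)) {
    for (ch in seq_len(ns)) {
      d <- readBin(con, "integer", n = spr[ch], size = 2L, signed = TRUE,
                   endian = "little")
      gain <- (phys_max[ch] - phys_min[ch]) / (dig_max[ch] - dig_min[ch])
      samples[ch, ((r - 1L) * spr[ch] + 1L):(r * spr[ch])] <-
        phys_min[ch] + (d - dig_min[ch]) * gain
    }
  }
  fs <- spr[1] / rec_dur
  label <- if (grepl("^S-?[0-9]+$", patient))
    as.integer(sub("^S", "", patient)) else NA_integer_
  rec <- eeg_recording(samples, fs, labels, label)
  if (!is.null(channels)) rec <- select_channels(rec, channels)
  rec
}

#' Write a synthetic cohort as EDF files
#'
#' One EDF file per subject (`subject_<label>.edf`) plus the ground-truth
#' generator coefficient table (`ground_truth.csv`).
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort_edf <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (rec in cohort$recordings)
    write_edf(rec, file.path(dir, sprintf("subject_%03d.edf", rec$subject_label)))
  utils::write.csv(cohort$ground_truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a directory of EDF files as a cohort
#'
#' @param dir Directory containing `.edf` files, one subject each.
#' @param channels Optional channel subset passed to [read_edf()].
#' @return List of [eeg_recording()] objects; subjects lacking an encoded
#'   label are numbered by file order.
#' @export
read_cohort_edf <- function(dir, channels = NULL) {
  if (!dir.exists(dir)) stop("EDF directory not found: ", dir, call. = FALSE)
  files <- sort(list.files(dir, pattern = "\\.edf$", full.names = TRUE,
                           ignore.case = TRUE))
  if (length(files) == 0L) stop("no .edf files in ", dir, call. = FALSE)
  recs <- lapply(files, read_edf, channels = channels)
  for (i in seq_along(recs))
    if (is.na(recs[[i]]$subject_label)) recs[[i]]$subject_label <- i
  recs
}
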