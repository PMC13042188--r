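#' Construct a resting-state EEG recording
#'
#' A light container for a multichannel recording: a channels-by-samples
#' matrix of microvolt values with sampling rate, 10-10 montage channel
#' names, optional per-sample eyes-open/eyes-closed labels, and segment
#' boundaries (spectral windows never span a boundary).
#'
#' @param data Numeric matrix, channels x samples.
#' @param sampling_rate Sampling frequency in Hz (analysis requires
#'   `> 2 * 30` Hz; the reference acquisition rate is 400 Hz).
#' @param channels Channel names (default taken from `rownames(data)`).
#' @param subject_id,visit Identifiers.
#' @param segment_labels Optional per-sample logical (or "EC"/"EO"
#'   character) vector: `TRUE`/"EC" marks eyes-closed samples.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, sampling_rate, channels = rownames(data),
                          subject_id = "s1", visit = 0L,
                          segment_labels = NULL) {
  data <- as.matrix(data)
  if (is.null(channels)) {
    channels <- paste0("ch", seq_len(nrow(data)))
  }
  if (length(channels) != nrow(data)) {
    abort("`channels` length must equal the number of data rows.")
  }
  if (anyDuplicated(channels) > 0) abort("Channel names must be unique.")
  if (sampling_rate <= 2 * 30) {
    abort("Sampling rate must exceed twice the highest analysis frequency (30 Hz).")
  }
  if (!is.null(segment_labels)) {
    if (is.character(segment_labels)) {
      segment_labels <- toupper(segment_labels) == "EC"
    }
    if (length(segment_labels) != ncol(data)) {
      abort("`segment_labels` must have one entry per sample.")
    }
  }
  rownames(data) <- channels
  structure(
    list(data = data, sampling_rate = sampling_rate, channels = channels,
         subject_id = subject_id, visit = as.integer(visit),
         segment_labels = segment_labels,
         boundaries = 1L,  # start index of each contiguous chunk
         provenance = list()),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("<eeg_recording> ", x$subject_id, " visit ", x$visit, ": ",
      length(x$channels), " channels x ", ncol(x$data), " samples @ ",
      x$sampling_rate, " Hz (", round(ncol(x$data) / x$sampling_rate, 1),
      " s)\n", sep = "")
  invisible(x)
}

# contiguous chunks of a recording as a list of column index ranges
recording_chunks <- function(rec) {
  starts <- sort(unique(c(1L, rec$boundaries)))
  ends <- c(starts[-1] - 1L, ncol(rec$data))
  purrr::map2(starts, ends, ~ .x:.y)
}

#' Read a recording from a plain two-file TSV format
#'
#' Expects a header file (one channel name per line) and a sample matrix
#' (TSV, one row per sample, one column per channel).
#'
#' @param matrix_path Path to the TSV sample matrix.
#' @param header_path Path to the channel-name file; defaults to
#'   `<matrix_path>.channels`.
#' @param sampling_rate Sampling frequency in Hz.
#' @inheritParams eeg_recording
#' @return An `eeg_recording`.
#' @export
read_raw_tsv <- function(matrix_path, header_path = paste0(matrix_path,
                                                           ".channels"),
                         sampling_rate, subject_id = "s1", visit = 0L) {
  channels <- readLines(header_path)
  m <- as.matrix(readr::read_tsv(matrix_path, col_names = FALSE,
                                 show_col_types = FALSE))
  if (ncol(m) != length(channels)) {
    abort("Sample matrix column count does not match the channel header.")
  }
  eeg_recording(t(m), sampling_rate = sampling_rate, channels = channels,
                subject_id = subject_id, visit = visit)
}

#' Read a 16-bit EDF recording
#'
#' Minimal reader for the standard European Data Format: ASCII headers,
#' little-endian 16-bit samples, per-signal physical/digital calibration.
#' All signals must share one sampling rate. Annotation channels are not
#' supported.
#'
#' @param path Path to the `.edf` file.
#' @param subject_id,visit Identifiers (default: the EDF local patient
#'   field, visit 0).
#' @return An `eeg_recording`.
#' @export
read_edf <- function(path, subject_id = NULL, visit = 0L) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nchar) trimws(rawToChar(readBin(con, "raw", nchar)))
  version <- rd(8)
  patient <- rd(80)
  rd(80)          # recording id
  rd(8); rd(8)    # start date, time
  rd(8)           # header bytes
  rd(44)          # reserved
  n_records <- as.integer(rd(8))
  record_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) abort("Malformed EDF header.")
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)  # transducer
  for (i in seq_len(ns)) rd(8)   # physical dimension
  pmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  pmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  for (i in seq_len(ns)) rd(80)  # prefiltering
  nsamp <- vapply(seq_len(ns), function(i) as.integer(rd(8)), integer(1))
  for (i in seq_len(ns)) rd(32)  # reserved
  if (length(unique(nsamp)) != 1) {
    abort("EDF signals with mixed sampling rates are not supported.")
  }
  gain <- (pmax_ - pmin_) / (dmax_ - dmin_)
  offset <- pmin_ - gain * dmin_
  data <- matrix(0, nrow = ns, ncol = n_records * nsamp[1])
  for (r in seq_len(n_records)) {
    for (s in seq_len(ns)) {
      dig <- readBin(con, "integer", n = nsamp[s], size = 2,
                     signed = TRUE, endian = "little")
      idx <- ((r - 1) * nsamp[s] + 1):(r * nsamp[s])
      data[s, idx] <- dig * gain[s] + offset[s]
    }
  }
  fs <- nsamp[1] / record_dur
  eeg_recording(data, sampling_rate = fs, channels = labels,
                subject_id = subject_id %||%
                  (if (nzchar(patient)) patient else "s1"),
                visit = visit)
}

#' Write a recording as 16-bit EDF
#'
#' Counterpart of [read_edf()] for round-trips and for exporting synthetic
#' recordings. Data are scaled into the signed 16-bit range per channel.
#'
#' @param rec An `eeg_recording` whose duration is an integer number of
#'   seconds (padded with zeros otherwise).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  fs <- rec$sampling_rate
  if (fs != round(fs)) abort("EDF export requires an integer sampling rate.")
  ns <- length(rec$channels)
  n_rec <- ceiling(ncol(rec$data) / fs)
  data <- rec$data
  if (ncol(data) < n_rec * fs) {
    data <- cbind(data, matrix(0, nrow = ns, ncol = n_rec * fs - ncol(data)))
  }
  pmax_ <- apply(abs(data), 1, max)
  pmax_ <- ifelse(pmax_ == 0, 1, pmax_ * 1.0001)
  dig <- round(sweep(data, 1, pmax_ / 32767, "/"))
  con <- file(path, "wb")
  on.exit(close(con))
  wf <- function(x, n) {
    s <- formatC(as.character(x), width = n, flag = "-")
    writeBin(charToRaw(substr(s, 1, n)), con)
  }
  wf("0", 8); wf(rec$subject_id, 80); wf("synthetic", 80)
  wf("01.01.26", 8); wf("00.00.00", 8)
  wf(256 + ns * 256, 8); wf("", 44); wf(n_rec, 8); wf("1", 8); wf(ns, 4)
  for (ch in rec$channels) wf(ch, 16)
  for (i in seq_len(ns)) wf("", 80)
  for (i in seq_len(ns)) wf("uV", 8)
  for (i in seq_len(ns)) wf(sprintf("%.2f", -pmax_[i]), 8)
  for (i in seq_len(ns)) wf(sprintf("%.2f", pmax_[i]), 8)
  for (i in seq_len(ns)) wf(-32767, 8)
  for (i in seq_len(ns)) wf(32767, 8)
  for (i in seq_len(ns)) wf("", 80)
  for (i in seq_len(ns)) wf(fs, 8)
  for (i in seq_len(ns)) wf("", 32)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (s in seq_len(ns)) {
      writeBin(as.integer(dig[s, idx]), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}
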