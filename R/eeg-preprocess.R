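#' Filter a recording (high-pass and power-line notch)
#'
#' Zero-phase filtering: a 4th-order Butterworth high-pass (slow drifts)
#' and a 2nd-order IIR notch at the power-line frequency, both applied
#' forward-backward with [signal::filtfilt()]. The filter designs are
#' recorded in the recording's provenance.
#'
#' @param rec An [eeg_recording()].
#' @param hp_hz High-pass cutoff in Hz (default 0.5).
#' @param notch_hz Notch center frequency in Hz (default 60); must lie
#'   below the Nyquist frequency.
#' @param hp_order Butterworth order (default 4).
#' @param notch_q Notch quality factor (default 30).
#' @return The filtered recording.
#' @export
preprocess_eeg <- function(rec, hp_hz = 0.5, notch_hz = 60, hp_order = 4,
                           notch_q = 30) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$sampling_rate
  if (hp_hz <= 0) abort("`hp_hz` must be positive.")
  if (notch_hz >= fs / 2) {
    abort(sprintf(
      "Sampling rate %g Hz is too low for a %g Hz notch (Nyquist %g Hz).",
      fs, notch_hz, fs / 2))
  }
  hp <- signal::butter(hp_order, hp_hz / (fs / 2), type = "high")
  # RBJ biquad notch
  w0 <- 2 * pi * notch_hz / fs
  alpha <- sin(w0) / (2 * notch_q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  out <- rec
  for (chunk in recording_chunks(rec)) {
    seg <- rec$data[, chunk, drop = FALSE]
    for (i in seq_len(nrow(seg))) {
      x <- signal::filtfilt(hp, seg[i, ])
      seg[i, ] <- signal::filtfilt(signal::Arma(b = b, a = a), x)
    }
    out$data[, chunk] <- seg
  }
  out$provenance <- c(rec$provenance, list(filter = list(
    highpass = list(type = "butterworth", order = hp_order, cutoff_hz = hp_hz,
                    zero_phase = TRUE),
    notch = list(type = "iir-biquad", q = notch_q, center_hz = notch_hz,
                 zero_phase = TRUE),
    cleaning_assumed = TRUE
  )))
  out
}

#' Extract the eyes-closed segments of a recording
#'
#' Concatenates the samples labelled eyes-closed. The starts of the
#' retained runs become segment boundaries so that downstream spectral
#' windows never span a discontinuity. Without segment labels the recording
#' is returned unchanged with a warning.
#'
#' @param rec An [eeg_recording()] with `segment_labels`.
#' @return The reduced recording; its retained duration is recorded in
#'   provenance.
#' @export
select_eyes_closed <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (is.null(rec$segment_labels)) {
    warn("No segment labels; returning the recording unchanged.")
    return(rec)
  }
  keep <- which(rec$segment_labels)
  if (length(keep) == 0) {
    abort(paste0("Subject ", rec$subject_id,
                 ": no eyes-closed samples to extract."))
  }
  run_starts <- cumsum(c(1L, head(rle_lengths_of_runs(keep), -1)))
  out <- rec
  out$data <- rec$data[, keep, drop = FALSE]
  out$segment_labels <- NULL
  out$boundaries <- run_starts
  out$provenance <- c(rec$provenance, list(eyes_closed = list(
    retained_s = length(keep) / rec$sampling_rate,
    n_segments = length(run_starts)
  )))
  out
}

# lengths of the contiguous runs within a sorted index vector
rle_lengths_of_runs <- function(keep) {
  if (length(keep) == 0) return(integer(0))
  brk <- c(TRUE, diff(keep) > 1L)
  as.integer(table(cumsum(brk)))
}
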