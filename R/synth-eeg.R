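#' Synthesize a raw EEG recording with target band powers
#'
#' Per channel, sums band-limited Gaussian noise components: white noise is
#' brick-wall filtered in the frequency domain to each band and scaled so
#' its variance (hence integrated PSD) matches the requested band power.
#' Eyes-closed labels cover the whole recording. Used as the round-trip
#' oracle for the spectral feature path.
#'
#' @param target_powers Named numeric vector (one target per band, in
#'   microvolt squared) or a channels x bands matrix / data frame whose
#'   column names are band names.
#' @param duration_s Recording length in seconds.
#' @param fs Sampling rate in Hz (>= 100).
#' @param bands Band definition tibble; bands must not overlap.
#' @param channels Channel names (default `ch1..chN` for matrix input, a
#'   single `"Cz"` for vector input).
#' @param seed Optional seed.
#' @return An [eeg_recording()] with all-samples eyes-closed labels.
#' @export
simulate_raw_eeg <- function(target_powers, duration_s, fs = 400,
                             bands = eeg_bands(), channels = NULL,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (fs < 100) abort("`fs` must be at least 100 Hz.")
  o <- order(bands$lo)
  if (any(bands$lo[o][-1] < bands$hi[o][-nrow(bands)])) {
    abort("Band definitions overlap.")
  }
  if (is.null(dim(target_powers))) {
    target_powers <- matrix(target_powers, nrow = 1,
                            dimnames = list(NULL, names(target_powers)))
    channels <- channels %||% "Cz"
  } else {
    target_powers <- as.matrix(target_powers)
    channels <- channels %||% paste0("ch", seq_len(nrow(target_powers)))
  }
  if (any(target_powers < 0)) abort("Target band powers must be nonnegative.")
  if (!all(colnames(target_powers) %in% bands$band)) {
    abort("Column names of `target_powers` must be band names.")
  }
  n <- round(duration_s * fs)
  freq <- (seq_len(n) - 1) * fs / n
  freq_folded <- pmin(freq, fs - freq)
  data <- matrix(0, nrow = nrow(target_powers), ncol = n)
  for (i in seq_len(nrow(target_powers))) {
    sig <- numeric(n)
    for (b in colnames(target_powers)) {
      tp <- target_powers[i, b]
      if (tp <= 0) next
      lo <- bands$lo[bands$band == b]
      hi <- bands$hi[bands$band == b]
      x <- rnorm(n)
      X <- fft(x)
      X[!(freq_folded >= lo & freq_folded <= hi)] <- 0
      comp <- Re(fft(X, inverse = TRUE)) / n
      v <- var(comp)
      if (v > 0) sig <- sig + comp * sqrt(tp / v)
    }
    data[i, ] <- sig
  }
  eeg_recording(data, sampling_rate = fs, channels = channels,
                segment_labels = rep(TRUE, n))
}
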