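#' Frequency band definitions
#'
#' The standard clinical bands: delta 0.5-3.5 Hz, theta 4-8 Hz, alpha
#' 8-13 Hz, beta 13-30 Hz.
#'
#' @param names Subset of bands to return.
#' @return A tibble with `band`, `lo`, `hi` (Hz).
#' @export
eeg_bands <- function(names = c("delta", "theta", "alpha", "beta")) {
  all <- tibble::tibble(
    band = c("delta", "theta", "alpha", "beta"),
    lo = c(0.5, 4, 8, 13),
    hi = c(3.5, 8, 13, 30)
  )
  out <- all[all$band %in% names, , drop = FALSE]
  if (nrow(out) == 0) abort("Unknown band names.")
  out
}

# Welch averaged periodogram of one signal chunk set.
# chunks: list of numeric vectors; returns list(freq, psd) with psd in
# units^2/Hz (one-sided density).
welch_psd <- function(chunks, fs, window_s = 2, overlap = 0.5) {
  nwin <- round(window_s * fs)
  w <- signal::hamming(nwin)
  U <- sum(w^2)
  step <- max(1L, round(nwin * (1 - overlap)))
  acc <- NULL
  nseg <- 0L
  for (x in chunks) {
    n <- length(x)
    if (n < nwin) next
    starts <- seq(1L, n - nwin + 1L, by = step)
    for (s0 in starts) {
      seg <- x[s0:(s0 + nwin - 1L)]
      seg <- (seg - mean(seg)) * w
      p <- abs(fft(seg))^2
      if (is.null(acc)) acc <- numeric(length(p))
      acc <- acc + p
      nseg <- nseg + 1L
    }
  }
  if (nseg == 0L) abort("Recording too short for the requested Welch window.")
  half <- floor(nwin / 2) + 1L
  psd <- acc[seq_len(half)] / (nseg * fs * U)
  # one-sided: double everything except DC (and Nyquist when nwin even)
  dbl <- rep(2, half)
  dbl[1] <- 1
  if (nwin %% 2 == 0) dbl[half] <- 1
  list(freq = (seq_len(half) - 1L) * fs / nwin, psd = psd * dbl,
       n_segments = nseg)
}

# trapezoid integral of psd over bins whose centers lie in [lo, hi]
integrate_band <- function(freq, psd, lo, hi) {
  sel <- which(freq >= lo & freq <= hi)
  if (length(sel) < 2) {
    abort(sprintf("Band %g-%g Hz is not resolvable at this spectral resolution.",
                  lo, hi))
  }
  f <- freq[sel]; p <- psd[sel]
  sum(diff(f) * (head(p, -1) + tail(p, -1)) / 2)
}

#' Per-channel spectral band power
#'
#' Estimates the power spectral density with Welch's averaged periodogram
#' (Hamming windows, mean-removed segments, configurable overlap; windows
#' never span a segment-concatenation boundary) and integrates it by
#' trapezoid over the frequency bins falling inside each band.
#'
#' @param rec An [eeg_recording()].
#' @param bands A band tibble as from [eeg_bands()].
#' @param window_s Welch window length in seconds (default 2, resolving the
#'   0.5 Hz delta edge).
#' @param overlap Fractional window overlap (default 0.5).
#' @return A tibble `channel`, `band`, `power` (microvolt squared).
#' @examples
#' t <- seq(0, 30, by = 1 / 200)[-1]
#' rec <- eeg_recording(matrix(2 * sin(2 * pi * 10 * t), nrow = 1),
#'                      sampling_rate = 200, channels = "O1")
#' band_power(rec)  # alpha close to 2^2 / 2
#' @export
band_power <- function(rec, bands = eeg_bands(), window_s = 2,
                       overlap = 0.5) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$sampling_rate
  if (ncol(rec$data) < 2 * window_s * fs) {
    abort("Recording must last at least twice the Welch window.")
  }
  if (any(bands$hi > fs / 2)) {
    abort("A requested band exceeds the Nyquist frequency.")
  }
  chunks_idx <- recording_chunks(rec)
  purrr::map_dfr(seq_along(rec$channels), function(i) {
    chunks <- lapply(chunks_idx, function(idx) rec$data[i, idx])
    sp <- welch_psd(chunks, fs, window_s, overlap)
    tibble::tibble(
      channel = rec$channels[i],
      band = bands$band,
      power = vapply(seq_len(nrow(bands)), function(b) {
        integrate_band(sp$freq, sp$psd, bands$lo[b], bands$hi[b])
      }, numeric(1))
    )
  })
}

#' Default channel-to-region map for a 58-channel 10-10 montage
#'
#' Ships the package's default mapping of 10-10 electrode names onto the
#' eight cortical regions of interest (medial/lateral frontal,
#' medial/lateral central, medial/lateral parietal, occipital, temporal).
#' The mapping is an explicit, auditable input: pass your own tibble or TSV
#' wherever the montage differs.
#'
#' @return A tibble with `channel` and `roi`.
#' @export
default_roi_map <- function() {
  path <- system.file("extdata", "roi_map_1010.tsv", package = "eegsustain")
  read_roi_map(path)
}

#' Read a channel-to-region map from TSV
#'
#' @param path TSV file with columns `channel` and `roi`.
#' @return A tibble with `channel` and `roi`.
#' @export
read_roi_map <- function(path) {
  m <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("channel", "roi") %in% colnames(m))) {
    abort("ROI map must have `channel` and `roi` columns.")
  }
  m
}

#' Build the regional band-power feature table
#'
#' Computes per-channel band power for each recording, averages channels
#' within each region of interest (unweighted mean, case-insensitive
#' channel matching), and joins subject demographics. Channels absent from
#' the map are ignored with a warning; a region with no available channels
#' yields `NA` and flags the subject.
#'
#' @param recs A list of [eeg_recording()] objects.
#' @param roi_map Tibble `channel`, `roi` (see [default_roi_map()]).
#' @param bands Bands to extract (default all four; delta/theta/beta are
#'   modelled downstream, alpha is tabulated only).
#' @param demographics Tibble with `subject_id`, `age`, `sex`, `group`, and
#'   optionally `years` (follow-up interval per visit).
#' @inheritParams band_power
#' @return A feature-table tibble: `subject_id`, `visit`, `age`, `sex`,
#'   `group`, `years`, then `<band>_<roi>` columns in fixed band-major
#'   order. Subjects with missing regions are listed in the
#'   `incomplete_subjects` attribute.
#' @export
build_feature_table <- function(recs, roi_map = default_roi_map(),
                                bands = eeg_bands(), demographics,
                                window_s = 2, overlap = 0.5) {
  if (inherits(recs, "eeg_recording")) recs <- list(recs)
  roi_map$channel_lc <- tolower(roi_map$channel)
  rois <- unique(roi_map$roi)
  miss_dem <- setdiff(vapply(recs, `[[`, character(1), "subject_id"),
                      demographics$subject_id)
  if (length(miss_dem) > 0) {
    abort(paste0("Missing demographics for: ",
                 paste(head(miss_dem, 5), collapse = ", ")))
  }
  feature_order <- as.vector(outer(bands$band, rois, paste, sep = "_"))
  flagged <- character(0)
  rows <- purrr::map_dfr(recs, function(rec) {
    bp <- band_power(rec, bands, window_s, overlap)
    bp$roi <- roi_map$roi[match(tolower(bp$channel), roi_map$channel_lc)]
    unmapped <- unique(bp$channel[is.na(bp$roi)])
    if (length(unmapped) > 0) {
      warn(paste0(rec$subject_id, ": ignoring unmapped channel(s) ",
                  paste(unmapped, collapse = ", ")))
    }
    agg <- bp |>
      dplyr::filter(!is.na(.data$roi)) |>
      dplyr::group_by(.data$band, .data$roi) |>
      dplyr::summarise(power = mean(.data$power), .groups = "drop")
    agg <- tidyr::complete(agg, band = bands$band, roi = rois)
    if (anyNA(agg$power)) flagged <<- c(flagged, rec$subject_id)
    wide <- setNames(agg$power, paste(agg$band, agg$roi, sep = "_"))
    dplyr::bind_cols(
      tibble::tibble(subject_id = rec$subject_id, visit = rec$visit),
      tibble::as_tibble(as.list(wide[feature_order]))
    )
  })
  dem_cols <- intersect(c("subject_id", "visit", "age", "sex", "group",
                          "years"), colnames(demographics))
  by <- intersect(c("subject_id", "visit"), dem_cols)
  out <- dplyr::left_join(rows, demographics[, dem_cols, drop = FALSE],
                          by = by)
  if (!"years" %in% colnames(out)) out$years <- 0
  if (!"group" %in% colnames(out)) out$group <- "unknown"
  out <- dplyr::relocate(out, "subject_id", "visit", "age", "sex", "group",
                         "years")
  attr(out, "incomplete_subjects") <- unique(flagged)
  out
}
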