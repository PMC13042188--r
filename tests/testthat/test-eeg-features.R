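test_that("high-pass removes DC offset and the notch attenuates 60 Hz", {
  fs <- 400
  n <- 20 * fs
  rec <- eeg_recording(matrix(50, nrow = 1, ncol = n), fs, channels = "Cz")
  out <- preprocess_eeg(rec)
  expect_lt(abs(mean(out$data)), 0.5)

  t <- seq_len(n) / fs
  line <- eeg_recording(matrix(20 * sin(2 * pi * 60 * t), nrow = 1), fs,
                        channels = "Cz")
  filt <- preprocess_eeg(line)
  p60 <- function(x) {
    sp <- eegsustain:::welch_psd(list(as.numeric(x)), fs, window_s = 2)
    eegsustain:::integrate_band(sp$freq, sp$psd, 58, 62)
  }
  atten_db <- 10 * log10(p60(line$data[1, ]) / p60(filt$data[1, ]))
  expect_gte(atten_db, 20)
})

test_that("preprocessing preserves the analysis passband on white noise", {
  fs <- 400
  set.seed(42)
  x <- rnorm(60 * fs)
  rec <- eeg_recording(matrix(x, nrow = 1), fs, channels = "Cz")
  out <- preprocess_eeg(rec)
  for (b in seq_len(4)) {
    bands <- eeg_bands()
    before <- band_power(rec, bands[b, ])$power
    after <- band_power(out, bands[b, ])$power
    expect_lt(abs(after - before) / before, 0.10)
  }
})

test_that("notch below Nyquist is enforced", {
  rec <- eeg_recording(matrix(rnorm(1000), nrow = 1), 100, channels = "Cz")
  expect_error(preprocess_eeg(rec, notch_hz = 60), "too low")
})

test_that("eyes-closed selection keeps labelled samples only", {
  fs <- 100
  n <- 5 * 60 * fs
  labels <- rep(rep(c(FALSE, TRUE), each = 30 * fs), length.out = n)
  rec <- eeg_recording(matrix(rnorm(n), nrow = 1), fs, channels = "Cz",
                       segment_labels = labels)
  out <- select_eyes_closed(rec)
  expect_equal(ncol(out$data) / fs, 150)  # half of five minutes
  expect_equal(length(out$boundaries), 5)

  all_ec <- eeg_recording(matrix(rnorm(1000), nrow = 1), fs,
                          channels = "Cz",
                          segment_labels = rep(TRUE, 1000))
  kept <- select_eyes_closed(all_ec)
  expect_identical(kept$data, all_ec$data)

  all_eo <- eeg_recording(matrix(rnorm(1000), nrow = 1), fs,
                          channels = "Cz",
                          segment_labels = rep(FALSE, 1000))
  expect_error(select_eyes_closed(all_eo), "no eyes-closed")

  unlabelled <- eeg_recording(matrix(rnorm(1000), nrow = 1), fs,
                              channels = "Cz")
  expect_warning(select_eyes_closed(unlabelled), "No segment labels")
})

test_that("band power recovers sinusoid power A^2/2 and is additive", {
  fs <- 400
  t <- seq_len(120 * fs) / fs
  A <- 3
  rec <- eeg_recording(matrix(A * sin(2 * pi * 10 * t), nrow = 1), fs,
                       channels = "O1")
  bp <- band_power(rec)
  alpha <- bp$power[bp$band == "alpha"]
  expect_lt(abs(alpha - A^2 / 2) / (A^2 / 2), 0.05)

  zero <- eeg_recording(matrix(0, nrow = 1, ncol = 10 * fs), fs,
                        channels = "Cz")
  expect_true(all(band_power(zero)$power == 0))

  two <- eeg_recording(
    matrix(2 * sin(2 * pi * 2 * t) + 1.5 * sin(2 * pi * 20 * t), nrow = 1),
    fs, channels = "Cz")
  bp2 <- band_power(two)
  expect_lt(abs(bp2$power[bp2$band == "delta"] - 2) / 2, 0.05)
  expect_lt(abs(bp2$power[bp2$band == "beta"] - 1.5^2 / 2) / (1.5^2 / 2),
            0.05)
  expect_lt(bp2$power[bp2$band == "theta"], 0.05)
})

test_that("band power scales quadratically and ignores channel order", {
  fs <- 200
  set.seed(7)
  x <- matrix(rnorm(2 * 30 * fs), nrow = 2)
  rec <- eeg_recording(x, fs, channels = c("C3", "C4"))
  rec3 <- eeg_recording(3 * x, fs, channels = c("C3", "C4"))
  bp <- band_power(rec)
  bp3 <- band_power(rec3)
  expect_equal(bp3$power, 9 * bp$power, tolerance = 1e-12)

  swapped <- eeg_recording(x[2:1, ], fs, channels = c("C4", "C3"))
  bps <- band_power(swapped)
  expect_equal(bps$power[bps$channel == "C3"],
               bp$power[bp$channel == "C3"], tolerance = 1e-12)
})

test_that("summed band powers stay below band-limited signal variance", {
  fs <- 400
  set.seed(11)
  rec <- eeg_recording(matrix(rnorm(60 * fs, sd = 5), nrow = 1), fs,
                       channels = "Cz")
  filt <- preprocess_eeg(rec)
  bp <- band_power(filt)
  # total variance of the 0.5-30 Hz content bounds the band sum
  sp <- eegsustain:::welch_psd(list(filt$data[1, ]), fs, 2)
  total <- eegsustain:::integrate_band(sp$freq, sp$psd, 0.5, 30)
  expect_lte(sum(bp$power), total * 1.10)
})

test_that("feature table averages channels within regions", {
  fs <- 200
  set.seed(3)
  # two channels built to known variances via scaled copies of one noise
  base <- rnorm(40 * fs)
  rec <- eeg_recording(rbind(2 * base, base, rnorm(40 * fs)), fs,
                       channels = c("O1", "O2", "F3"))
  roi_map <- tibble::tibble(channel = c("O1", "O2", "F3"),
                            roi = c("occipital", "occipital", "mfrontal"))
  dem <- tibble::tibble(subject_id = "s1", age = 60, sex = 1, group = "HC")
  ft <- build_feature_table(list(rec), roi_map, eeg_bands(), dem)
  bp <- band_power(rec)
  occ_alpha <- mean(bp$power[bp$band == "alpha" & bp$channel %in%
                               c("O1", "O2")])
  expect_equal(ft$alpha_occipital, occ_alpha, tolerance = 1e-12)
  # single-channel region equals that channel
  expect_equal(ft$delta_mfrontal,
               bp$power[bp$band == "delta" & bp$channel == "F3"],
               tolerance = 1e-12)
})

test_that("feature table flags unmapped channels and missing demographics", {
  fs <- 200
  rec <- eeg_recording(matrix(rnorm(2 * 20 * fs), nrow = 2), fs,
                       channels = c("O1", "XX"))
  roi_map <- tibble::tibble(channel = "O1", roi = "occipital")
  dem <- tibble::tibble(subject_id = "s1", age = 60, sex = 1, group = "HC")
  expect_warning(build_feature_table(list(rec), roi_map, eeg_bands(), dem),
                 "unmapped")
  expect_error(
    suppressWarnings(build_feature_table(
      list(rec), roi_map, eeg_bands(),
      tibble::tibble(subject_id = "other", age = 1, sex = 0, group = "HC"))),
    "Missing demographics")
})

test_that("EDF files round-trip through the reader and writer", {
  fs <- 200
  set.seed(9)
  rec <- eeg_recording(matrix(rnorm(3 * 10 * fs, sd = 40), nrow = 3), fs,
                       channels = c("Fp1", "Cz", "O2"), subject_id = "edf01")
  path <- tempfile(fileext = ".edf")
  write_edf(rec, path)
  back <- read_edf(path)
  expect_equal(back$channels, rec$channels)
  expect_equal(back$sampling_rate, fs)
  # 16-bit quantization: relative error bounded by the digitization step
  expect_lt(max(abs(back$data - rec$data)), max(abs(rec$data)) / 32000 * 2)
  unlink(path)
})

test_that("plain TSV recordings load with matching channel header", {
  fs <- 100
  m <- matrix(rnorm(2 * 3 * fs), nrow = 2)
  mp <- tempfile(fileext = ".tsv")
  readr::write_tsv(as.data.frame(t(m)), mp, col_names = FALSE)
  writeLines(c("C3", "C4"), paste0(mp, ".channels"))
  rec <- read_raw_tsv(mp, sampling_rate = fs)
  expect_equal(rec$channels, c("C3", "C4"))
  expect_equal(dim(rec$data), c(2L, 3L * fs))
  expect_equal(unname(rec$data), unname(m), tolerance = 1e-9)
  unlink(c(mp, paste0(mp, ".channels")))
})

test_that("default ROI map covers eight regions with 58 channels", {
  m <- default_roi_map()
  expect_equal(nrow(m), 58)
  expect_equal(length(unique(m$roi)), 8)
})
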