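#' @title Control-referenced harmonization of spectral features
#' @description Turns raw regional band-power features into the monotone,
#'   healthy-control-referenced z-score matrix the progression model
#'   consumes. The convention is the W-score: each feature is regressed on
#'   age and sex over healthy-control baseline rows, and every row is then
#'   expressed as (observed - predicted) / residual SD. Features whose
#'   disease cohort sits below the control reference are sign-inverted so
#'   that abnormality is always a positive deviation.
#' @name harmonize
NULL

# feature columns follow the `<band>_<roi>` convention
feature_columns <- function(features, bands = NULL) {
  cols <- colnames(features)
  fc <- cols[grepl("^(delta|theta|alpha|beta)_", cols)]
  if (!is.null(bands)) {
    fc <- fc[sub("_.*$", "", fc) %in% bands]
  }
  fc
}

baseline_rows <- function(features) {
  features[features$visit == min(features$visit), , drop = FALSE]
}

#' Fit harmonization parameters on healthy controls
#'
#' Per modelled feature, fits `power ~ age + sex` by least squares over
#' healthy-control baseline rows and stores the coefficients, the residual
#' SD (denominator n - 3), and the sign-inversion flag chosen by
#' [decide_inversion()]. The alpha band is excluded from the modelled set
#' (it is kept in the feature table for spectral comparisons only).
#'
#' @param features A feature table: one row per subject-visit with columns
#'   `subject_id`, `visit`, `age`, `sex` (0 = female, 1 = male), `group`
#'   (`"HC"`, `"disease-nonconverter"`, `"disease-converter"`, or
#'   `"unknown"`), and `<band>_<roi>` power columns.
#' @param modelled_bands Bands entering the model (default delta, theta,
#'   beta).
#' @param hc_floor Minimum number of healthy-control baseline subjects
#'   required for a stable fit (default 10).
#' @return An object of class `harmonization_params`: a tibble with one row
#'   per modelled feature (`feature`, `intercept`, `age_slope`,
#'   `sex_offset`, `resid_sd`, `inversion`, `disease_mean_z`) plus metadata
#'   attributes (`n_hc`, `modelled_features`).
#' @examples
#' study <- simulate_study(sim_config(n_hc = 60, n_disease = 80, seed = 4))
#' pars <- fit_harmonization(study$features)
#' head(tidy(pars))
#' @export
fit_harmonization <- function(features,
                              modelled_bands = c("delta", "theta", "beta"),
                              hc_floor = 10) {
  fc <- feature_columns(features, modelled_bands)
  if (length(fc) == 0) abort("No `<band>_<roi>` feature columns found.")
  hc <- baseline_rows(features)
  hc <- hc[hc$group == "HC" & !is.na(hc$age) & !is.na(hc$sex), , drop = FALSE]
  if (nrow(hc) < max(2, hc_floor)) {
    abort(sprintf(
      "Harmonization needs at least %d healthy-control baseline rows (found %d).",
      max(2, hc_floor), nrow(hc)))
  }
  if (length(unique(hc$age)) == 1 && length(unique(hc$sex)) == 1) {
    abort("Degenerate design: all healthy controls share age and sex.")
  }
  X <- cbind(1, hc$age, as.numeric(hc$sex))
  qrX <- qr(X)
  if (qrX$rank < 3) {
    abort("Degenerate healthy-control design (age/sex not estimable).")
  }
  n <- nrow(hc)
  fits <- purrr::map_dfr(fc, function(f) {
    y <- hc[[f]]
    beta <- qr.coef(qrX, y)
    res <- y - X %*% beta
    tibble::tibble(
      feature = f,
      intercept = beta[1], age_slope = beta[2], sex_offset = beta[3],
      resid_sd = sqrt(sum(res^2) / (n - 3))
    )
  })
  if (any(fits$resid_sd <= 0)) {
    abort("Zero residual SD for at least one feature; controls are degenerate.")
  }
  params <- structure(fits,
                      n_hc = n,
                      modelled_features = fc,
                      class = c("harmonization_params", class(fits)))
  inv <- decide_inversion(features, params)
  params$inversion <- inv$inversion
  params$disease_mean_z <- inv$disease_mean_z
  params
}

#' Decide per-feature sign inversion
#'
#' For each modelled feature, computes the mean age/sex-adjusted z-score
#' over all baseline disease rows (converters and non-converters pooled;
#' outcomes never enter the rule). Features with a negative pooled mean are
#' flagged for inversion (`-1`); an exact zero keeps `+1`.
#'
#' @inheritParams fit_harmonization
#' @param params A [fit_harmonization()] object (inversion flags may be
#'   absent; only the regression parameters are used).
#' @return A tibble with `feature`, `disease_mean_z` and `inversion`.
#' @export
decide_inversion <- function(features, params) {
  dis <- baseline_rows(features)
  dis <- dis[dis$group %in% c("disease-nonconverter", "disease-converter"),
             , drop = FALSE]
  if (nrow(dis) == 0) {
    abort("No baseline disease rows available to set inversion flags.")
  }
  dis <- dis[!is.na(dis$age) & !is.na(dis$sex), , drop = FALSE]
  purrr::map_dfr(seq_len(nrow(params)), function(i) {
    p <- params[i, ]
    pred <- p$intercept + p$age_slope * dis$age +
      p$sex_offset * as.numeric(dis$sex)
    mz <- mean((dis[[p$feature]] - pred) / p$resid_sd)
    tibble::tibble(feature = p$feature, disease_mean_z = mz,
                   inversion = ifelse(mz < 0, -1, 1))
  })
}

#' Apply harmonization to a feature table
#'
#' Computes `z = inversion * (x - predicted(age, sex)) / resid_sd` for every
#' modelled feature, using the frozen baseline-fitted parameters for any
#' visit (follow-up visits are referenced to the same healthy-control
#' model). Rows with missing age or sex are dropped with a warning.
#'
#' @inheritParams fit_harmonization
#' @param params A fitted [fit_harmonization()] object with inversion flags.
#' @return A `z_matrix` tibble: `subject_id`, `visit`, `group`, `years`
#'   (follow-up interval when present), and one z-score column per modelled
#'   feature.
#' @export
harmonize_features <- function(features, params) {
  if (inherits(features, "z_matrix")) {
    abort("Input is already a z-matrix; refusing to harmonize twice.")
  }
  if (!inherits(params, "harmonization_params") ||
      is.null(params$inversion)) {
    abort("`params` must be a fitted harmonization_params object with inversion flags.")
  }
  ok <- !is.na(features$age) & !is.na(features$sex)
  if (any(!ok)) {
    warn(sprintf("Dropping %d row(s) with missing age or sex.", sum(!ok)))
    features <- features[ok, , drop = FALSE]
  }
  z <- features[, intersect(c("subject_id", "visit", "group", "years"),
                            colnames(features)), drop = FALSE]
  for (i in seq_len(nrow(params))) {
    p <- params[i, ]
    pred <- p$intercept + p$age_slope * features$age +
      p$sex_offset * as.numeric(features$sex)
    z[[p$feature]] <- p$inversion *
      (features[[p$feature]] - pred) / p$resid_sd
  }
  z <- tibble::as_tibble(z)
  attr(z, "modelled_features") <- params$feature
  attr(z, "n_hc") <- attr(params, "n_hc")
  class(z) <- c("z_matrix", class(z))
  z
}

# modelled feature names of a z-matrix (or any data frame of z columns)
modelled_features <- function(z) {
  mf <- attr(z, "modelled_features")
  if (!is.null(mf)) return(mf)
  if (is.data.frame(z)) {
    fc <- feature_columns(z, c("delta", "theta", "beta"))
    if (length(fc) > 0) return(fc)
    return(setdiff(colnames(z), c("subject_id", "visit", "group", "years")))
  }
  if (!is.null(colnames(z))) return(colnames(z))
  abort("Cannot infer modelled features; supply an event_config.")
}

#' Coerce a data frame of z-scores to a z-matrix
#'
#' @param z A data frame with optional id columns and one numeric column per
#'   modelled feature.
#' @param features Character vector naming the modelled feature columns; by
#'   default every column other than `subject_id`, `visit`, `group`,
#'   `years`.
#' @return A `z_matrix` tibble.
#' @export
as_z_matrix <- function(z, features = NULL) {
  z <- tibble::as_tibble(z)
  if (is.null(features)) {
    features <- setdiff(colnames(z),
                        c("subject_id", "visit", "group", "years"))
  }
  attr(z, "modelled_features") <- features
  if (!inherits(z, "z_matrix")) class(z) <- c("z_matrix", class(z))
  z
}
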