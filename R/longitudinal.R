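#' Pair baseline and follow-up placements
#'
#' Joins each subject's baseline placement with one follow-up placement
#' from the same frozen model and harmonization. Subjects with several
#' follow-ups contribute their earliest by default.
#'
#' @param baseline,followup Placement tibbles (see [sustain_place()]) with
#'   `subject_id`, `subtype`, `stage`, and a `years` column on the
#'   follow-up side (interval since baseline, in years). `followup` may be
#'   omitted when `baseline` already holds both visits (`years == 0` marks
#'   baseline rows).
#' @param which_followup `"earliest"` (default) or `"latest"`.
#' @param meta Optional tibble `subject_id`, `years` supplying intervals
#'   when the follow-up placement lacks them.
#' @return A `visit_pairs` tibble: `subject_id`, `subtype_bl`, `stage_bl`,
#'   `subtype_fu`, `stage_fu`, `dt_years`, plus any `group` column carried
#'   from baseline.
#' @export
pair_visits <- function(baseline, followup = NULL,
                        which_followup = c("earliest", "latest"),
                        meta = NULL) {
  which_followup <- match.arg(which_followup)
  if (is.null(followup)) {
    if (!"years" %in% colnames(baseline)) {
      abort("Single-table input needs a `years` column to split visits.")
    }
    followup <- baseline[baseline$years > 0, , drop = FALSE]
    baseline <- baseline[baseline$years == 0, , drop = FALSE]
  }
  if (!is.null(meta)) {
    followup <- dplyr::left_join(
      dplyr::select(followup, -dplyr::any_of("years")),
      meta[, c("subject_id", "years")], by = "subject_id")
  }
  if (!"years" %in% colnames(followup)) {
    abort("Follow-up placements need a `years` interval column.")
  }
  bad <- followup$years <= 0
  if (any(bad)) {
    abort(paste0("Non-positive follow-up interval for subject(s): ",
                 paste(unique(followup$subject_id[bad]), collapse = ", ")))
  }
  fu <- followup |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::arrange(.data$years, .by_group = TRUE) |>
    dplyr::slice(if (which_followup == "earliest") 1L else dplyr::n()) |>
    dplyr::ungroup()
  keep_bl <- intersect(c("subject_id", "group", "subtype", "stage"),
                       colnames(baseline))
  out <- dplyr::inner_join(
    dplyr::rename(tibble::as_tibble(baseline)[, keep_bl],
                  subtype_bl = "subtype", stage_bl = "stage"),
    dplyr::rename(tibble::as_tibble(fu)[, c("subject_id", "subtype",
                                            "stage", "years")],
                  subtype_fu = "subtype", stage_fu = "stage",
                  dt_years = "years"),
    by = "subject_id"
  )
  class(out) <- c("visit_pairs", class(out))
  out
}

#' Baseline-to-follow-up subtype transition summary
#'
#' Tallies subtype labels (0..C) at baseline against follow-up, with
#' row-normalized percentages and per-subtype retention rates.
#'
#' @param pairs A [pair_visits()] tibble.
#' @param n_subtypes Number of non-zero subtypes (default: largest label
#'   observed).
#' @return An object of class `transition_summary`: `counts` matrix,
#'   `percent` matrix (rows sum to 100 where occupied), `retention` vector,
#'   `n`.
#' @export
subtype_transitions <- function(pairs, n_subtypes = NULL) {
  if (nrow(pairs) < 1) abort("Need at least one visit pair.")
  if (anyDuplicated(pairs$subject_id) > 0) {
    abort("Duplicate subject in visit pairs.")
  }
  C <- n_subtypes %||% max(pairs$subtype_bl, pairs$subtype_fu)
  labs <- 0:C
  counts <- table(factor(pairs$subtype_bl, levels = labs),
                  factor(pairs$subtype_fu, levels = labs))
  counts <- matrix(as.integer(counts), nrow = length(labs),
                   dimnames = list(baseline = labs, followup = labs))
  rs <- rowSums(counts)
  percent <- counts / ifelse(rs == 0, NA, rs) * 100
  structure(
    list(counts = counts, percent = percent,
         retention = diag(counts) / ifelse(rs == 0, NA, rs),
         n = nrow(pairs)),
    class = "transition_summary"
  )
}

#' @export
print.transition_summary <- function(x, ...) {
  cat("<transition_summary>", x$n, "pairs\ncounts:\n")
  print(x$counts)
  cat("row %:\n")
  print(round(x$percent, 1))
  invisible(x)
}

#' One-sample chi-square test of subtype retention
#'
#' Compares the observed number of subjects retaining their baseline
#' subtype against a binomial expectation under an explicit null retention
#' probability (the null is a modelling choice and must be supplied).
#'
#' @param summary A [subtype_transitions()] object.
#' @param null_p0 Null retention probability, strictly inside (0, 1).
#' @return A tibble with `statistic` (chi-square, 1 df), `df`, `p.value`,
#'   `retained`, `n`.
#' @export
retention_test <- function(summary, null_p0) {
  stopifnot(inherits(summary, "transition_summary"))
  if (!is.numeric(null_p0) || null_p0 <= 0 || null_p0 >= 1) {
    abort("`null_p0` must lie strictly inside (0, 1).")
  }
  n <- summary$n
  if (n == 0) abort("No visit pairs.")
  retained <- sum(diag(summary$counts))
  e1 <- n * null_p0
  e0 <- n * (1 - null_p0)
  stat <- (retained - e1)^2 / e1 + ((n - retained) - e0)^2 / e0
  tibble::tibble(statistic = stat, df = 1L,
                 p.value = pchisq(stat, 1, lower.tail = FALSE),
                 retained = retained, n = n)
}

#' Per-subject stage change and annualized velocity
#'
#' `delta_stage = stage_fu - stage_bl`; velocity `v = delta_stage /
#' dt_years` in stages/year; the high-progression class is `v >= 2`
#' (closed on the boundary).
#'
#' @param pairs A [pair_visits()] tibble.
#' @return A tibble adding `delta_stage`, `velocity`, `velocity_class`
#'   (`"high"` / `"low"`).
#' @export
stage_deltas <- function(pairs) {
  if (any(pairs$dt_years <= 0)) {
    abort(paste0("Non-positive interval for subject(s): ",
                 paste(pairs$subject_id[pairs$dt_years <= 0],
                       collapse = ", ")))
  }
  pairs |>
    dplyr::mutate(
      delta_stage = .data$stage_fu - .data$stage_bl,
      velocity = .data$delta_stage / .data$dt_years,
      velocity_class = ifelse(.data$velocity >= 2, "high", "low")
    )
}

#' Stage-change summaries and tests
#'
#' Mean and SD of the stage change overall, by baseline subtype, and (when
#' a `converted` indicator is present or joinable) by conversion status;
#' a paired t-test of follow-up versus baseline stage and a Welch t-test of
#' converters versus non-converters. Degenerate (zero-variance) tests
#' report `p = 1` with a flag.
#'
#' @param deltas A [stage_deltas()] tibble, optionally with a `converted`
#'   0/1 column.
#' @param outcomes Optional tibble `subject_id`, `converted` to join.
#' @return A list of class `stage_change_summary`: `overall`, `by_subtype`,
#'   `by_conversion`, `paired_test`, `conversion_test`.
#' @export
stage_change_tests <- function(deltas, outcomes = NULL) {
  if (!is.null(outcomes)) {
    deltas <- dplyr::left_join(
      deltas, outcomes[, c("subject_id", "converted")], by = "subject_id")
  }
  overall <- tibble::tibble(
    n = nrow(deltas),
    mean_delta = mean(deltas$delta_stage),
    sd_delta = sd(deltas$delta_stage)
  )
  by_subtype <- deltas |>
    dplyr::group_by(subtype_bl = .data$subtype_bl) |>
    dplyr::summarise(n = dplyr::n(), mean_delta = mean(.data$delta_stage),
                     sd_delta = sd(.data$delta_stage), .groups = "drop")
  paired <- degenerate_safe_t(deltas$delta_stage)
  by_conv <- NULL
  conv_test <- NULL
  if ("converted" %in% colnames(deltas) && !all(is.na(deltas$converted))) {
    by_conv <- deltas |>
      dplyr::filter(!is.na(.data$converted)) |>
      dplyr::group_by(converted = .data$converted) |>
      dplyr::summarise(n = dplyr::n(), mean_delta = mean(.data$delta_stage),
                       sd_delta = sd(.data$delta_stage), .groups = "drop")
    cv <- deltas$delta_stage[deltas$converted == 1 & !is.na(deltas$converted)]
    nc <- deltas$delta_stage[deltas$converted == 0 & !is.na(deltas$converted)]
    if (length(cv) > 1 && length(nc) > 1 &&
        (sd(cv) > 0 || sd(nc) > 0)) {
      tt <- t.test(cv, nc)
      conv_test <- tibble::tibble(statistic = unname(tt$statistic),
                                  p.value = tt$p.value, degenerate = FALSE)
    } else {
      conv_test <- tibble::tibble(statistic = NA_real_, p.value = 1,
                                  degenerate = TRUE)
    }
  }
  structure(list(overall = overall, by_subtype = by_subtype,
                 by_conversion = by_conv, paired_test = paired,
                 conversion_test = conv_test),
            class = "stage_change_summary")
}

degenerate_safe_t <- function(d) {
  if (length(d) < 2 || sd(d) == 0) {
    return(tibble::tibble(statistic = NA_real_, p.value = 1,
                          degenerate = TRUE))
  }
  tt <- t.test(d)
  tibble::tibble(statistic = unname(tt$statistic), p.value = tt$p.value,
                 degenerate = FALSE)
}
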