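#' Positional-variance diagram of a fitted progression model
#'
#' Heatmap of each biomarker event's posterior position distribution
#' (from the thinned MCMC samples), one panel per subtype — the standard
#' way to display event-ordering uncertainty.
#'
#' @param object A [sustain_fit()] model.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.progression_model <- function(object, ...) {
  dat <- purrr::map_dfr(seq_len(object$C), function(c) {
    sm <- object$samples[[c]]
    if (is.null(sm) || nrow(sm) == 0) sm <- matrix(object$sequences[[c]],
                                                   nrow = 1)
    purrr::map_dfr(seq_len(nrow(sm)), function(i) {
      tibble::tibble(subtype = paste("Subtype", c),
                     event_id = sm[i, ],
                     position = seq_len(ncol(sm)))
    })
  })
  ev <- object$cfg$events
  dat$label <- paste0(ev$biomarker[dat$event_id],
                      ifelse(ev$level[dat$event_id] == 1, " (z1)", " (z2)"))
  dat$label <- factor(dat$label, levels = unique(
    paste0(rep(object$cfg$biomarkers, each = 2),
           c(" (z1)", " (z2)"))))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$position, y = .data$label)) +
    ggplot2::stat_bin_2d(binwidth = c(1, 1),
                         ggplot2::aes(fill = ggplot2::after_stat(
                           .data$count / max(.data$count)))) +
    ggplot2::facet_wrap(~subtype) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 name = "P(position)") +
    ggplot2::labs(x = "Stage (event position)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot conversion-free survival curves
#'
#' @param object A [km_fit()] curve tibble.
#' @param conf Draw confidence ribbons (default `TRUE`).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.km_curve <- function(object, conf = TRUE, ...) {
  start <- object |>
    dplyr::distinct(.data$stratum) |>
    dplyr::mutate(time = 0, estimate = 1, conf.low = 1, conf.high = 1)
  dat <- dplyr::bind_rows(start, object) |>
    dplyr::arrange(.data$stratum, .data$time)
  p <- ggplot2::ggplot(dat, ggplot2::aes(.data$time, .data$estimate,
                                         colour = .data$stratum)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Years from baseline EEG",
                  y = "Conversion-free survival", colour = NULL) +
    ggplot2::theme_minimal()
  if (conf) {
    p <- p + ggplot2::geom_step(ggplot2::aes(y = .data$conf.low),
                                linetype = "dotted", na.rm = TRUE) +
      ggplot2::geom_step(ggplot2::aes(y = .data$conf.high),
                         linetype = "dotted", na.rm = TRUE)
  }
  p
}

#' Plot a subtype transition matrix
#'
#' @param x A [subtype_transitions()] summary.
#' @return A ggplot object (tile matrix annotated with row percentages).
#' @export
plot_transitions <- function(x) {
  stopifnot(inherits(x, "transition_summary"))
  dat <- tidy(x)
  ggplot2::ggplot(dat, ggplot2::aes(.data$followup, .data$baseline,
                                    fill = .data$percent)) +
    ggplot2::geom_tile(colour = "grey70") +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(is.na(.data$percent), "",
                     sprintf("%.1f%%\n(n=%d)", .data$percent, .data$n)))) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 na.value = "grey95", name = "Row %") +
    ggplot2::labs(x = "Follow-up subtype", y = "Baseline subtype") +
    ggplot2::theme_minimal()
}

#' Plot per-feature z-score trajectories of a subtype
#'
#' Expected z-score of each biomarker as a function of stage under a
#' fitted ordering.
#'
#' @param model A [sustain_fit()] model.
#' @param subtype Which subtype's trajectories to draw.
#' @return A ggplot object.
#' @export
plot_trajectories <- function(model, subtype = 1) {
  G <- expected_trajectory(model$sequences[[subtype]], model$cfg)
  dat <- tibble::as_tibble(as.data.frame(t(G)))
  dat$stage <- 0:(ncol(G) - 1)
  dat <- tidyr::pivot_longer(dat, -"stage", names_to = "biomarker",
                             values_to = "z")
  ggplot2::ggplot(dat, ggplot2::aes(.data$stage, .data$z,
                                    colour = .data$biomarker)) +
    ggplot2::geom_line(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = model$cfg$z1[1], linetype = "dashed") +
    ggplot2::geom_hline(yintercept = model$cfg$z2[1], linetype = "dashed") +
    ggplot2::labs(x = "Stage", y = "Expected z-score",
                  title = paste("Subtype", subtype)) +
    ggplot2::theme_minimal()
}
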