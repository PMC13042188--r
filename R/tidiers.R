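#' Tidy a fitted progression model
#'
#' One row per subtype-event pair with the event's position in the
#' ordering and, when MCMC samples are available, the posterior mean
#' position and its 90% interval.
#'
#' @param x A [sustain_fit()] model.
#' @param ... Unused.
#' @return A tibble: `subtype`, `biomarker`, `level`, `z`, `position`,
#'   `position_mean`, `position_lo`, `position_hi`.
#' @exportS3Method generics::tidy
tidy.progression_model <- function(x, ...) {
  purrr::map_dfr(seq_len(x$C), function(c) {
    s <- x$sequences[[c]]
    pos <- match(x$cfg$events$event_id, s)
    out <- dplyr::mutate(x$cfg$events, subtype = c, position = pos)
    sm <- x$samples[[c]]
    if (!is.null(sm) && nrow(sm) > 0) {
      pm <- apply(sm, 1, function(row) match(x$cfg$events$event_id, row))
      out$position_mean <- rowMeans(pm)
      out$position_lo <- apply(pm, 1, quantile, 0.05)
      out$position_hi <- apply(pm, 1, quantile, 0.95)
    }
    dplyr::select(out, "subtype", "biomarker", "level", "z",
                  "position", dplyr::any_of(c("position_mean",
                                              "position_lo", "position_hi")))
  })
}

#' @rdname tidy.progression_model
#' @exportS3Method generics::glance
glance.progression_model <- function(x, ...) {
  tibble::tibble(
    C = x$C, n_events = x$cfg$n_events, n_subjects = x$n_subjects,
    loglik = x$loglik, converged = x$converged, flat_likelihood = x$flat
  )
}

#' @exportS3Method generics::tidy
tidy.harmonization_params <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @exportS3Method generics::glance
glance.harmonization_params <- function(x, ...) {
  tibble::tibble(n_features = nrow(x), n_hc = attr(x, "n_hc"),
                 n_inverted = sum(x$inversion == -1))
}

#' @exportS3Method generics::tidy
tidy.cvic_result <- function(x, ...) x$table

#' @exportS3Method generics::glance
glance.cvic_result <- function(x, ...) {
  tibble::tibble(chosen = x$chosen, folds = x$folds, epsilon = x$epsilon)
}

#' @exportS3Method generics::tidy
tidy.transition_summary <- function(x, ...) {
  cc <- as.data.frame(as.table(x$counts), stringsAsFactors = FALSE)
  pc <- as.data.frame(as.table(x$percent), stringsAsFactors = FALSE)
  tibble::tibble(
    baseline = cc$baseline, followup = cc$followup,
    n = cc$Freq, percent = pc$Freq
  )
}

#' @exportS3Method generics::tidy
tidy.logrank_result <- function(x, ...) x$pairwise

#' @exportS3Method generics::glance
glance.logrank_result <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p.value = x$p.value)
}
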