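#' Event configuration for the z-score progression model
#'
#' Defines the biomarker event grid of the subtype-and-stage model. Each
#' biomarker contributes one event per z-score threshold: with the default
#' two thresholds (1.5 and 3) a panel of `B` biomarkers yields `E = 2 * B`
#' events. A subtype is an ordering of all `E` events; a subject's stage is
#' the number of events that have already occurred (0 to `E`).
#'
#' @param biomarkers Character vector of biomarker (feature) names.
#' @param z1,z2 First and second z-score thresholds, scalars or one value
#'   per biomarker. Defaults 1.5 and 3, the light/saturated convention of
#'   two-threshold z-score event models.
#' @param z_max Plateau z-score reached at the final stage (scalar or per
#'   biomarker). Must exceed `z2`; default 5.
#'
#' @return An object of class `event_config`: a list with `biomarkers`,
#'   `events` (a tibble with one row per event: `event_id`, `biomarker`,
#'   `bm` index, `level` 1 or 2, threshold `z`), `n_biomarkers`, `n_events`,
#'   and the threshold vectors.
#' @examples
#' cfg <- event_config(c("delta_frontal", "theta_frontal"))
#' cfg$n_events
#' @export
event_config <- function(biomarkers, z1 = 1.5, z2 = 3, z_max = 5) {
  if (!is.character(biomarkers) || length(biomarkers) < 1 ||
      anyDuplicated(biomarkers) > 0) {
    abort("`biomarkers` must be a character vector of unique names.")
  }
  B <- length(biomarkers)
  z1 <- rep_len(z1, B)
  z2 <- rep_len(z2, B)
  z_max <- rep_len(z_max, B)
  if (any(!(z1 > 0 & z1 < z2 & z2 < z_max))) {
    abort("Thresholds must satisfy 0 < z1 < z2 < z_max for every biomarker.")
  }
  events <- tibble::tibble(
    event_id = seq_len(2L * B),
    biomarker = rep(biomarkers, each = 2L),
    bm = rep(seq_len(B), each = 2L),
    level = rep(c(1L, 2L), B),
    z = as.numeric(rbind(z1, z2))
  )
  structure(
    list(
      biomarkers = biomarkers, events = events,
      n_biomarkers = B, n_events = 2L * B,
      z1 = z1, z2 = z2, z_max = z_max
    ),
    class = "event_config"
  )
}

#' @export
print.event_config <- function(x, ...) {
  cat("<event_config> ", x$n_biomarkers, " biomarkers, ",
      x$n_events, " events (z1 = ", x$z1[1], ", z2 = ", x$z2[1],
      ", z_max = ", x$z_max[1], ")\n", sep = "")
  invisible(x)
}

# event ids of the level-1 / level-2 event of biomarker b
event_id_z1 <- function(b) 2L * b - 1L
event_id_z2 <- function(b) 2L * b

#' Check that an event ordering respects the threshold order
#'
#' A sequence is a permutation of the event ids; within each biomarker the
#' z1 event must occur before the z2 event (a biomarker cannot pass its
#' second threshold before its first).
#'
#' @param s Integer vector: event ids in stage order.
#' @param cfg An [event_config()].
#' @return Logical scalar.
#' @export
valid_sequence <- function(s, cfg) {
  E <- cfg$n_events
  if (length(s) != E || anyDuplicated(s) > 0 || !all(sort(s) == seq_len(E))) {
    return(FALSE)
  }
  pos <- match(seq_len(E), s)
  all(pos[event_id_z1(seq_len(cfg$n_biomarkers))] <
        pos[event_id_z2(seq_len(cfg$n_biomarkers))])
}

# draw a uniform valid ordering: random permutation, then swap any
# within-biomarker pair that is out of order (a measure-preserving fix-up)
random_sequence <- function(cfg) {
  s <- sample.int(cfg$n_events)
  pos <- match(seq_len(cfg$n_events), s)
  for (b in seq_len(cfg$n_biomarkers)) {
    i <- event_id_z1(b); j <- event_id_z2(b)
    if (pos[i] > pos[j]) {
      tmp <- s[pos[i]]; s[pos[i]] <- s[pos[j]]; s[pos[j]] <- tmp
      tmp <- pos[i]; pos[i] <- pos[j]; pos[j] <- tmp
    }
  }
  s
}

#' Expected biomarker trajectories along a subtype sequence
#'
#' For an event ordering `s`, the expected z-score of biomarker `b` at stage
#' `k` is the piecewise-linear function through the knots
#' `(0, 0)`, `(pos(z1 event), z1)`, `(pos(z2 event), z2)` and `(E, z_max)`.
#' When the z2 event sits at the final position the trajectory ends at `z2`.
#'
#' @inheritParams valid_sequence
#' @return Numeric matrix `B x (E + 1)`; column `k + 1` holds the expected
#'   z-scores at stage `k`.
#' @examples
#' cfg <- event_config(c("a", "b", "c"))
#' g <- expected_trajectory(1:6, cfg)
#' g[, 1]  # all zero at stage 0
#' @export
expected_trajectory <- function(s, cfg) {
  B <- cfg$n_biomarkers
  E <- cfg$n_events
  pos <- match(seq_len(E), s)
  p1 <- pos[event_id_z1(seq_len(B))]
  p2 <- pos[event_id_z2(seq_len(B))]
  z1 <- cfg$z1; z2 <- cfg$z2; zmax <- cfg$z_max
  K <- matrix(rep(0:E, each = B), nrow = B)  # stage grid per biomarker
  G <- matrix(0, nrow = B, ncol = E + 1L)
  # segment 1: 0..p1 rising to z1
  seg1 <- K <= p1
  G[seg1] <- (z1 / p1 * K)[seg1]
  # segment 2: p1..p2 rising to z2
  seg2 <- K > p1 & K <= p2
  G[seg2] <- (z1 + (z2 - z1) * (K - p1) / (p2 - p1))[seg2]
  # segment 3: p2..E rising to z_max (empty when p2 == E)
  seg3 <- K > p2
  if (any(seg3)) {
    slope3 <- ifelse(E > p2, (zmax - z2) / (E - p2), 0)
    G[seg3] <- (z2 + slope3 * (K - p2))[seg3]
  }
  rownames(G) <- cfg$biomarkers
  G
}

# log N(x; g, sigma^2) summed over biomarkers, for every subject x stage.
# Z: n x B matrix; G: B x (E+1); sigma: length-B positive vector.
# Returns n x (E+1) matrix of per-stage log-likelihoods.
stage_loglik_matrix <- function(Z, G, sigma) {
  B <- ncol(Z)
  inv_v <- 1 / sigma^2
  const <- -sum(log(sigma)) - B / 2 * log(2 * pi)
  cross <- (Z %*% (G * inv_v))              # n x (E+1)
  zq <- rowSums(Z^2 * rep(inv_v, each = nrow(Z)))
  gq <- colSums(G^2 * inv_v)
  LL <- cross - 0.5 * outer(zq, gq, "+") + const
  LL
}

row_logsumexp <- function(M) {
  mx <- M[cbind(seq_len(nrow(M)), max.col(M, ties.method = "first"))]
  mx + log(rowSums(exp(M - mx)))
}

# marginal log P(x | S) under a uniform stage prior, per subject
marginal_loglik <- function(Z, G, sigma) {
  LL <- stage_loglik_matrix(Z, G, sigma)
  row_logsumexp(LL) - log(ncol(LL))
}

#' Subject log-likelihood and stage posterior under one sequence
#'
#' Marginalizes a uniform stage prior over stages `0..E`:
#' `P(x | S) = (E + 1)^-1 * sum_k prod_b N(x_b; g_b(k), sigma_b^2)`,
#' computed with log-sum-exp stabilization.
#'
#' @param z Numeric matrix or data frame of z-scores (subjects x biomarkers,
#'   columns ordered as `cfg$biomarkers`), or a single row.
#' @param s Event ordering (integer vector of event ids).
#' @param cfg An [event_config()].
#' @param sigma Observation noise SD per biomarker (recycled); default 1.
#' @return A list with `loglik` (length-n vector of marginal log-likelihoods)
#'   and `stage_posterior` (n x (E+1) matrix, rows summing to one).
#' @export
subject_loglik <- function(z, s, cfg, sigma = 1) {
  Z <- as_z_rows(z, cfg)
  sigma <- rep_len(sigma, cfg$n_biomarkers)
  if (any(sigma <= 0)) abort("`sigma` must be positive.")
  if (!valid_sequence(s, cfg)) abort("`s` is not a valid event sequence.")
  if (any(!is.finite(Z))) abort("z-scores must all be finite.")
  G <- expected_trajectory(s, cfg)
  LL <- stage_loglik_matrix(Z, G, sigma)
  ml <- row_logsumexp(LL) - log(ncol(LL))
  post <- exp(LL - row_logsumexp(LL))
  list(loglik = ml, stage_posterior = post)
}

# coerce z input (z_matrix tibble, data frame, matrix, or single row vector)
# to a plain numeric matrix with columns in cfg order
as_z_rows <- function(z, cfg) {
  if (is.null(dim(z))) {
    z <- matrix(as.numeric(z), nrow = 1,
                dimnames = list(NULL, names(z)))
  }
  if (inherits(z, "tbl_df") || is.data.frame(z)) {
    miss <- setdiff(cfg$biomarkers, colnames(z))
    if (length(miss) > 0) {
      abort(paste0("z input lacks modelled features: ",
                   paste(head(miss, 4), collapse = ", ")))
    }
    z <- as.matrix(as.data.frame(z)[, cfg$biomarkers, drop = FALSE])
  } else if (!is.null(colnames(z)) && all(cfg$biomarkers %in% colnames(z))) {
    z <- z[, cfg$biomarkers, drop = FALSE]
  }
  if (ncol(z) != cfg$n_biomarkers) {
    abort("z input must have one column per modelled biomarker.")
  }
  storage.mode(z) <- "double"
  z
}
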