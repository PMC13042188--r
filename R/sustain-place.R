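#' Stage and subtype placement of subjects
#'
#' Computes the joint posterior `P(c, k | x) \propto f_c P(x | k, S_c)`
#' under a uniform stage prior and reports the maximum a posteriori subtype
#' and stage per subject-visit. Ties are broken toward the smaller stage,
#' then the smaller subtype index. Subjects whose MAP stage is 0 receive
#' subtype label 0 (the "no distinguishable spectral features" group); the
#' `max_z_below_z1` flag records whether every modelled feature sits below
#' the first threshold, and `hard_zero = TRUE` turns that flag into a
#' pre-filter that forces such subjects to stage 0 before the posterior is
#' consulted.
#'
#' @param z A `z_matrix`, data frame or matrix of harmonized z-scores; id
#'   columns (`subject_id`, `visit`, `group`, `years`) are carried through
#'   when present.
#' @param model A fitted [sustain_fit()] model.
#' @param hard_zero Apply the all-features-below-z1 pre-filter (default
#'   `FALSE`: MAP staging decides).
#' @return A tibble of class `sustain_placement`: one row per subject-visit
#'   with `subtype` (0..C), `stage` (0..E), posterior mass of the MAP cell,
#'   `stage_post` and `subtype_post` list-columns are avoided in favour of
#'   an attached `posterior` attribute (n x C x (E+1) array).
#' @export
sustain_place <- function(z, model, hard_zero = FALSE) {
  cfg <- model$cfg
  if (inherits(z, "tbl_df") || is.data.frame(z)) {
    miss <- setdiff(cfg$biomarkers, colnames(z))
    if (length(miss) > 0) {
      abort("z-matrix features do not match the fitted model's biomarkers.")
    }
  }
  Z <- as_z_rows(z, cfg)
  n <- nrow(Z)
  E <- cfg$n_events
  C <- model$C
  post <- array(0, dim = c(n, C, E + 1L))
  for (c in seq_len(C)) {
    G <- expected_trajectory(model$sequences[[c]], cfg)
    LL <- stage_loglik_matrix(Z, G, model$sigma)
    post[, c, ] <- exp(LL) * model$fractions[c] / (E + 1)
  }
  tot <- apply(post, 1, sum)
  # renormalize in log-safe fashion for extreme rows
  if (any(tot == 0 | !is.finite(tot))) {
    for (c in seq_len(C)) {
      G <- expected_trajectory(model$sequences[[c]], cfg)
      LL <- stage_loglik_matrix(Z, G, model$sigma) +
        log(model$fractions[c]) - log(E + 1)
      post[, c, ] <- LL
    }
    mx <- apply(post, 1, max)
    post <- exp(post - array(mx, dim = dim(post)))
    tot <- apply(post, 1, sum)
  }
  post <- post / array(tot, dim = dim(post))

  below <- apply(abs(Z) < cfg$z1[col(Z)], 1, all)
  subtype <- integer(n); stage <- integer(n); mass <- numeric(n)
  for (j in seq_len(n)) {
    pj <- matrix(post[j, , ], nrow = C)
    if (hard_zero && below[j]) {
      subtype[j] <- 0L; stage[j] <- 0L
      mass[j] <- sum(pj[, 1])
      next
    }
    # MAP with ties toward smaller stage then smaller subtype:
    # scan stages ascending, subtypes ascending
    best <- -Inf; bc <- 1L; bk <- 0L
    for (k in 0:E) {
      for (c in seq_len(C)) {
        if (pj[c, k + 1L] > best + 1e-15) {
          best <- pj[c, k + 1L]; bc <- c; bk <- k
        }
      }
    }
    stage[j] <- bk
    subtype[j] <- if (bk == 0L) 0L else bc
    mass[j] <- best
  }

  ids <- placement_id_cols(z, n)
  out <- dplyr::bind_cols(
    ids,
    tibble::tibble(subtype = subtype, stage = stage,
                   map_posterior = mass, max_z_below_z1 = below)
  )
  attr(out, "posterior") <- post
  attr(out, "cfg") <- cfg
  class(out) <- c("sustain_placement", class(out))
  out
}

placement_id_cols <- function(z, n) {
  keep <- intersect(c("subject_id", "visit", "group", "years"),
                    if (is.data.frame(z)) colnames(z) else character(0))
  if (length(keep) > 0) {
    tibble::as_tibble(as.data.frame(z)[, keep, drop = FALSE])
  } else {
    tibble::tibble(subject_id = paste0("row", seq_len(n)))
  }
}

#' Cross-validated selection of the number of subtypes
#'
#' Splits subjects into folds, fits models with `C = 1..c_max` subtypes on
#' the training folds and evaluates held-out log-likelihood under the fitted
#' mixture. The cross-validation information criterion is
#' `CVIC(C) = -2 * sum(held-out log-likelihood)`. The chosen `C` is the
#' smallest candidate such that no larger candidate improves CVIC by more
#' than `epsilon` (an explicit parsimony margin).
#'
#' @inheritParams sustain_fit
#' @param c_max Largest candidate subtype count (>= 2).
#' @param folds Number of cross-validation folds (default 5, i.e. 80/20
#'   train/test splits).
#' @param epsilon Parsimony margin on the CVIC scale (default 6).
#' @return An object of class `cvic_result` with a per-candidate tibble
#'   (`C`, `cvic`, total held-out log-likelihood), the per-fold matrix, and
#'   `chosen`.
#' @export
select_subtypes <- function(z, c_max = 2, folds = 5, cfg = NULL, sigma = 1,
                            epsilon = 6, control = sustain_control(),
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (c_max < 2) abort("`c_max` must be at least 2.")
  if (is.null(cfg)) cfg <- event_config(modelled_features(z))
  Z <- as_z_rows(z, cfg)
  n <- nrow(Z)
  if (n < folds) abort("Need at least as many subjects as folds.")
  fold_id <- sample(rep_len(seq_len(folds), n))
  held <- matrix(NA_real_, nrow = c_max, ncol = folds,
                 dimnames = list(paste0("C", seq_len(c_max)), NULL))
  for (f in seq_len(folds)) {
    train <- Z[fold_id != f, , drop = FALSE]
    test <- Z[fold_id == f, , drop = FALSE]
    if (nrow(test) == 0) abort("A fold contains no subjects.")
    for (C in seq_len(c_max)) {
      m <- suppressWarnings(
        sustain_fit(train, C = C, cfg = cfg, sigma = sigma,
                    control = control)
      )
      lm_ <- mixture_logmat(test, m$sequences, m$fractions, cfg, sigma)
      held[C, f] <- sum(row_logsumexp(lm_))
    }
  }
  cvic <- -2 * rowSums(held)
  # smallest C such that no larger C improves CVIC by more than epsilon
  chosen <- c_max
  for (C in seq_len(c_max)) {
    if (all(cvic[C] - cvic[seq_len(c_max) > C] <= epsilon)) {
      chosen <- C
      break
    }
  }
  structure(
    list(
      table = tibble::tibble(C = seq_len(c_max), cvic = as.numeric(cvic),
                             heldout_loglik = as.numeric(rowSums(held))),
      fold_loglik = held, chosen = as.integer(chosen),
      folds = folds, epsilon = epsilon
    ),
    class = "cvic_result"
  )
}

#' @export
print.cvic_result <- function(x, ...) {
  cat("<cvic_result> chosen C =", x$chosen, "\n")
  print(x$table)
  invisible(x)
}
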