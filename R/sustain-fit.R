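#' Fitting controls for the progression model
#'
#' @param n_starts Number of random restarts of the greedy ascent (C = 1
#'   stage of the fit).
#' @param mcmc_iter Metropolis iterations run after the greedy optimum.
#' @param mcmc_keep Number of thinned posterior sequence samples retained.
#' @param em_max_iter,em_tol Expectation-maximization iteration cap and
#'   absolute log-likelihood convergence tolerance (C > 1).
#' @param mcmc_iter_em Metropolis iterations inside each EM M-step (kept
#'   short; the full `mcmc_iter` run happens once after convergence).
#' @param split_tries Random splits of the weakest cluster attempted when
#'   growing the subtype count; the best resulting EM run is kept.
#' @param greedy_tol Minimum log-likelihood improvement for a greedy move.
#' @return A list of class `sustain_control`.
#' @export
sustain_control <- function(n_starts = 25, mcmc_iter = 10000,
                            mcmc_keep = 100, em_max_iter = 100,
                            em_tol = 1e-6, mcmc_iter_em = 200,
                            split_tries = 3, greedy_tol = 1e-9) {
  stopifnot(n_starts >= 1, mcmc_iter >= 0, em_max_iter >= 1,
            split_tries >= 1)
  structure(
    list(n_starts = as.integer(n_starts), mcmc_iter = as.integer(mcmc_iter),
         mcmc_keep = as.integer(mcmc_keep),
         em_max_iter = as.integer(em_max_iter), em_tol = em_tol,
         mcmc_iter_em = as.integer(mcmc_iter_em),
         split_tries = as.integer(split_tries), greedy_tol = greedy_tol),
    class = "sustain_control"
  )
}

# relocate the element at position `from` to position `to`
relocate_seq <- function(s, from, to) {
  ev <- s[from]
  s <- s[-from]
  append(s, ev, after = to - 1L)
}

# weighted total objective for a sequence
seq_objective <- function(Z, w, s, cfg, sigma) {
  sum(w * marginal_loglik(Z, expected_trajectory(s, cfg), sigma))
}

# Greedy ascent: repeatedly apply the single event relocation that most
# improves the (weighted) total log-likelihood, until no move improves.
greedy_ascent <- function(Z, w, s, cfg, sigma, tol = 1e-9) {
  E <- cfg$n_events
  cur <- seq_objective(Z, w, s, cfg, sigma)
  n_moves <- 0L
  repeat {
    best_gain <- tol
    best_seq <- NULL
    best_ll <- cur
    for (from in seq_len(E)) {
      for (to in seq_len(E)) {
        if (to == from) next
        cand <- relocate_seq(s, from, to)
        if (!valid_sequence(cand, cfg)) next
        ll <- seq_objective(Z, w, cand, cfg, sigma)
        if (ll - cur > best_gain) {
          best_gain <- ll - cur
          best_seq <- cand
          best_ll <- ll
        }
      }
    }
    if (is.null(best_seq)) break
    s <- best_seq
    cur <- best_ll
    n_moves <- n_moves + 1L
  }
  list(seq = s, loglik = cur, n_moves = n_moves)
}

# Metropolis MCMC over orderings: propose relocating one uniformly chosen
# event to a uniformly chosen position; proposals violating the
# within-biomarker threshold order are rejected (symmetric proposal over the
# valid neighbourhood). Tracks the maximum-likelihood visited sequence and
# retains `keep` thinned samples.
mcmc_sequences <- function(Z, w, s, cfg, sigma, iter, keep = 100) {
  E <- cfg$n_events
  cur_ll <- seq_objective(Z, w, s, cfg, sigma)
  best <- list(seq = s, loglik = cur_ll)
  samples <- matrix(NA_integer_, nrow = 0, ncol = E)
  if (iter > 0) {
    thin <- max(1L, iter %/% max(1L, keep))
    samples <- matrix(NA_integer_, nrow = iter %/% thin, ncol = E)
    si <- 0L
    froms <- sample.int(E, iter, replace = TRUE)
    tos <- sample.int(E, iter, replace = TRUE)
    us <- runif(iter)
    for (i in seq_len(iter)) {
      if (tos[i] != froms[i]) {
        cand <- relocate_seq(s, froms[i], tos[i])
        if (valid_sequence(cand, cfg)) {
          ll <- seq_objective(Z, w, cand, cfg, sigma)
          if (ll >= cur_ll || us[i] < exp(ll - cur_ll)) {
            s <- cand
            cur_ll <- ll
            if (ll > best$loglik) best <- list(seq = s, loglik = ll)
          }
        }
      }
      if (i %% thin == 0 && si < nrow(samples)) {
        si <- si + 1L
        samples[si, ] <- s
      }
    }
    samples <- samples[seq_len(si), , drop = FALSE]
  }
  list(seq = best$seq, loglik = best$loglik, samples = samples,
       final_seq = s)
}

# single-sequence (C = 1) optimizer: multi-start greedy + MCMC refinement
fit_single_sequence <- function(Z, w, cfg, sigma, control,
                                mcmc_iter = control$mcmc_iter) {
  starts <- vector("list", control$n_starts)
  for (i in seq_len(control$n_starts)) {
    starts[[i]] <- greedy_ascent(Z, w, random_sequence(cfg), cfg, sigma,
                                 tol = control$greedy_tol)
  }
  lls <- vapply(starts, `[[`, numeric(1), "loglik")
  best <- starts[[which.max(lls)]]
  mc <- mcmc_sequences(Z, w, best$seq, cfg, sigma, mcmc_iter,
                       keep = control$mcmc_keep)
  # non-identifiable ordering: every subject MAP-stages at 0, so the data
  # carry no information about the event order
  LL <- stage_loglik_matrix(Z, expected_trajectory(mc$seq, cfg), sigma)
  flat <- all(max.col(LL, ties.method = "first") == 1L)
  list(seq = mc$seq, loglik = mc$loglik, samples = mc$samples, flat = flat)
}

# Expectation-maximization over a fixed number of subtypes, from given
# starting sequences/fractions. A few winner-take-all (hard-assignment)
# rounds precede the soft updates: they break the symmetric fixed point a
# random split starts close to.
run_em <- function(Z, seqs, fractions, cfg, sigma, control) {
  C <- length(seqs)
  hard_rounds <- 3L
  prev_ll <- -Inf
  converged <- FALSE
  loglik <- -Inf
  for (it in seq_len(control$em_max_iter)) {
    lm_ <- mixture_logmat(Z, seqs, fractions, cfg, sigma)
    lse <- row_logsumexp(lm_)
    total <- sum(lse)
    R <- exp(lm_ - lse)
    if (it > hard_rounds + 1L && abs(total - prev_ll) < control$em_tol) {
      converged <- TRUE
      loglik <- total
      break
    }
    prev_ll <- total
    loglik <- total
    if (it <= hard_rounds) {
      # hard assignment: responsibility 1 for the best-fitting subtype
      win <- max.col(lm_, ties.method = "first")
      R <- matrix(0, nrow = nrow(Z), ncol = C)
      R[cbind(seq_len(nrow(Z)), win)] <- 1
      R <- R + 1e-6  # keep every subtype alive
    }
    fractions <- pmax(colMeans(R), 1e-12)
    fractions <- fractions / sum(fractions)
    for (c in seq_len(C)) {
      g <- greedy_ascent(Z, R[, c], seqs[[c]], cfg, sigma,
                         tol = control$greedy_tol)
      s_c <- g$seq
      if (control$mcmc_iter_em > 0) {
        mc <- mcmc_sequences(Z, R[, c], s_c, cfg, sigma,
                             control$mcmc_iter_em,
                             keep = min(control$mcmc_keep, 20L))
        s_c <- mc$seq
      }
      seqs[[c]] <- s_c
    }
  }
  list(seqs = seqs, fractions = fractions, loglik = loglik,
       converged = converged)
}

# mixture log-likelihood pieces: n x C matrix of log f_c + log P(x_j | S_c)
mixture_logmat <- function(Z, seqs, fractions, cfg, sigma) {
  lp <- vapply(seq_along(seqs), function(c) {
    marginal_loglik(Z, expected_trajectory(seqs[[c]], cfg), sigma)
  }, numeric(nrow(Z)))
  if (is.null(dim(lp))) lp <- matrix(lp, nrow = nrow(Z))
  sweep(lp, 2, log(fractions), "+")
}

#' Fit the subtype-and-stage progression model
#'
#' Estimates `C` subtype event orderings and mixture fractions from a matrix
#' of harmonized z-scores (baseline disease rows only; healthy-control rows
#' must not be passed in). For `C = 1` the fit is multi-start greedy ascent
#' over single-event relocations followed by Metropolis MCMC over orderings.
#' For `C > 1` the model is grown hierarchically: the weakest-fitting
#' subtype's subjects are split into two random halves whose separately
#' fitted orderings seed an expectation-maximization loop (E-step:
#' stage-marginalized responsibilities; M-step: fraction update and
#' responsibility-weighted re-optimization of each ordering).
#'
#' @param z A `z_matrix` (from [harmonize_features()]), data frame or matrix
#'   whose columns include the modelled biomarkers of `cfg`.
#' @param C Number of subtypes to fit (>= 1).
#' @param cfg An [event_config()]. If `NULL`, built from the z-matrix's
#'   modelled features with default thresholds.
#' @param sigma Observation noise SD per biomarker; default 1 (the data are
#'   control-standardized).
#' @param control A [sustain_control()] list.
#' @param seed Optional integer seed for the fit's randomness.
#' @return An object of class `progression_model`: sequences, `fractions`,
#'   `cfg`, `sigma`, `loglik`, thinned MCMC `samples` per subtype, and fit
#'   metadata. Supports [tidy()], [glance()] and [autoplot()].
#' @examples
#' cfg <- event_config(paste0("bm", 1:3))
#' sim <- simulate_z_cohort(n = 80, cfg = cfg, seed = 2)
#' m <- sustain_fit(sim$z, C = 1, cfg = cfg,
#'                  control = sustain_control(n_starts = 3, mcmc_iter = 200))
#' glance(m)
#' @export
sustain_fit <- function(z, C = 1, cfg = NULL, sigma = 1,
                        control = sustain_control(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(cfg)) cfg <- event_config(modelled_features(z))
  Z <- as_z_rows(z, cfg)
  n <- nrow(Z)
  if (n < C) abort("Fewer subjects than requested subtypes.")
  if (C < 1) abort("`C` must be at least 1.")
  sigma <- rep_len(sigma, cfg$n_biomarkers)
  if (any(sigma <= 0)) abort("`sigma` must be positive.")
  w1 <- rep(1, n)

  fit1 <- fit_single_sequence(Z, w1, cfg, sigma, control)
  if (fit1$flat) {
    warn(paste("Flat likelihood: every subject stages at 0, so the event",
               "ordering is not identifiable."))
  }
  seqs <- list(fit1$seq)
  fractions <- 1
  samples <- list(fit1$samples)
  loglik <- fit1$loglik
  converged <- TRUE

  cc <- 1L
  while (cc < C) {
    cc <- cc + 1L
    # hard-assign subjects, find the weakest subtype (lowest mean loglik)
    lm_ <- mixture_logmat(Z, seqs, fractions, cfg, sigma)
    assign_c <- max.col(lm_, ties.method = "first")
    mean_ll <- vapply(seq_along(seqs), function(c) {
      idx <- assign_c == c
      if (!any(idx)) return(Inf)
      mean(lm_[idx, c])
    }, numeric(1))
    weak <- which.min(mean_ll)
    idx <- which(assign_c == weak)
    if (length(idx) < 4) idx <- seq_len(n)  # degenerate: split everyone
    old_f <- if (weak <= length(fractions)) fractions[weak] else 1 / cc

    # several splits of the weakest cluster; the first try splits by
    # k-means on direction-normalized z-rows (pattern, not severity),
    # later tries split at random. The best EM run is kept.
    best_run <- NULL
    for (try in seq_len(max(1L, control$split_tries))) {
      if (try == 1L && length(idx) >= 8) {
        U <- Z[idx, , drop = FALSE]
        U <- U / pmax(sqrt(rowSums(U^2)), 1e-6)
        km <- tryCatch(stats::kmeans(U, 2, nstart = 5),
                       error = function(e) NULL)
        if (!is.null(km) && min(table(km$cluster)) >= 2) {
          half <- idx[km$cluster == 1]
        } else {
          half <- sample(idx, floor(length(idx) / 2))
        }
      } else {
        half <- sample(idx, floor(length(idx) / 2))
      }
      other <- setdiff(idx, half)
      sub_ctl <- control
      sub_ctl$n_starts <- max(2L, control$n_starts %/% 4L)
      f_a <- fit_single_sequence(Z[half, , drop = FALSE],
                                 rep(1, length(half)), cfg, sigma, sub_ctl,
                                 mcmc_iter = 0L)
      f_b <- fit_single_sequence(Z[other, , drop = FALSE],
                                 rep(1, length(other)), cfg, sigma, sub_ctl,
                                 mcmc_iter = 0L)
      try_seqs <- seqs
      try_seqs[[weak]] <- f_a$seq
      try_seqs[[cc]] <- f_b$seq
      try_frac <- fractions
      try_frac[weak] <- old_f / 2
      try_frac <- c(try_frac, old_f / 2)
      run <- run_em(Z, try_seqs, try_frac, cfg, sigma, control)
      if (is.null(best_run) || run$loglik > best_run$loglik) best_run <- run
    }
    seqs <- best_run$seqs
    fractions <- best_run$fractions
    loglik <- best_run$loglik
    converged <- best_run$converged
    if (!converged) {
      warn("EM did not converge within `em_max_iter`; returning best so far.")
    }
  }

  if (C > 1) {
    # final posterior sampling per subtype under converged responsibilities
    lm_ <- mixture_logmat(Z, seqs, fractions, cfg, sigma)
    R <- exp(lm_ - row_logsumexp(lm_))
    samples <- lapply(seq_len(C), function(c) {
      mcmc_sequences(Z, R[, c], seqs[[c]], cfg, sigma, control$mcmc_iter,
                     keep = control$mcmc_keep)$samples
    })
    lm_ <- mixture_logmat(Z, seqs, fractions, cfg, sigma)
    loglik <- sum(row_logsumexp(lm_))
  }

  structure(
    list(
      sequences = seqs, fractions = as.numeric(fractions), cfg = cfg,
      sigma = sigma, loglik = loglik, samples = samples,
      n_subjects = n, C = C, control = control, seed = seed,
      flat = fit1$flat, converged = converged
    ),
    class = "progression_model"
  )
}

#' @export
print.progression_model <- function(x, ...) {
  cat("<progression_model> ", x$C, " subtype(s), ",
      x$cfg$n_events, " events, fitted on ", x$n_subjects,
      " subjects\n  log-likelihood: ", format(x$loglik), "\n  fractions: ",
      paste(sprintf("%.3f", x$fractions), collapse = ", "), "\n", sep = "")
  invisible(x)
}

# exhaustively enumerate every valid ordering (small E only)
enumerate_sequences <- function(cfg) {
  E <- cfg$n_events
  if (E > 8) abort("Exhaustive enumeration is limited to E <= 8.")
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  Filter(function(s) valid_sequence(s, cfg), perms(seq_len(E)))
}
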