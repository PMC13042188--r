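#' Simulation configuration for synthetic prodromal cohorts
#'
#' Collects every parameter of the synthetic-data generator. Defaults
#' emulate the published study conditions: a healthy-control arm that is
#' standard normal after age/sex adjustment, a disease arm mixing two latent
#' subtypes with distinct event orderings (a posterior-beta-early subtype
#' and a frontal-slowing subtype), roughly half of the disease cohort at
#' stage 0, stage advancement at subtype-specific Poisson rates with
#' occasional generating-subtype shifts, and a phenoconversion hazard whose
#' odds ratio per 5 stages defaults to 2.14 over a 7.5-year horizon.
#'
#' @param seed Integer seed (mandatory; every emitted table is reproducible
#'   from the configuration alone).
#' @param n_hc,n_disease Arm sizes (defaults 51 and 234).
#' @param bands,rois Modelled bands and region labels; features are named
#'   `<band>_<roi>`. The alpha band is generated for the feature table but
#'   carries no disease signal.
#' @param fractions True subtype mixing fractions (default the published
#'   51/64 split of staged subjects).
#' @param stage_rho Truncated-geometric baseline-stage parameter:
#'   `P(k) proportional to (1 - stage_rho)^k` over `0..E`. The default 0.5
#'   leaves about half the cohort at stage 0; values near 0 approach a
#'   uniform stage spread (used by the recovery experiments).
#' @param sigma Observation noise SD on the latent z-scale.
#' @param age_mean_hc,age_sd_hc,age_mean_dis,age_sd_dis,male_p Demographics.
#' @param mu,tau,age_slope,sex_offset Raw-feature affine map per feature
#'   (scalars are recycled): `raw = mu + age_slope * age + sex_offset * sex
#'   + tau * latent`.
#' @param neg_beta Should beta-band features carry a negative disease
#'   direction (exercising sign inversion)? Default `TRUE`.
#' @param lambda Stage-advancement rate per subtype (stages/year, Poisson);
#'   default `c(0.1, 0.9)`: a largely static and a progressive subtype.
#' @param pi_shift Probability that a subject's generating subtype switches
#'   before follow-up (default 0.1).
#' @param dt_mean,dt_sd,dt_min,dt_max Follow-up interval distribution
#'   (truncated normal, years); default mean 3.8.
#' @param h0 Baseline yearly conversion hazard at stage 0 (default 0.02).
#' @param or5 Hazard odds ratio per 5 stages (default 2.14).
#' @param horizon Censoring horizon in years (default 7.5).
#' @param z1,z2,z_max Event thresholds passed to [event_config()].
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_hc = 51, n_disease = 234,
                       bands = c("delta", "theta", "beta"),
                       rois = c("mfrontal", "lfrontal", "mcentral",
                                "lcentral", "mparietal", "lparietal",
                                "occipital", "temporal"),
                       fractions = c(51, 64) / 115,
                       stage_rho = 0.5, sigma = 1,
                       age_mean_hc = 66.2, age_sd_hc = 6.4,
                       age_mean_dis = 68, age_sd_dis = 7.5, male_p = 0.6,
                       mu = NULL, tau = NULL,
                       age_slope = NULL, sex_offset = NULL,
                       neg_beta = TRUE,
                       lambda = c(0.1, 0.9), pi_shift = 0.1,
                       dt_mean = 3.8, dt_sd = 1.5, dt_min = 0.5,
                       dt_max = 7, h0 = 0.02, or5 = 2.14, horizon = 7.5,
                       z1 = 1.5, z2 = 3, z_max = 5) {
  if (missing(seed) || is.null(seed) || !is.finite(seed)) {
    abort("`seed` is mandatory in sim_config().")
  }
  if (abs(sum(fractions) - 1) > 1e-8 || any(fractions <= 0)) {
    abort("`fractions` must be positive and sum to 1.")
  }
  if (any(c(lambda, pi_shift, h0, sigma) < 0)) {
    abort("Rates and noise levels must be nonnegative.")
  }
  if (stage_rho < 0 || stage_rho >= 1) {
    abort("`stage_rho` must lie in [0, 1).")
  }
  features <- as.vector(outer(bands, rois, paste, sep = "_"))
  band_of <- sub("_.*$", "", features)
  base_mu <- c(delta = 12, theta = 8, alpha = 10, beta = 4)
  mu <- mu %||% base_mu[band_of]
  tau <- tau %||% (0.2 * mu)
  age_slope <- age_slope %||% (0.005 * mu)
  sex_offset <- sex_offset %||% (0.05 * mu)
  direction <- ifelse(neg_beta & band_of == "beta", -1, 1)
  cfg <- event_config(features, z1 = z1, z2 = z2, z_max = z_max)
  structure(
    list(seed = as.integer(seed), n_hc = n_hc, n_disease = n_disease,
         bands = bands, rois = rois, features = features,
         event_cfg = cfg,
         sequences = default_true_sequences(cfg, length(fractions)),
         fractions = fractions, stage_rho = stage_rho, sigma = sigma,
         age_mean_hc = age_mean_hc, age_sd_hc = age_sd_hc,
         age_mean_dis = age_mean_dis, age_sd_dis = age_sd_dis,
         male_p = male_p,
         mu = setNames(rep_len(mu, length(features)), features),
         tau = setNames(rep_len(tau, length(features)), features),
         age_slope = setNames(rep_len(age_slope, length(features)), features),
         sex_offset = setNames(rep_len(sex_offset, length(features)), features),
         direction = setNames(direction, features),
         lambda = lambda, pi_shift = pi_shift,
         dt_mean = dt_mean, dt_sd = dt_sd, dt_min = dt_min, dt_max = dt_max,
         h0 = h0, or5 = or5, horizon = horizon),
    class = "sim_config"
  )
}

#' Default ground-truth subtype orderings
#'
#' Builds well-separated event orderings over an event grid. When the
#' biomarkers follow the `<band>_<roi>` convention the first subtype passes
#' its posterior beta events first (an occipital/parietal beta phenotype)
#' and the second starts with frontal theta followed by frontal/temporal
#' delta before spreading; for generic biomarker panels the orderings are
#' the canonical order and its biomarker-reversed counterpart. All z1
#' events precede all z2 events, which guarantees validity.
#'
#' @param cfg An [event_config()].
#' @param C Number of subtypes (default 2).
#' @return A list of `C` valid event orderings.
#' @export
default_true_sequences <- function(cfg, C = 2) {
  B <- cfg$n_biomarkers
  nm <- cfg$biomarkers
  prio_for <- function(scores) {
    # staircase: each biomarker passes z1 then z2 before the next biomarker
    # starts (valid by construction, and maximally distinct across
    # subtype-specific biomarker orders)
    ord <- order(scores, seq_len(B))
    as.integer(rbind(event_id_z1(ord), event_id_z2(ord)))
  }
  named <- all(grepl("^(delta|theta|alpha|beta)_", nm))
  if (named) {
    band <- sub("_.*$", "", nm)
    roi <- sub("^[a-z]+_", "", nm)
    posterior <- roi %in% c("occipital", "mparietal", "lparietal")
    frontal <- roi %in% c("mfrontal", "lfrontal")
    temporal <- roi %in% c("temporal")
    s1_score <- 10 + 5 * seq_len(B) / B
    s1_score[band == "beta" & posterior] <- 1:sum(band == "beta" & posterior)
    s2_score <- rep(20, B) + seq_len(B) / B
    s2_score[band == "theta" & frontal] <- 1
    s2_score[band == "delta" & (frontal | temporal)] <- 5
    s2_score[band == "theta" & !frontal] <- 10
    s2_score[band == "delta" & !(frontal | temporal)] <- 15
    seqs <- list(prio_for(s1_score), prio_for(s2_score))
  } else {
    seqs <- list(prio_for(seq_len(B)), prio_for(rev(seq_len(B))))
  }
  if (C == 1) return(seqs[1])
  if (C > 2) {
    extra <- lapply(seq_len(C - 2), function(i) {
      prio_for(sample(seq_len(B)))
    })
    seqs <- c(seqs, extra)
  }
  seqs
}

draw_stages <- function(n, E, rho) {
  prob <- (1 - rho)^(0:E)
  sample(0:E, n, replace = TRUE, prob = prob / sum(prob))
}

#' Simulate a latent z-score cohort
#'
#' Generates disease z-rows directly on the model scale: each subject draws
#' a subtype from `fractions` and a baseline stage from the truncated
#' geometric stage distribution, and observes
#' `z_b = g_b(stage) + Normal(0, sigma)` under the subject's true ordering.
#' This is the workhorse of the parameter-recovery experiments; use
#' [simulate_cohort()] for the full raw-feature pipeline.
#'
#' @param n Number of disease subjects.
#' @param cfg An [event_config()].
#' @param sequences List of true orderings (default
#'   [default_true_sequences()]).
#' @param fractions True mixing fractions.
#' @param stage_rho Truncated-geometric stage parameter (0 = uniform).
#' @param sigma Noise SD.
#' @param seed Integer seed.
#' @return A list with `z` (a `z_matrix` tibble) and `truth` (tibble with
#'   `subject_id`, `subtype_true`, `stage_true`).
#' @export
simulate_z_cohort <- function(n, cfg, sequences = NULL, fractions = NULL,
                              stage_rho = 0, sigma = 1, seed) {
  if (missing(seed)) abort("`seed` is mandatory.")
  set.seed(seed)
  if (is.null(sequences)) {
    sequences <- default_true_sequences(cfg, max(1, length(fractions %||% 1)))
  }
  if (is.null(fractions)) fractions <- rep(1 / length(sequences),
                                           length(sequences))
  stopifnot(length(sequences) == length(fractions))
  for (s in sequences) {
    if (!valid_sequence(s, cfg)) abort("Invalid true sequence supplied.")
  }
  E <- cfg$n_events
  subtype <- sample.int(length(fractions), n, replace = TRUE,
                        prob = fractions)
  stage <- draw_stages(n, E, stage_rho)
  G <- lapply(sequences, expected_trajectory, cfg = cfg)
  Z <- t(vapply(seq_len(n), function(j) {
    G[[subtype[j]]][, stage[j] + 1L] + rnorm(cfg$n_biomarkers, 0, sigma)
  }, numeric(cfg$n_biomarkers)))
  colnames(Z) <- cfg$biomarkers
  ids <- sprintf("sim%04d", seq_len(n))
  z <- tibble::as_tibble(as.data.frame(Z))
  z <- dplyr::bind_cols(
    tibble::tibble(subject_id = ids, visit = 0L,
                   group = "disease-nonconverter"),
    z
  )
  z <- as_z_matrix(z, cfg$biomarkers)
  list(
    z = z,
    truth = tibble::tibble(subject_id = ids, subtype_true = subtype,
                           stage_true = stage)
  )
}

#' Simulate a baseline cohort of raw spectral features
#'
#' Healthy controls draw
#' `raw = mu + age_slope * age + sex_offset * sex + tau * Normal(0, 1)`.
#' Disease subjects draw a latent z-cascade under their true subtype and
#' stage and map it back through the same affine model, with a configurable
#' subset of features (beta band by default) given a negative disease
#' direction so that sign inversion is exercised. Alpha-band columns are
#' generated control-like for every row (they are tabulated but never
#' modelled).
#'
#' @param cfg A [sim_config()].
#' @return A list of class `sim_cohort` with `features` (feature table
#'   tibble) and `truth` (per-subject ground truth).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  ecfg <- cfg$event_cfg
  E <- ecfg$n_events

  hc_ids <- sprintf("hc%03d", seq_len(cfg$n_hc))
  dis_ids <- sprintf("pt%03d", seq_len(cfg$n_disease))
  age_hc <- pmin(pmax(rnorm(cfg$n_hc, cfg$age_mean_hc, cfg$age_sd_hc), 45), 90)
  age_dis <- pmin(pmax(rnorm(cfg$n_disease, cfg$age_mean_dis,
                             cfg$age_sd_dis), 45), 90)
  sex_hc <- rbinom(cfg$n_hc, 1, cfg$male_p)
  sex_dis <- rbinom(cfg$n_disease, 1, cfg$male_p)

  subtype <- sample.int(length(cfg$fractions), cfg$n_disease,
                        replace = TRUE, prob = cfg$fractions)
  stage <- draw_stages(cfg$n_disease, E, cfg$stage_rho)
  G <- lapply(cfg$sequences, expected_trajectory, cfg = ecfg)

  latent_hc <- matrix(rnorm(cfg$n_hc * E / 2), nrow = cfg$n_hc)
  latent_dis <- t(vapply(seq_len(cfg$n_disease), function(j) {
    G[[subtype[j]]][, stage[j] + 1L] + rnorm(E / 2, 0, cfg$sigma)
  }, numeric(E / 2)))

  raw_block <- function(latent, age, sex) {
    n <- nrow(latent)
    f <- cfg$features
    raw <- sweep(latent, 2, cfg$direction[f], "*")
    raw <- sweep(raw, 2, cfg$tau[f], "*")
    raw <- raw + outer(age, cfg$age_slope[f]) + outer(sex, cfg$sex_offset[f])
    raw <- sweep(raw, 2, cfg$mu[f], "+")
    colnames(raw) <- f
    raw
  }
  raw_hc <- raw_block(latent_hc, age_hc, sex_hc)
  raw_dis <- raw_block(latent_dis, age_dis, sex_dis)

  # alpha columns: control-like for everyone, never modelled
  alpha_cols <- paste0("alpha_", cfg$rois)
  alpha_block <- function(n, age, sex) {
    a <- matrix(rnorm(n * length(cfg$rois), 0, 1), nrow = n)
    a <- 10 + 0.05 * age + 0.5 * outer(sex, rep(1, length(cfg$rois))) + 2 * a
    colnames(a) <- alpha_cols
    a
  }

  features <- dplyr::bind_rows(
    dplyr::bind_cols(
      tibble::tibble(subject_id = hc_ids, visit = 0L, age = age_hc,
                     sex = sex_hc, group = "HC", years = 0),
      tibble::as_tibble(as.data.frame(raw_hc)),
      tibble::as_tibble(as.data.frame(alpha_block(cfg$n_hc, age_hc, sex_hc)))
    ),
    dplyr::bind_cols(
      tibble::tibble(subject_id = dis_ids, visit = 0L, age = age_dis,
                     sex = sex_dis, group = "disease-nonconverter",
                     years = 0),
      tibble::as_tibble(as.data.frame(raw_dis)),
      tibble::as_tibble(as.data.frame(alpha_block(cfg$n_disease, age_dis,
                                                  sex_dis)))
    )
  )
  # raw powers must stay physical (nonnegative): clamp the rare negatives
  fcols <- c(cfg$features, alpha_cols)
  features[fcols] <- lapply(features[fcols], function(x) pmax(x, 0))

  truth <- tibble::tibble(
    subject_id = dis_ids, subtype_true = subtype, stage_true = stage,
    age = age_dis, sex = sex_dis
  )
  structure(list(features = features, truth = truth, cfg = cfg),
            class = "sim_cohort")
}

#' Simulate a follow-up wave for a baseline cohort
#'
#' Draws a per-subject inter-visit interval, advances the true stage by
#' `Poisson(lambda_c * dt)` (capped at `E`), switches the generating subtype
#' with probability `pi_shift` before synthesis, and regenerates raw
#' features at the new stage (age advanced by `dt`).
#'
#' @param cohort A [simulate_cohort()] result.
#' @param cfg The same [sim_config()].
#' @return The cohort with `features_followup` added and `truth` gaining
#'   `subtype_fu`, `stage_fu`, `dt_years`.
#' @export
simulate_followup <- function(cohort, cfg = cohort$cfg) {
  stopifnot(inherits(cohort, "sim_cohort"))
  set.seed(cfg$seed + 1L)
  truth <- cohort$truth
  n <- nrow(truth)
  E <- cfg$event_cfg$n_events
  dt <- pmin(pmax(rnorm(n, cfg$dt_mean, cfg$dt_sd), cfg$dt_min), cfg$dt_max)
  C <- length(cfg$sequences)
  shift <- rbinom(n, 1, cfg$pi_shift) == 1 & C > 1
  sub_fu <- truth$subtype_true
  if (any(shift)) {
    sub_fu[shift] <- vapply(truth$subtype_true[shift], function(c) {
      cands <- setdiff(seq_len(C), c)
      if (length(cands) == 1) cands else sample(cands, 1)
    }, integer(1))
  }
  lam <- rep_len(cfg$lambda, C)[sub_fu]
  stage_fu <- pmin(truth$stage_true + rpois(n, lam * dt), E)

  G <- lapply(cfg$sequences, expected_trajectory, cfg = cfg$event_cfg)
  latent <- t(vapply(seq_len(n), function(j) {
    G[[sub_fu[j]]][, stage_fu[j] + 1L] + rnorm(E / 2, 0, cfg$sigma)
  }, numeric(E / 2)))
  age_fu <- truth$age + dt
  f <- cfg$features
  raw <- sweep(latent, 2, cfg$direction[f], "*")
  raw <- sweep(raw, 2, cfg$tau[f], "*")
  raw <- raw + outer(age_fu, cfg$age_slope[f]) +
    outer(truth$sex, cfg$sex_offset[f])
  raw <- sweep(raw, 2, cfg$mu[f], "+")
  colnames(raw) <- f
  alpha_cols <- paste0("alpha_", cfg$rois)
  a <- matrix(rnorm(n * length(cfg$rois), 0, 1), nrow = n)
  a <- 10 + 0.05 * age_fu + 0.5 * outer(truth$sex, rep(1, length(cfg$rois))) +
    2 * a
  colnames(a) <- alpha_cols
  fu <- dplyr::bind_cols(
    tibble::tibble(subject_id = truth$subject_id, visit = 1L, age = age_fu,
                   sex = truth$sex, group = "disease-nonconverter",
                   years = dt),
    tibble::as_tibble(as.data.frame(pmax(raw, 0))),
    tibble::as_tibble(as.data.frame(pmax(a, 0)))
  )
  cohort$features_followup <- fu
  cohort$truth$subtype_fu <- sub_fu
  cohort$truth$stage_fu <- stage_fu
  cohort$truth$dt_years <- dt
  cohort
}

#' Simulate phenoconversion times from staged ground truth
#'
#' Conversion follows a piecewise-constant yearly hazard
#' `h(t) = h0 * exp(log(or5) / 5 * stage(t))`, with `stage(t)` linearly
#' interpolated between the baseline and follow-up visits (constant beyond
#' the last visit, and constant at baseline when no follow-up exists).
#' Subjects who do not convert are censored at the horizon.
#'
#' @param truth A ground-truth tibble with `stage_true` (and optionally
#'   `stage_fu`, `dt_years`).
#' @param cfg A [sim_config()].
#' @return A tibble of survival records: `subject_id`, `time_years`,
#'   `event`.
#' @export
simulate_conversion <- function(truth, cfg) {
  if (cfg$h0 < 0) abort("`h0` must be nonnegative.")
  set.seed(cfg$seed + 2L)
  n <- nrow(truth)
  has_fu <- "stage_fu" %in% names(truth)
  beta <- log(cfg$or5) / 5
  stage_at <- function(j, t) {
    k0 <- truth$stage_true[j]
    if (!has_fu || is.na(truth$stage_fu[j])) return(k0)
    dt <- truth$dt_years[j]
    k1 <- truth$stage_fu[j]
    ifelse(t >= dt, k1, k0 + (k1 - k0) * t / dt)
  }
  time <- numeric(n)
  event <- integer(n)
  u <- runif(n)
  grid <- seq(0, cfg$horizon, by = 1)
  for (j in seq_len(n)) {
    target <- -log(u[j])
    cum <- 0
    t_ev <- NA_real_
    for (i in seq_len(length(grid) - 1)) {
      width <- grid[i + 1] - grid[i]
      rate <- cfg$h0 * exp(beta * stage_at(j, grid[i] + width / 2))
      if (cum + rate * width >= target && rate > 0) {
        t_ev <- grid[i] + (target - cum) / rate
        break
      }
      cum <- cum + rate * width
    }
    # partial final interval up to the horizon
    if (is.na(t_ev) && cfg$horizon > max(grid)) {
      width <- cfg$horizon - max(grid)
      rate <- cfg$h0 * exp(beta * stage_at(j, max(grid) + width / 2))
      if (cum + rate * width >= target && rate > 0) {
        t_ev <- max(grid) + (target - cum) / rate
      }
    }
    if (!is.na(t_ev) && t_ev <= cfg$horizon) {
      time[j] <- t_ev
      event[j] <- 1L
    } else {
      time[j] <- cfg$horizon
      event[j] <- 0L
    }
  }
  tibble::tibble(subject_id = truth$subject_id,
                 time_years = pmax(time, 1e-6), event = event)
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper: baseline cohort, follow-up wave, conversion
#' outcomes, and group labels (`disease-converter` /
#' `disease-nonconverter`) applied consistently across tables.
#'
#' @param cfg A [sim_config()].
#' @param followup Simulate the follow-up wave (default `TRUE`).
#' @return A list of class `sim_study`: `features`, `features_followup`,
#'   `survival`, `truth`, `cfg`.
#' @examples
#' study <- simulate_study(sim_config(n_hc = 40, n_disease = 60, seed = 9))
#' dplyr::count(study$features, group)
#' @export
simulate_study <- function(cfg, followup = TRUE) {
  cohort <- simulate_cohort(cfg)
  if (followup) cohort <- simulate_followup(cohort, cfg)
  surv <- simulate_conversion(cohort$truth, cfg)
  lab <- ifelse(surv$event == 1, "disease-converter", "disease-nonconverter")
  names(lab) <- surv$subject_id
  relabel <- function(df) {
    idx <- df$subject_id %in% names(lab)
    df$group[idx] <- lab[df$subject_id[idx]]
    df
  }
  cohort$features <- relabel(cohort$features)
  if (!is.null(cohort$features_followup)) {
    cohort$features_followup <- relabel(cohort$features_followup)
  }
  cohort$truth$converted <- as.integer(surv$event[match(
    cohort$truth$subject_id, surv$subject_id)])
  structure(
    list(features = cohort$features,
         features_followup = cohort$features_followup,
         survival = surv, truth = cohort$truth, cfg = cfg),
    class = "sim_study"
  )
}
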