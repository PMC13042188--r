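test_that("expected trajectories pass through the event knots", {
  cfg <- event_config(c("a", "b", "c"))
  G0 <- expected_trajectory(1:6, cfg)
  expect_true(all(G0[, 1] == 0))
  # biomarker a: events at positions 1 and 2 -> hits z1 then z2
  expect_equal(unname(G0["a", 2]), 1.5)
  expect_equal(unname(G0["a", 3]), 3)
  # interpolation between (p2, z2) and (E, z_max):
  # biomarker a events at positions 2 and 4 of E = 6 -> g(5) = 4
  s <- c(3, 1, 5, 2, 4, 6)
  expect_equal(unname(expected_trajectory(s, cfg)["a", 6]), 4.0)
  # monotone non-decreasing in stage for every biomarker
  for (rep in 1:5) {
    set.seed(rep)
    si <- eegsustain:::random_sequence(cfg)
    G <- expected_trajectory(si, cfg)
    expect_true(all(diff(t(G)) >= -1e-12))
  }
})

test_that("sequence validity enforces the within-biomarker threshold order", {
  cfg <- event_config(c("a", "b"))
  expect_true(valid_sequence(c(1, 2, 3, 4), cfg))
  expect_false(valid_sequence(c(2, 1, 3, 4), cfg))  # z2 of a before z1
  expect_false(valid_sequence(c(1, 2, 3), cfg))
  for (rep in 1:20) {
    expect_true(valid_sequence(eegsustain:::random_sequence(cfg), cfg))
  }
})

test_that("subject likelihood equals the brute-force stage sum", {
  cfg <- event_config("only")  # one biomarker, E = 2
  s <- c(1L, 2L)
  z <- 1.2
  sl <- subject_loglik(setNames(z, "only"), s, cfg, sigma = 0.8)
  g <- expected_trajectory(s, cfg)[1, ]
  manual <- log(mean(dnorm(z, mean = g, sd = 0.8)))
  expect_equal(sl$loglik, manual, tolerance = 1e-12)
  post <- dnorm(z, g, 0.8)
  expect_equal(sl$stage_posterior[1, ], post / sum(post), tolerance = 1e-12)
})

test_that("stage posterior peaks where the trajectory matches the data", {
  cfg <- event_config(paste0("b", 1:3))
  s <- eegsustain:::random_sequence(cfg)
  G <- expected_trajectory(s, cfg)
  sl0 <- subject_loglik(rep(0, 3), s, cfg)
  expect_equal(which.max(sl0$stage_posterior[1, ]), 1L)  # stage 0
  slE <- subject_loglik(G[, ncol(G)], s, cfg)
  expect_equal(which.max(slE$stage_posterior[1, ]), ncol(G))
  expect_error(subject_loglik(rep(0, 3), s, cfg, sigma = 0), "positive")
  expect_error(subject_loglik(c(0, NA, 0), s, cfg), "finite")
})

test_that("the fitted ordering matches exhaustive-enumeration ML at E = 6", {
  cfg <- event_config(paste0("b", 1:3))
  truth <- c(1L, 3L, 2L, 5L, 4L, 6L)
  sim <- simulate_z_cohort(200, cfg, sequences = list(truth), fractions = 1,
                           stage_rho = 0, sigma = 1, seed = 61)
  m <- sustain_fit(sim$z, C = 1, cfg = cfg,
                   control = sustain_control(n_starts = 5, mcmc_iter = 300),
                   seed = 62)
  Z <- eegsustain:::as_z_rows(sim$z, cfg)
  seqs <- eegsustain:::enumerate_sequences(cfg)
  expect_equal(length(seqs), 90)  # 6!/2^3 orderings satisfy the constraint
  lls <- vapply(seqs, function(s) {
    sum(eegsustain:::marginal_loglik(Z, expected_trajectory(s, cfg),
                                     rep(1, 3)))
  }, numeric(1))
  best <- seqs[[which.max(lls)]]
  expect_equal(as.integer(m$sequences[[1]]), as.integer(best))
  expect_equal(m$loglik, max(lls), tolerance = 1e-9)
})

test_that("an all-zero cohort triggers the flat-likelihood warning", {
  cfg <- event_config(paste0("b", 1:3))
  z <- matrix(0, nrow = 30, ncol = 3,
              dimnames = list(NULL, cfg$biomarkers))
  expect_warning(
    sustain_fit(z, C = 1, cfg = cfg,
                control = sustain_control(n_starts = 3, mcmc_iter = 0),
                seed = 1),
    "[Ff]lat")
})

test_that("fit validates subject count against subtype count", {
  cfg <- event_config(c("a", "b"))
  z <- matrix(rnorm(2 * 2), nrow = 2, dimnames = list(NULL, cfg$biomarkers))
  expect_error(sustain_fit(z, C = 3, cfg = cfg), "Fewer subjects")
})

test_that("placement posterior equals brute-force normalization (E = 4)", {
  cfg <- event_config(c("a", "b"))
  seqs <- list(c(1L, 2L, 3L, 4L), c(3L, 4L, 1L, 2L))
  model <- structure(
    list(sequences = seqs, fractions = c(0.6, 0.4), cfg = cfg,
         sigma = c(1, 1), loglik = NA, samples = list(NULL, NULL),
         n_subjects = 0, C = 2, control = NULL, seed = NULL,
         flat = FALSE, converged = TRUE),
    class = "progression_model")
  z <- matrix(c(1.1, -0.4), nrow = 1, dimnames = list(NULL, c("a", "b")))
  pl <- sustain_place(z, model)
  post <- attr(pl, "posterior")
  manual <- matrix(0, 2, 5)
  for (c in 1:2) {
    G <- expected_trajectory(seqs[[c]], cfg)
    for (k in 0:4) {
      manual[c, k + 1] <- model$fractions[c] / 5 *
        prod(dnorm(z, G[, k + 1], 1))
    }
  }
  manual <- manual / sum(manual)
  expect_equal(post[1, , ], manual, tolerance = 1e-12)
})

test_that("placement applies the stage-0 subtype rule and exact matches", {
  cfg <- event_config(paste0("b", 1:3))
  seqs <- list(eegsustain:::random_sequence(cfg))
  set.seed(8)
  seqs[[2]] <- eegsustain:::random_sequence(cfg)
  model <- structure(
    list(sequences = seqs, fractions = c(0.5, 0.5), cfg = cfg,
         sigma = rep(1, 3), loglik = NA, samples = list(NULL, NULL),
         n_subjects = 0, C = 2, control = NULL, seed = NULL,
         flat = FALSE, converged = TRUE),
    class = "progression_model")
  z0 <- matrix(0, 1, 3, dimnames = list(NULL, cfg$biomarkers))
  pl0 <- sustain_place(z0, model)
  expect_equal(pl0$subtype, 0L)
  expect_equal(pl0$stage, 0L)
  expect_true(pl0$max_z_below_z1)

  G2 <- expected_trajectory(seqs[[2]], cfg)
  zk <- matrix(G2[, 5], 1, dimnames = list(NULL, cfg$biomarkers))
  plk <- sustain_place(zk, model)
  expect_equal(plk$subtype, 2L)
  expect_equal(plk$stage, 4L)

  # hard pre-filter forces sub-threshold rows to stage 0
  zq <- matrix(rep(1.2, 3), 1, dimnames = list(NULL, cfg$biomarkers))
  hard <- sustain_place(zq, model, hard_zero = TRUE)
  expect_equal(hard$stage, 0L)
  expect_equal(hard$subtype, 0L)
})

test_that("noise-free staged rows place at their true stages", {
  cfg <- event_config(paste0("b", 1:4))
  sim <- simulate_z_cohort(60, cfg, stage_rho = 0, sigma = 0, seed = 17)
  model <- structure(
    list(sequences = default_true_sequences(cfg, 2),
         fractions = c(0.5, 0.5), cfg = cfg, sigma = rep(1, 4),
         loglik = NA, samples = list(NULL, NULL), n_subjects = 60, C = 2,
         control = NULL, seed = NULL, flat = FALSE, converged = TRUE),
    class = "progression_model")
  pl <- sustain_place(sim$z, model)
  expect_equal(pl$stage, sim$truth$stage_true)
  staged <- sim$truth$stage_true > 0
  expect_equal(pl$subtype[staged], sim$truth$subtype_true[staged])
  # all-sub-threshold rows get stage 0 under the default configuration
  expect_true(all(pl$stage[pl$max_z_below_z1] == 0))
})

test_that("scaling a noise-free row up never lowers its MAP stage", {
  cfg <- event_config(paste0("b", 1:3))
  s <- eegsustain:::random_sequence(cfg)
  model <- structure(
    list(sequences = list(s), fractions = 1, cfg = cfg, sigma = rep(1, 3),
         loglik = NA, samples = list(NULL), n_subjects = 0, C = 1,
         control = NULL, seed = NULL, flat = FALSE, converged = TRUE),
    class = "progression_model")
  G <- expected_trajectory(s, cfg)
  base <- G[, 4]
  stages <- vapply(c(1, 1.2, 1.5, 2), function(lam) {
    z <- matrix(lam * base, 1, dimnames = list(NULL, cfg$biomarkers))
    sustain_place(z, model)$stage
  }, integer(1))
  expect_true(all(diff(stages) >= 0))
})

test_that("fitted quantities ignore subject order", {
  cfg <- event_config(paste0("b", 1:3))
  sim <- simulate_z_cohort(80, cfg, sequences = list(1:6), fractions = 1,
                           stage_rho = 0.1, sigma = 1, seed = 5)
  ctl <- sustain_control(n_starts = 3, mcmc_iter = 100)
  m1 <- sustain_fit(sim$z, C = 1, cfg = cfg, control = ctl, seed = 9)
  perm <- sample(nrow(sim$z))
  m2 <- sustain_fit(sim$z[perm, ], C = 1, cfg = cfg, control = ctl, seed = 9)
  expect_equal(m1$sequences[[1]], m2$sequences[[1]])
  expect_equal(m1$loglik, m2$loglik, tolerance = 1e-9)
})

test_that("subtype-count selection validates its inputs", {
  cfg <- event_config(c("a", "b"))
  z <- matrix(rnorm(8), nrow = 4, dimnames = list(NULL, cfg$biomarkers))
  expect_error(select_subtypes(z, c_max = 1, cfg = cfg), "at least 2")
  z3 <- matrix(rnorm(6), nrow = 3, dimnames = list(NULL, cfg$biomarkers))
  expect_error(select_subtypes(z3, c_max = 2, folds = 5, cfg = cfg),
               "at least as many subjects")
})
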