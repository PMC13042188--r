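test_that("Kaplan-Meier matches hand product-limit computation", {
  # all censored -> survival stays 1
  rec <- tibble::tibble(subject_id = letters[1:4],
                        time_years = c(1, 2, 3, 4), event = 0)
  km <- km_fit(rec)
  expect_true(all(km$estimate == 1))

  # one event among four -> (n-1)/n
  rec2 <- tibble::tibble(subject_id = letters[1:4],
                         time_years = c(2, 3, 4, 5), event = c(1, 0, 0, 0))
  km2 <- km_fit(rec2)
  expect_equal(min(km2$estimate), 0.75, tolerance = 1e-12)

  # hand-built 6-record mix: events at 1 (n=6), 3 (n=4), censor at 2, 3, 5
  rec3 <- tibble::tibble(
    subject_id = letters[1:6],
    time_years = c(1, 2, 3, 3, 4, 5),
    event = c(1, 0, 1, 0, 1, 0))
  km3 <- km_fit(rec3)
  # S(1) = 5/6; S(3) = 5/6 * 3/4 (censored-at-3 subject still at risk);
  # S(4) = 5/6 * 3/4 * 1/2
  expect_equal(km3$estimate[km3$time == 1], 5 / 6, tolerance = 1e-12)
  expect_equal(km3$estimate[km3$time == 3], 5 / 6 * 3 / 4,
               tolerance = 1e-12)
  expect_equal(km3$estimate[km3$time == 4], 5 / 6 * 3 / 4 * 1 / 2,
               tolerance = 1e-12)
  expect_true(all(km3$conf.low >= 0 & km3$conf.high <= 1, na.rm = TRUE))
})

test_that("KM without censoring equals the empirical survival function", {
  set.seed(2)
  t_ <- sort(sample(1:20, 10, replace = TRUE)) + runif(10)
  rec <- tibble::tibble(subject_id = sprintf("s%d", 1:10),
                        time_years = t_, event = 1)
  km <- km_fit(rec)
  emp <- vapply(km$time, function(tt) mean(t_ > tt), numeric(1))
  expect_equal(km$estimate, emp, tolerance = 1e-12)
})

test_that("KM stratifies and merges labels", {
  rec <- tibble::tibble(
    subject_id = sprintf("s%d", 1:9),
    time_years = c(1, 2, 3, 4, 5, 6, 7, 7.5, 7.5),
    event = c(1, 1, 0, 1, 0, 0, 1, 0, 0),
    followup_subtype = c(2, 2, 2, 0, 1, 0, 2, 1, 0))
  km <- km_fit(rec, "followup_subtype",
               merge = list("0or1" = c("0", "1")))
  expect_setequal(unique(km$stratum), c("0or1", "2"))
})

test_that("log-rank behaves on cloned groups and counts df", {
  base <- tibble::tibble(subject_id = sprintf("a%d", 1:6),
                         time_years = c(1, 2, 3, 4, 5, 6),
                         event = c(1, 0, 1, 0, 1, 0), g = "x")
  clone <- dplyr::mutate(base, subject_id = sprintf("b%d", 1:6), g = "y")
  lr <- logrank_test(dplyr::bind_rows(base, clone), "g")
  expect_equal(lr$statistic, 0, tolerance = 1e-9)
  expect_equal(lr$p.value, 1, tolerance = 1e-9)

  three <- dplyr::bind_rows(base, clone,
                            dplyr::mutate(base, subject_id = sprintf("c%d", 1:6),
                                          g = "z", time_years = time_years / 2))
  lr3 <- logrank_test(three, "g")
  expect_equal(lr3$df, 2L)
  expect_equal(nrow(lr3$pairwise), 3L)

  expect_error(logrank_test(base, "g"), "two groups")
})

test_that("log-rank matches the hand observed-minus-expected computation", {
  # two groups, single event time: group x has the only event at t=1 with
  # 2 of 4 at risk -> O - E = 1 - 0.5, V = 0.25 -> chi-square = 1
  rec <- tibble::tibble(
    subject_id = c("x1", "x2", "y1", "y2"),
    time_years = c(1, 5, 5, 5), event = c(1, 0, 0, 0),
    g = c("x", "x", "y", "y"))
  lr <- logrank_test(rec, "g")
  d1 <- 1; n1 <- 2; n <- 4
  e1 <- d1 * n1 / n
  v <- d1 * (n1 / n) * (1 - n1 / n) * (n - d1) / (n - 1)
  expect_equal(lr$statistic, (1 - e1)^2 / v, tolerance = 1e-9)

  # adding a subject censored before the first event changes nothing
  rec2 <- dplyr::bind_rows(rec, tibble::tibble(
    subject_id = "y3", time_years = 0.5, event = 0, g = "y"))
  expect_equal(logrank_test(rec2, "g")$statistic, lr$statistic,
               tolerance = 1e-9)
})

test_that("Fisher's exact test matches enumeration and conventions", {
  # balanced table -> p = 1
  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2))$p.value, 1)

  # direct enumeration over the 5 admissible tables with margins (4,4,4,4)
  tab <- matrix(c(3, 1, 1, 3), 2, byrow = TRUE)
  x <- 0:4
  pr <- dhyper(x, 4, 4, 4)
  pobs <- dhyper(3, 4, 4, 4)
  expect_equal(fisher_exact(tab)$p.value, sum(pr[pr <= pobs + 1e-12]),
               tolerance = 1e-12)

  # equals stats::fisher.test (the same two-sided convention) on random
  # tables with totals up to 200
  set.seed(5)
  for (i in 1:25) {
    m <- matrix(rpois(4, 12), 2)
    if (sum(m) == 0 || sum(m) > 200) next
    expect_equal(fisher_exact(m)$p.value,
                 stats::fisher.test(m)$p.value, tolerance = 1e-9)
  }

  # the doubling convention is at least the one-sided tail, at most 1
  d <- fisher_exact(tab, method = "doubling")
  expect_lte(d$p.value, 1)
  expect_error(fisher_exact(matrix(c(-1, 1, 1, 1), 2)), "nonnegative")
})

test_that("BH adjustment matches hand computation and is idempotent", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(fdr_adjust(0.2), 0.2)
  expect_equal(fdr_adjust(rep(1, 4)), rep(1, 4))
  expect_equal(fdr_adjust(numeric(0)), numeric(0))
  p <- c(0.001, 0.01, 0.04, 0.2, 0.9)
  adj <- fdr_adjust(p)
  expect_true(all(diff(adj[order(p)]) >= 0))
  # re-adjusting a tied (step-up-flattened) block is stable
  flat <- fdr_adjust(c(0.01, 0.02, 0.03))
  expect_equal(fdr_adjust(flat), flat)
  expect_error(fdr_adjust(c(0.1, 1.4)), "\\[0, 1\\]")
})

test_that("stage-outcome logistic handles null, recovery and separation", {
  set.seed(14)
  # outcomes independent of stage -> OR/5 near 1, inside its own CI
  s <- sample(0:24, 600, replace = TRUE)
  y <- rbinom(600, 1, 0.3)
  fit <- stage_outcome_logistic(data.frame(stage = s, converted = y))
  expect_false(fit$separated)
  expect_true(fit$conf.low <= 1 && fit$conf.high >= 1)

  # complete separation flagged
  ss <- c(0:9, 15:24)
  yy <- c(rep(0, 10), rep(1, 10))
  sep <- stage_outcome_logistic(data.frame(stage = ss, converted = yy))
  expect_true(sep$separated)
  expect_true(is.na(sep$or_per_5))

  expect_error(stage_outcome_logistic(
    data.frame(stage = rep(1, 5), converted = c(0, 1, 0, 1, 0))),
    "distinct stages")
})

test_that("survival records join placement and longitudinal strata", {
  surv <- tibble::tibble(subject_id = c("a", "b"), time_years = c(2, 3),
                         event = c(1, 0))
  pl <- tibble::tibble(subject_id = c("a", "b"), subtype = c(2L, 0L),
                       stage = c(5L, 0L))
  d <- make_pairs(c(2L, 0L), c(2L, 0L), stage_bl = c(5L, 0L),
                  stage_fu = c(9L, 0L), dt_years = 2)
  d$subject_id <- c("a", "b")
  sr <- survival_records(surv, pl, stage_deltas(d))
  expect_equal(sr$baseline_subtype, c(2L, 0L))
  expect_equal(sr$velocity_class, c("high", "low"))
})
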