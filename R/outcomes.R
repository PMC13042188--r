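#' Kaplan-Meier conversion-free survival by stratum
#'
#' Product-limit estimate of conversion-free survival with Greenwood
#' standard errors and log-log 95% confidence intervals, via
#' [survival::survfit()]. Subjects censored at an event time are counted at
#' risk for that time's events.
#'
#' @param records A survival tibble: `subject_id`, `time_years` (> 0),
#'   `event` (1 = phenoconverted, 0 = censored), and stratum label columns.
#' @param stratum Name of the stratum column (`NULL` for a single pooled
#'   curve).
#' @param merge Optional named list collapsing labels, e.g.
#'   `list("0or1" = c("0", "1"))` for the follow-up-status stratification
#'   that groups subtype 0 and 1 against subtype 2.
#' @return A `km_curve` tibble: `stratum`, `time`, `n_risk`, `n_event`,
#'   `n_censor`, `estimate`, `std.error`, `conf.low`, `conf.high`.
#' @examples
#' rec <- tibble::tibble(subject_id = letters[1:4],
#'                       time_years = c(2, 3, 4, 5),
#'                       event = c(1, 0, 0, 0))
#' km_fit(rec)
#' @export
km_fit <- function(records, stratum = NULL, merge = NULL) {
  check_survival_records(records)
  records <- tibble::as_tibble(records)
  if (is.null(stratum)) {
    records$.stratum <- "all"
  } else {
    records$.stratum <- as.character(records[[stratum]])
  }
  if (!is.null(merge)) {
    for (new in names(merge)) {
      records$.stratum[records$.stratum %in% as.character(merge[[new]])] <- new
    }
  }
  empty <- table(factor(records$.stratum))
  if (any(empty == 0)) warn("Empty stratum skipped.")
  fit <- survival::survfit(
    survival::Surv(time_years, event) ~ .stratum, data = records,
    conf.type = "log-log")
  s <- summary(fit, censored = TRUE)
  strat <- if (is.null(s$strata)) rep("all", length(s$time)) else
    sub("^\\.stratum=", "", as.character(s$strata))
  out <- tibble::tibble(
    stratum = strat, time = s$time, n_risk = s$n.risk, n_event = s$n.event,
    n_censor = s$n.censor, estimate = s$surv, std.error = s$std.err,
    conf.low = s$lower, conf.high = s$upper
  )
  class(out) <- c("km_curve", class(out))
  out
}

check_survival_records <- function(records) {
  need <- c("time_years", "event")
  if (!all(need %in% colnames(records))) {
    abort("Survival records need `time_years` and `event` columns.")
  }
  if (any(records$time_years <= 0)) abort("All times must be positive.")
  if (!all(records$event %in% c(0, 1))) abort("`event` must be 0 or 1.")
  invisible(records)
}

#' Log-rank test of conversion-free survival
#'
#' Global observed-minus-expected log-rank statistic over pooled event
#' times ([survival::survdiff()]) plus all pairwise group comparisons with
#' false-discovery-rate adjustment.
#'
#' @inheritParams km_fit
#' @param stratum Name of the grouping column (>= 2 non-empty groups).
#' @return A list of class `logrank_result`: `statistic`, `df`, `p.value`,
#'   and a `pairwise` tibble (`group1`, `group2`, `statistic`, `p.value`,
#'   `p.adjusted`).
#' @export
logrank_test <- function(records, stratum, merge = NULL) {
  check_survival_records(records)
  records <- tibble::as_tibble(records)
  records$.stratum <- as.character(records[[stratum]])
  if (!is.null(merge)) {
    for (new in names(merge)) {
      records$.stratum[records$.stratum %in% as.character(merge[[new]])] <- new
    }
  }
  groups <- sort(unique(records$.stratum))
  if (length(groups) < 2) abort("Log-rank needs at least two groups.")
  sd_ <- survival::survdiff(
    survival::Surv(time_years, event) ~ .stratum, data = records)
  df <- length(groups) - 1L
  pairs <- combn(groups, 2)
  pw <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    sub <- records[records$.stratum %in% pairs[, i], , drop = FALSE]
    d <- survival::survdiff(
      survival::Surv(time_years, event) ~ .stratum, data = sub)
    tibble::tibble(group1 = pairs[1, i], group2 = pairs[2, i],
                   statistic = d$chisq,
                   p.value = pchisq(d$chisq, 1, lower.tail = FALSE))
  })
  pw$p.adjusted <- fdr_adjust(pw$p.value)
  structure(
    list(statistic = sd_$chisq, df = df,
         p.value = pchisq(sd_$chisq, df, lower.tail = FALSE),
         pairwise = pw, groups = groups),
    class = "logrank_result"
  )
}

#' @export
print.logrank_result <- function(x, ...) {
  cat("<logrank_result> chi-square =", format(x$statistic), "df =", x$df,
      "p =", format(x$p.value), "\n")
  print(x$pairwise)
  invisible(x)
}

#' Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric test with fixed margins. The default two-sided
#' p-value follows the point-probability rule: the sum of the probabilities
#' of all tables no more probable than the observed one (within 1e-12
#' slack), which is also the convention of [stats::fisher.test()]. The
#' tail-doubling alternative (`2 * min(one-sided)`, capped at 1) is exposed
#' as `method = "doubling"`.
#'
#' @param table A 2x2 matrix/data frame of counts, or the count `a` with
#'   `b`, `c`, `d` supplied.
#' @param b,c,d Remaining cells when `table` is given as a scalar count.
#' @param method `"minlike"` (default) or `"doubling"`.
#' @return A tibble with `p.value`, `odds_ratio` (sample OR), and `method`.
#' @examples
#' fisher_exact(matrix(c(51, 0, 45, 19), 2, byrow = TRUE))
#' @export
fisher_exact <- function(table, b = NULL, c = NULL, d = NULL,
                         method = c("minlike", "doubling")) {
  method <- match.arg(method)
  if (is.null(dim(table))) {
    table <- matrix(c(table, b, c, d), 2, 2, byrow = TRUE)
  }
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) abort("Need a 2x2 table.")
  if (any(table < 0) || any(table != round(table))) {
    abort("Counts must be nonnegative integers.")
  }
  if (sum(table) == 0) abort("Table total must be positive.")
  a <- table[1, 1]
  m <- sum(table[1, ]); n2 <- sum(table[2, ]); k <- sum(table[, 1])
  lo <- max(0, k - n2); hi <- min(k, m)
  x <- lo:hi
  pr <- dhyper(x, m, n2, k)
  p_obs <- dhyper(a, m, n2, k)
  if (method == "minlike") {
    p <- sum(pr[pr <= p_obs * (1 + 1e-12)])
  } else {
    lower <- sum(pr[x <= a])
    upper <- sum(pr[x >= a])
    p <- min(1, 2 * min(lower, upper))
  }
  or <- (table[1, 1] * table[2, 2]) / (table[1, 2] * table[2, 1])
  tibble::tibble(p.value = min(p, 1), odds_ratio = or, method = method)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjustment with monotonicity enforcement (a thin, validated
#' wrapper over [stats::p.adjust()]).
#'
#' @param p Numeric vector of p-values in \\[0, 1\\].
#' @return Adjusted p-values in the input order (empty in, empty out).
#' @export
fdr_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.na(p) & (p < 0 | p > 1))) abort("p-values must lie in [0, 1].")
  p.adjust(p, method = "BH")
}

#' Logistic association of phenoconversion with model stage
#'
#' Single-predictor logistic regression of the conversion indicator on
#' stage, reported as the odds ratio per 5 stages (`exp(5 * beta)`) with a
#' Wald p-value. Complete separation is detected and flagged instead of
#' reporting a spuriously finite estimate.
#'
#' @param data A data frame; or omit and pass `stage` / `outcome` vectors.
#' @param stage,outcome Column names (tidy usage) or numeric vectors.
#' @return A tibble with `or_per_5`, `conf.low`, `conf.high` (Wald 95%),
#'   `p.value`, `n`, `separated`.
#' @export
stage_outcome_logistic <- function(data = NULL, stage = "stage",
                                   outcome = "converted") {
  if (is.data.frame(data)) {
    s <- data[[stage]]
    y <- data[[outcome]]
  } else {
    s <- data %||% stage
    y <- outcome
    if (is.character(s) || is.character(y)) {
      abort("Pass a data frame plus column names, or two numeric vectors.")
    }
  }
  ok <- !is.na(s) & !is.na(y)
  s <- s[ok]; y <- as.numeric(y[ok])
  if (length(unique(s)) < 2 || length(unique(y)) < 2) {
    abort("Need at least two distinct stages and both outcome classes.")
  }
  fit <- suppressWarnings(glm(y ~ s, family = binomial(),
                              control = list(epsilon = 1e-10, maxit = 100)))
  beta <- coef(fit)[2]
  se <- sqrt(diag(vcov(fit)))[2]
  sep <- !fit$converged || abs(beta) > 15 || se > 100 ||
    separation_check(s, y)
  if (sep) {
    return(tibble::tibble(or_per_5 = NA_real_, conf.low = NA_real_,
                          conf.high = NA_real_, p.value = NA_real_,
                          n = length(y), separated = TRUE))
  }
  z <- beta / se
  tibble::tibble(
    or_per_5 = exp(5 * beta),
    conf.low = exp(5 * (beta - 1.96 * se)),
    conf.high = exp(5 * (beta + 1.96 * se)),
    p.value = 2 * pnorm(-abs(z)),
    n = length(y), separated = FALSE
  )
}

# complete separation: some stage cut has all converters above and all
# non-converters below (or vice versa)
separation_check <- function(s, y) {
  max0 <- suppressWarnings(max(s[y == 0]))
  min1 <- suppressWarnings(min(s[y == 1]))
  max1 <- suppressWarnings(max(s[y == 1]))
  min0 <- suppressWarnings(min(s[y == 0]))
  (is.finite(max0) && is.finite(min1) && max0 < min1) ||
    (is.finite(max1) && is.finite(min0) && max1 < min0)
}

#' Build survival records from placements and outcomes
#'
#' Joins conversion outcomes with stratum labels: baseline subtype,
#' follow-up subtype group, and velocity class when longitudinal data are
#' supplied.
#'
#' @param survival Tibble `subject_id`, `time_years`, `event`.
#' @param placement Baseline [sustain_place()] tibble.
#' @param deltas Optional [stage_deltas()] tibble (adds `subtype_fu` and
#'   `velocity_class` strata).
#' @return A survival-record tibble with stratum columns.
#' @export
survival_records <- function(survival, placement, deltas = NULL) {
  check_survival_records(survival)
  out <- dplyr::inner_join(
    tibble::as_tibble(survival),
    dplyr::select(tibble::as_tibble(placement), "subject_id",
                  baseline_subtype = "subtype"),
    by = "subject_id")
  if (!is.null(deltas)) {
    out <- dplyr::left_join(
      out,
      dplyr::select(tibble::as_tibble(deltas), "subject_id",
                    followup_subtype = "subtype_fu", "velocity_class"),
      by = "subject_id")
  }
  out
}
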