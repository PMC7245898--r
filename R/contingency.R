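#' Two-by-two event-by-arm table
#'
#' Container for a fourfold table with the layout `a` = intervention with
#' event, `b` = intervention without event, `c` = control with event,
#' `d` = control without event.
#'
#' @param a,b,c,d Non-negative integer counts.
#' @return An object of class `fourfold_table`.
#' @export
#' @examples
#' fourfold_table(2, 11, 25, 16) # low cardiac output by arm
fourfold_table <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    abort_levo("fourfold counts must be non-negative integers",
               "levoCEA_validation_error")
  }
  counts <- as.integer(counts)
  structure(list(a = counts[1], b = counts[2], c = counts[3],
                 d = counts[4]),
            class = "fourfold_table")
}

#' @export
print.fourfold_table <- function(x, ...) {
  m <- as.matrix(x)
  cat("fourfold table (rows: arm, cols: event yes/no)\n")
  print(m)
  invisible(x)
}

#' @export
as.matrix.fourfold_table <- function(x, ...) {
  matrix(c(x$a, x$b, x$c, x$d), nrow = 2, byrow = TRUE,
         dimnames = list(arm_levels, c("event", "no_event")))
}

#' Tabulate a complication flag by arm
#'
#' @param records A cohort tibble.
#' @param event One of the flag columns: `"noaf"`, `"lco"`,
#'   `"cardiogenic_shock"`, `"renal_failure"`, `"prolonged_mv"`, `"death"`.
#' @return A [fourfold_table()].
#' @export
#' @examples
#' tabulate_event(reference_cohort(), "lco")
tabulate_event <- function(records, event) {
  if (!is.character(event) || length(event) != 1 ||
      !event %in% cohort_flags) {
    abort_levo(
      sprintf("unknown event flag `%s`; expected one of %s",
              paste(event, collapse = ","),
              paste(cohort_flags, collapse = ", ")),
      "levoCEA_domain_error"
    )
  }
  records <- validate_cohort(records)
  ev <- records[[event]]
  int <- records$arm == "intervention"
  fourfold_table(
    a = sum(ev & int), b = sum(!ev & int),
    c = sum(ev & !int), d = sum(!ev & !int)
  )
}

#' Per-arm event percentages
#'
#' Percentages of patients with the event in each arm, reported at one
#' decimal place with half-up rounding (the convention used for tabulated
#' shares such as 2/13 = 15.4).
#'
#' @param t A [fourfold_table()].
#' @param digits Decimal places for reporting (default 1).
#' @return Named vector `c(intervention = , control = )`.
#' @export
#' @examples
#' arm_percentages(fourfold_table(2, 11, 25, 16))
arm_percentages <- function(t, digits = 1) {
  stopifnot(inherits(t, "fourfold_table"))
  n_int <- t$a + t$b
  n_ctl <- t$c + t$d
  if (n_int == 0 || n_ctl == 0) {
    abort_levo("cannot compute a percentage for an empty arm",
               "levoCEA_undefined_proportion_error")
  }
  c(intervention = round_half_up(100 * t$a / n_int, digits),
    control = round_half_up(100 * t$c / n_ctl, digits))
}

#' Stratify an event table by LVEF stratum
#'
#' Builds one fourfold table per LVEF stratum (35--40% first, then < 35%),
#' the layout used by the stratified Mantel-Haenszel test.
#'
#' @inheritParams tabulate_event
#' @return Named list of [fourfold_table()] objects.
#' @export
stratify_event <- function(records, event) {
  records <- validate_cohort(records)
  strata <- lapply(lvef_levels, function(s) {
    tabulate_event(records[records$lvef_stratum == s, , drop = FALSE], event)
  })
  names(strata) <- lvef_levels
  strata
}

new_test_result <- function(method, statistic, p_value, sidedness,
                            continuity_correction) {
  stopifnot(p_value >= 0, p_value <= 1)
  tibble(
    method = method,
    statistic = statistic,
    p_value = p_value,
    sidedness = sidedness,
    continuity_correction = continuity_correction
  )
}

#' Pearson chi-square test on a fourfold table
#'
#' Two-sided chi-square test of association with one degree of freedom;
#' with `correction = TRUE` the Yates continuity correction is applied.
#'
#' @param t A [fourfold_table()].
#' @param correction Apply the Yates continuity correction? Default `FALSE`.
#' @return A one-row tibble with `method`, `statistic`, `p_value`,
#'   `sidedness` and `continuity_correction`.
#' @export
#' @examples
#' pearson_chi2(fourfold_table(2, 11, 25, 16))
pearson_chi2 <- function(t, correction = FALSE) {
  stopifnot(inherits(t, "fourfold_table"))
  m <- as.matrix(t)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    abort_levo("degenerate table: a marginal total is zero",
               "levoCEA_degenerate_table_error")
  }
  res <- suppressWarnings(chisq.test(m, correct = correction))
  new_test_result("pearson_chi2", unname(res$statistic), res$p.value,
                  "two_sided", correction)
}

#' Fisher exact test on a fourfold table
#'
#' The one-sided p-value is the hypergeometric tail probability of tables at
#' least as extreme as the observed one in the observed direction (determined
#' by the sign of `a - E[a]`); the two-sided p-value sums the point
#' probabilities of all tables no more probable than the observed one.
#'
#' @param t A [fourfold_table()].
#' @param sidedness `"one_sided"` or `"two_sided"`.
#' @return A one-row test-result tibble (no statistic: the test is reported
#'   as a p-value only).
#' @export
#' @examples
#' fisher_exact(fourfold_table(0, 13, 10, 31), "one_sided")
fisher_exact <- function(t, sidedness = c("two_sided", "one_sided")) {
  stopifnot(inherits(t, "fourfold_table"))
  sidedness <- match.arg(sidedness)
  m <- as.matrix(t)
  if (sidedness == "two_sided") {
    p <- fisher.test(m)$p.value
  } else {
    expected_a <- (t$a + t$b) * (t$a + t$c) / sum(m)
    alt <- if (t$a <= expected_a) "less" else "greater"
    p <- fisher.test(m, alternative = alt)$p.value
  }
  new_test_result("fisher_exact", NA_real_, min(p, 1), sidedness, FALSE)
}

#' Mantel-Haenszel test over LVEF strata
#'
#' Stratified chi-square test of a common association across 2x2 strata,
#' using the conditional hypergeometric moments per stratum
#' (variance denominator N^2 (N - 1)). The continuity correction is on by
#' default: that convention reproduces the tabulated stratified p-value of
#' 0.01 for the low-cardiac-output analysis, whereas the uncorrected
#' statistic gives p = 0.005.
#'
#' @param strata A named list of [fourfold_table()] objects (>= 1), e.g. from
#'   [stratify_event()].
#' @param correction Apply the continuity correction? Default `TRUE`.
#' @return A one-row test-result tibble.
#' @export
#' @examples
#' mantel_haenszel(stratify_event(reference_cohort(), "lco"))
mantel_haenszel <- function(strata, correction = TRUE) {
  if (length(strata) < 1 ||
      !all(vapply(strata, inherits, logical(1), "fourfold_table"))) {
    abort_levo("`strata` must be a non-empty list of fourfold tables",
               "levoCEA_validation_error")
  }
  totals <- vapply(strata, function(s) s$a + s$b + s$c + s$d, numeric(1))
  if (any(totals == 0)) {
    abort_levo("degenerate stratum with zero total",
               "levoCEA_degenerate_stratum_error")
  }
  # conditional hypergeometric moments per stratum: E[a] = n1 m1 / N,
  # Var[a] = n1 n2 m1 m2 / (N^2 (N - 1)); the N^2 (N-1) denominator is the
  # convention under which a single stratum reduces to the Pearson
  # chi-square statistic times (N - 1) / N
  moments <- vapply(strata, function(s) {
    n1 <- s$a + s$b; n2 <- s$c + s$d
    m1 <- s$a + s$c; m2 <- s$b + s$d
    n <- n1 + n2
    c(a = s$a, e = n1 * m1 / n,
      v = if (n > 1) n1 * n2 * m1 * m2 / (n^2 * (n - 1)) else 0)
  }, numeric(3))
  v_total <- sum(moments["v", ])
  if (v_total == 0) {
    abort_levo("all strata are degenerate: zero total variance",
               "levoCEA_degenerate_stratum_error")
  }
  dev <- abs(sum(moments["a", ]) - sum(moments["e", ]))
  if (correction) dev <- max(0, dev - 0.5)
  statistic <- dev^2 / v_total
  new_test_result("mantel_haenszel", statistic,
                  pchisq(statistic, df = 1, lower.tail = FALSE),
                  "two_sided", correction)
}

#' Compare two continuous samples
#'
#' Two-sided Student t-test or Mann-Whitney U test, provided for cohort
#' summaries on synthetic data (no tabulated value is reproduced from the
#' study's continuous variables, whose per-patient values are unpublished).
#' The Mann-Whitney test uses the midrank convention with the exact
#' permutation distribution up to 20 observations in total and the normal
#' approximation with continuity correction above that.
#'
#' @param values_a,values_b Non-empty numeric vectors.
#' @param method `"t_test"` or `"mann_whitney"`.
#' @return A one-row test-result tibble.
#' @export
continuous_compare <- function(values_a, values_b,
                               method = c("t_test", "mann_whitney")) {
  method <- match.arg(method)
  if (length(values_a) == 0 || length(values_b) == 0) {
    abort_levo("both samples must be non-empty", "levoCEA_validation_error")
  }
  if (method == "t_test") {
    if (length(values_a) < 2 || length(values_b) < 2) {
      abort_levo("t-test needs at least 2 values per group",
                 "levoCEA_insufficient_data_error")
    }
    res <- t.test(values_a, values_b)
    new_test_result("t_test", unname(res$statistic), res$p.value,
                    "two_sided", FALSE)
  } else {
    n_total <- length(values_a) + length(values_b)
    if (n_total <= 20) {
      # exact permutation distribution of the midrank sum
      ranks <- rank(c(values_a, values_b))
      n_a <- length(values_a)
      t_obs <- sum(ranks[seq_len(n_a)])
      expected <- n_a * (n_total + 1) / 2
      sums <- utils::combn(ranks, n_a, sum)
      p <- mean(abs(sums - expected) >= abs(t_obs - expected) - 1e-9)
      u_stat <- t_obs - n_a * (n_a + 1) / 2
      new_test_result("mann_whitney", u_stat, p, "two_sided", FALSE)
    } else {
      res <- suppressWarnings(wilcox.test(values_a, values_b,
                                          exact = FALSE, correct = TRUE))
      new_test_result("mann_whitney", unname(res$statistic), res$p.value,
                      "two_sided", FALSE)
    }
  }
}

#' Comparative statistics table for a two-arm cohort
#'
#' One row per complication flag with per-arm counts and percentages and the
#' comparative p-value (Pearson chi-square, or the Fisher exact test when any
#' expected cell count falls below 5), plus one stratified Mantel-Haenszel
#' row for low cardiac output across LVEF strata.
#'
#' @param records A cohort tibble.
#' @param events Flags to tabulate (default: all six).
#' @return A tidy tibble, one test per row.
#' @export
cohort_stats_table <- function(records, events = cohort_flags) {
  records <- validate_cohort(records)
  rows <- lapply(events, function(ev) {
    t <- tabulate_event(records, ev)
    pct <- arm_percentages(t)
    m <- as.matrix(t)
    expected <- outer(rowSums(m), colSums(m)) / sum(m)
    res <- if (any(expected < 5)) {
      fisher_exact(t, "two_sided")
    } else {
      pearson_chi2(t, correction = FALSE)
    }
    tibble(
      event = ev, stratified = FALSE,
      n_intervention = t$a, pct_intervention = pct[["intervention"]],
      n_control = t$c, pct_control = pct[["control"]],
      res
    )
  })
  mh <- mantel_haenszel(stratify_event(records, "lco"))
  t_lco <- tabulate_event(records, "lco")
  pct_lco <- arm_percentages(t_lco)
  rows <- c(rows, list(tibble(
    event = "lco", stratified = TRUE,
    n_intervention = t_lco$a, pct_intervention = pct_lco[["intervention"]],
    n_control = t_lco$c, pct_control = pct_lco[["control"]],
    mh
  )))
  dplyr::bind_rows(rows)
}
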