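test_that("cohort CSV round trip preserves records and validates the schema", {
  cohort <- reference_cohort()
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort, path)
  expect_equal(read_cohort(path), cohort)

  # header-only file -> empty cohort
  readr::write_csv(cohort[0, ], path)
  expect_equal(nrow(read_cohort(path)), 0L)

  # schema violations are named
  broken <- cohort
  broken$arm <- NULL
  readr::write_csv(broken, path)
  expect_error(read_cohort(path), "arm", class = "levoCEA_schema_error")

  flagged <- cohort
  flagged$lco <- as.character(as.integer(flagged$lco))
  flagged$lco[3] <- "yes"
  readr::write_csv(flagged, path)
  expect_error(read_cohort(path), "row.*3", class = "levoCEA_parse_error")

  shocked <- cohort
  shocked$cardiogenic_shock[1] <- TRUE  # patient 1 has no LCO
  expect_error(validate_cohort(shocked),
               class = "levoCEA_consistency_error")
})

test_that("event tabulation reproduces the cohort contingency tables", {
  cohort <- reference_cohort()
  lco <- tabulate_event(cohort, "lco")
  expect_equal(unclass(lco)[c("a", "b", "c", "d")],
               list(a = 2L, b = 11L, c = 25L, d = 16L))
  shock <- tabulate_event(cohort, "cardiogenic_shock")
  expect_equal(unclass(shock)[c("a", "b", "c", "d")],
               list(a = 0L, b = 13L, c = 10L, d = 31L))
  expect_error(tabulate_event(cohort, "sepsis"),
               class = "levoCEA_domain_error")

  # an all-false flag splits into the arm sizes
  none <- cohort
  none$noaf <- FALSE
  t0 <- tabulate_event(none, "noaf")
  expect_equal(c(t0$a, t0$b, t0$c, t0$d), c(0L, 13L, 0L, 41L))
  expect_equal(unname(arm_percentages(t0)), c(0, 0))
})

test_that("arm percentages use half-up rounding at one decimal", {
  expect_equal(arm_percentages(fourfold_table(2, 11, 25, 16)),
               c(intervention = 15.4, control = 61.0))
  expect_equal(arm_percentages(fourfold_table(0, 13, 10, 31)),
               c(intervention = 0.0, control = 24.4))
  expect_equal(arm_percentages(fourfold_table(1, 12, 10, 31)),
               c(intervention = 7.7, control = 24.4))
  expect_error(arm_percentages(fourfold_table(0, 0, 3, 4)),
               class = "levoCEA_undefined_proportion_error")
})

test_that("Pearson chi-square matches the closed-form statistic", {
  res <- pearson_chi2(fourfold_table(2, 11, 25, 16))
  expect_equal(res$statistic, chi2_formula(2, 11, 25, 16), tolerance = 1e-12)
  expect_equal(res$statistic, 8.206, tolerance = 1e-3)
  expect_equal(res$p_value, pchisq(res$statistic, 1, lower.tail = FALSE))
  expect_lt(res$p_value, 0.01)

  # balanced table: no association
  bal <- pearson_chi2(fourfold_table(4, 4, 4, 4))
  expect_equal(bal$statistic, 0)
  expect_equal(bal$p_value, 1)

  expect_error(pearson_chi2(fourfold_table(0, 0, 5, 5)),
               class = "levoCEA_degenerate_table_error")

  set.seed(11)
  for (i in 1:25) {
    t <- random_fourfold()
    for (corr in c(FALSE, TRUE)) {
      res <- pearson_chi2(t, correction = corr)
      expect_equal(res$statistic, chi2_formula(t$a, t$b, t$c, t$d, corr),
                   tolerance = 1e-10)
      # invariant under simultaneous swap of arms and event polarity
      swapped <- pearson_chi2(fourfold_table(t$d, t$c, t$b, t$a), corr)
      expect_equal(res$statistic, swapped$statistic, tolerance = 1e-10)
    }
  }
})

test_that("Fisher exact test agrees with exhaustive enumeration", {
  one <- fisher_exact(fourfold_table(0, 13, 10, 31), "one_sided")
  expect_equal(round(one$p_value, 3), 0.047)
  expect_equal(one$p_value, fisher_oracle(0, 13, 10, 31, "one_sided"),
               tolerance = 1e-12)

  # only one table consistent with the margins
  expect_equal(fisher_exact(fourfold_table(0, 6, 0, 9), "one_sided")$p_value,
               1)

  set.seed(12)
  for (i in 1:25) {
    t <- random_fourfold(60)
    p1 <- fisher_exact(t, "one_sided")$p_value
    p2 <- fisher_exact(t, "two_sided")$p_value
    expect_equal(p1, fisher_oracle(t$a, t$b, t$c, t$d, "one_sided"),
                 tolerance = 1e-12)
    expect_equal(p2, fisher_oracle(t$a, t$b, t$c, t$d, "two_sided"),
                 tolerance = 1e-12)
    expect_lte(p1, p2 + 1e-12)
    expect_lte(p2, 1)
  }
})

test_that("Mantel-Haenszel uses the conditional hypergeometric moments", {
  strata <- stratify_event(reference_cohort(), "lco")
  expect_equal(vapply(strata, function(s) c(s$a, s$b, s$c, s$d),
                      numeric(4)),
               matrix(c(0, 5, 20, 13, 2, 6, 5, 3), ncol = 2,
                      dimnames = list(NULL, names(strata))))

  res <- mantel_haenszel(strata, correction = TRUE)
  m1 <- mh_moments_oracle(0, 5, 20, 13)
  m2 <- mh_moments_oracle(2, 6, 5, 3)
  stat_oracle <- (abs((0 + 2) - (m1$e + m2$e)) - 0.5)^2 / (m1$v + m2$v)
  expect_equal(res$statistic, stat_oracle, tolerance = 1e-10)
  expect_equal(round(res$p_value, 2), 0.01)

  no_cc <- mantel_haenszel(strata, correction = FALSE)
  expect_equal(round(no_cc$p_value, 3), 0.005)

  # cross-check against the reference implementation for both conventions
  arr <- array(c(0, 20, 5, 13, 2, 5, 6, 3), dim = c(2, 2, 2))
  for (corr in c(TRUE, FALSE)) {
    ref <- stats::mantelhaen.test(arr, correct = corr)
    got <- mantel_haenszel(strata, correction = corr)
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
  }

  expect_error(
    mantel_haenszel(list(fourfold_table(0, 0, 0, 0))),
    class = "levoCEA_degenerate_stratum_error"
  )
})

test_that("single-stratum Mantel-Haenszel reduces to chi-square times (N-1)/N", {
  set.seed(13)
  for (i in 1:20) {
    t <- random_fourfold()
    n <- t$a + t$b + t$c + t$d
    for (corr in c(FALSE, TRUE)) {
      mh <- mantel_haenszel(list(s = t), correction = corr)$statistic
      chi <- pearson_chi2(t, correction = corr)$statistic
      expect_equal(mh, chi * (n - 1) / n, tolerance = 1e-9)
    }
  }
})

test_that("continuous comparisons follow the exact and asymptotic contracts", {
  same <- continuous_compare(c(1, 2, 3), c(1, 2, 3), "mann_whitney")
  expect_equal(same$p_value, 1)

  expect_error(continuous_compare(1, c(1, 2), "t_test"),
               class = "levoCEA_insufficient_data_error")

  # complete separation at n = 3 vs 3: exact permutation tail
  sep <- continuous_compare(c(0, 0, 0), c(1, 1, 1), "mann_whitney")
  ranksums <- apply(combn(6, 3), 2, sum)
  obs <- sum(1:3)  # the zeros take the three smallest ranks
  p_perm <- mean(ranksums <= obs | ranksums >= sum(4:6))
  expect_equal(sep$p_value, p_perm)

  t_res <- continuous_compare(rnorm(10), rnorm(10), "t_test")
  expect_true(t_res$p_value >= 0 && t_res$p_value <= 1)
})

test_that("Mann-Whitney type I error is near nominal under the null", {
  set.seed(14)
  reps <- 4000
  rejections <- 0
  for (i in seq_len(reps)) {
    p <- continuous_compare(rnorm(60), rnorm(60), "mann_whitney")$p_value
    rejections <- rejections + (p < 0.05)
  }
  rate <- rejections / reps
  expect_lt(abs(rate - 0.05), binom99_halfwidth(0.05, reps))
})

test_that("the comparative statistics table covers all flags and the stratified test", {
  stats <- cohort_stats_table(reference_cohort())
  expect_equal(nrow(stats), 7)
  lco_row <- stats[stats$event == "lco" & !stats$stratified, ]
  expect_equal(lco_row$method, "pearson_chi2")
  expect_lt(lco_row$p_value, 0.01)
  mh_row <- stats[stats$stratified, ]
  expect_equal(mh_row$method, "mantel_haenszel")
  expect_equal(round(mh_row$p_value, 2), 0.01)
  shock_row <- stats[stats$event == "cardiogenic_shock", ]
  expect_equal(shock_row$method, "fisher_exact")
})
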