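test_that("chain probabilities are estimated as empirical fractions", {
  ep <- estimate_probabilities(reference_cohort())
  expect_equal(ep$intervention$noaf, list(events = 2L, n = 13L))
  expect_equal(ep$control$rf_given_lco, list(events = 9L, n = 25L))
  m_int <- implied_marginals(ep$intervention)
  m_ctl <- implied_marginals(ep$control)
  expect_equal(m_int[["lco"]], 2 / 13, tolerance = 1e-12)
  expect_equal(m_ctl[["lco"]], 25 / 41, tolerance = 1e-12)
  expect_equal(m_ctl[["rf"]], 10 / 41, tolerance = 1e-12)
  expect_equal(m_ctl[["mv"]], 9 / 41, tolerance = 1e-12)

  # all-false flags estimate to zero throughout (conditionals on empty
  # denominators fall back to the zero marginal, with a warning)
  quiet <- reference_cohort()
  for (fl in c("noaf", "lco", "cardiogenic_shock", "renal_failure",
               "prolonged_mv", "death")) {
    quiet[[fl]] <- FALSE
  }
  w <- capture_warnings(ep0 <- estimate_probabilities(quiet))
  expect_true(all(grepl("empty denominator", w)) && length(w) > 0)
  for (arm in c("intervention", "control")) {
    p <- implied_marginals(ep0[[arm]])
    expect_equal(unname(p), rep(0, 4))
  }

  expect_error(
    estimate_probabilities(reference_cohort()[1:13, ]),
    class = "levoCEA_estimation_error"
  )
})

test_that("the tree enumerates 16 pathways whose probabilities conserve mass", {
  config <- default_model_config()
  for (arm in c("intervention", "control")) {
    tree <- build_tree(config, arm)
    expect_equal(nrow(tree), 16)
    expect_equal(sum(tree$probability), 1, tolerance = 1e-12)
    expect_true(all(tree$cost > 0))
    expect_equal(tree$complication_free,
                 !(tree$noaf | tree$lco | tree$rf | tree$mv))
  }

  # degenerate chain: a single certain, complication-free pathway
  cfg0 <- config
  for (arm in c("intervention", "control")) {
    for (par in setdiff(names(cfg0$probabilities[[arm]]), "noaf")) {
      cfg0$probabilities[[arm]][[par]] <- 0
    }
    cfg0$probabilities[[arm]]$noaf <- 0
  }
  tree0 <- build_tree(cfg0, "control")
  expect_equal(sum(tree0$probability > 0), 1)
  expect_true(tree0$complication_free[tree0$probability == 1])
})

test_that("rollback computes probability-weighted expectations", {
  one <- tibble::tibble(
    arm = "control", noaf = FALSE, lco = FALSE, rf = FALSE, mv = FALSE,
    probability = 1, icu_days = 3, ward_days = 5, cost = 123.45,
    complication_free = TRUE
  )
  exp1 <- rollback(one)
  expect_equal(exp1$expected_cost, 123.45)
  expect_equal(exp1$pct_no_complications, 100)

  two <- dplyr::bind_rows(one, one)
  two$probability <- c(0.5, 0.5)
  two$cost <- c(0, 100)
  two$complication_free <- c(TRUE, FALSE)
  exp2 <- rollback(two)
  expect_equal(exp2$expected_cost, 50)
  expect_equal(exp2$pct_no_complications, 50)

  bad <- one
  bad$probability <- 0.9
  expect_error(rollback(bad), class = "levoCEA_conservation_error")
})

test_that("rollback equals exhaustive pathway enumeration on random models", {
  config <- default_model_config()
  catalogue <- default_catalogue()
  set.seed(31)
  for (i in 1:40) {
    cfg <- config
    arm <- sample(c("intervention", "control"), 1)
    cfg$probabilities[[arm]][levoCEA:::prob_params] <- random_chain_probs()
    cfg$los$icu_base[[arm]] <- runif(1, 0, 5)
    cfg$los$ward_base[[arm]] <- runif(1, 0, 8)
    got <- rollback(build_tree(cfg, arm, catalogue))
    want <- enumeration_oracle(
      as.list(cfg$probabilities[[arm]][levoCEA:::prob_params]),
      cfg$los$icu_base[[arm]], cfg$los$ward_base[[arm]],
      cfg$los$icu_increment, cfg$los$ward_increment,
      cfg$profiles, catalogue, upfront = arm == "intervention"
    )
    expect_equal(got$expected_cost, want$cost, tolerance = 1e-9)
    expect_equal(got$mean_icu_days, want$icu, tolerance = 1e-12)
    expect_equal(got$mean_ward_days, want$ward, tolerance = 1e-12)
    expect_equal(got$pct_no_complications, want$eff, tolerance = 1e-12)
  }
})

test_that("expected cost is monotone in the LCO incidence", {
  config <- default_model_config()
  base <- base_case(config)$control$expected_cost
  p_lco_base <- implied_marginals(config$probabilities$control)[["lco"]]
  costs <- vapply(c(0.3, 0.45, p_lco_base, 0.7), function(target) {
    cfg <- config
    cfg$probabilities$control <-
      levoCEA:::override_p_lco(cfg$probabilities$control, target)
    base_case(cfg)$control$expected_cost
  }, numeric(1))
  expect_true(all(diff(costs) > 0))
  expect_equal(costs[3], base, tolerance = 1e-6)
})

test_that("incremental comparison reports deltas, dominance and the ICER", {
  exp_a <- structure(list(expected_cost = 14792.33, mean_icu_days = 2.50,
                          mean_ward_days = 6.46,
                          pct_no_complications = 53.85),
                     class = "strategy_expectation")
  exp_b <- structure(list(expected_cost = 17006.94, mean_icu_days = 5.70,
                          mean_ward_days = 6.40,
                          pct_no_complications = 31.71),
                     class = "strategy_expectation")
  inc <- incremental(exp_a, exp_b)
  # arithmetic differences of the printed columns
  expect_equal(inc$delta_cost, 2214.61)
  expect_equal(inc$delta_icu, -3.20)
  expect_equal(inc$delta_ward, 0.06)
  expect_equal(inc$delta_effect, 22.14)
  expect_true(inc$dominance)
  expect_true(is.na(inc$icer))

  same <- incremental(exp_a, exp_a)
  expect_equal(same$delta_cost, 0)
  expect_false(same$dominance)

  # cheaper but less effective: no dominance, ICER reported
  exp_c <- exp_a
  exp_c$pct_no_complications <- 20
  inc2 <- incremental(exp_c, exp_b)
  expect_false(inc2$dominance)
  expect_equal(inc2$icer,
               (exp_c$expected_cost - exp_b$expected_cost) /
                 ((20 - 31.71) / 100))
})

test_that("the packaged configuration round-trips through YAML", {
  config <- default_model_config()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_model_config(config, path)
  reloaded <- load_model_config(path)
  expect_equal(prob_table <- reloaded$probabilities, config$probabilities)
  expect_equal(reloaded$los$icu_base, config$los$icu_base,
               tolerance = 1e-12)
  expect_equal(reloaded$profiles, config$profiles)

  packaged <- load_model_config()
  expect_equal(base_case(packaged)$intervention$expected_cost,
               base_case(config)$intervention$expected_cost,
               tolerance = 1e-9)

  broken <- config
  broken$los <- NULL
  expect_error(validate_model_config(broken),
               class = "levoCEA_configuration_error")
})
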