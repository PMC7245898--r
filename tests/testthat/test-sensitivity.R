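test_that("distribution draws respect supports, means and bounds", {
  set.seed(41)
  b <- sample_dist(dist_beta(2, 11), 50000)
  expect_true(all(b >= 0 & b <= 1))
  expect_equal(mean(b), 2 / 13, tolerance = 0.01)

  # zero-occurrence cell: Jeffreys-adjusted, proper and strictly positive
  b0 <- sample_dist(dist_beta(0, 2), 10000)
  expect_true(all(b0 > 0 & b0 < 1))
  expect_equal(mean(b0), 0.5 / 3, tolerance = 0.02)

  g <- sample_dist(dist_gamma(1266.95, 0.10), 100000)
  expect_true(all(g > 0))
  expect_equal(mean(g), 1266.95, tolerance = 0.005)
  expect_equal(unname(quantile(g, c(0.025, 0.975))),
               c(1140.26, 1393.65), tolerance = 0.005)

  u <- sample_dist(dist_unif(0.9, 1.1), 10000)
  expect_true(all(u >= 0.9 & u <= 1.1))
  expect_equal(sample_dist(dist_fixed(5), 3), c(5, 5, 5))

  expect_error(dist_beta(0, 0), class = "levoCEA_validation_error")
  expect_error(dist_gamma(-1), class = "levoCEA_validation_error")
  expect_error(dist_unif(2, 1), class = "levoCEA_validation_error")
})

test_that("deterministic sensitivity rows move with the LCO override only", {
  config <- default_model_config()
  # a no-op override reproduces the base case
  noop <- tibble::tibble(
    label = "noop", arm = "control",
    p_lco = implied_marginals(config$probabilities$control)[["lco"]]
  )
  dsa <- run_dsa(config, noop)
  base_row <- dsa[dsa$label == "Base case" & dsa$arm == "control", ]
  noop_row <- dsa[dsa$label == "noop", ]
  expect_equal(noop_row$expected_cost, base_row$expected_cost,
               tolerance = 1e-9)
  expect_equal(noop_row$pct_no_complications,
               base_row$pct_no_complications, tolerance = 1e-9)

  full <- run_dsa(config)
  cost_at <- function(lbl) full$expected_cost[full$label == lbl]
  # cost increases with the LCO incidence
  expect_lt(cost_at("LCO 6%"), cost_at("Base case")[1])
  expect_lt(cost_at("Base case")[1], cost_at("LCO 18%"))
  # the milder control scenario leaves more patients complication-free
  free_at <- function(lbl) full$pct_no_complications[full$label == lbl]
  expect_gt(free_at("LCO 25%"), free_at("LCO 35%"))
  expect_lt(cost_at("LCO 25%"), cost_at("LCO 35%"))

  expect_error(run_dsa(config, tibble::tibble(label = "x", arm = "placebo",
                                              p_lco = 0.5)),
               class = "levoCEA_validation_error")
})

test_that("the probabilistic analysis is seed-deterministic", {
  cfg <- default_model_config()
  a <- run_psa(cfg, psa_config(n_draws = 200, seed = 99))
  b <- run_psa(cfg, psa_config(n_draws = 200, seed = 99))
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- run_psa(cfg, psa_config(n_draws = 200, seed = 100))
  expect_false(identical(a$cost, c$cost))

  s1 <- summarize_psa(a)
  s2 <- summarize_psa(b)
  expect_identical(s1, s2)
})

test_that("a degenerate PSA reproduces the base case in every draw", {
  cfg <- default_model_config()
  bc <- base_case(cfg)
  draws <- run_psa(cfg, psa_config(n_draws = 25, seed = 5), fixed = TRUE)
  for (arm in c("intervention", "control")) {
    sub <- draws[draws$strategy == arm, ]
    expect_true(all(sub$cost == bc[[arm]]$expected_cost))
    expect_true(all(sub$icu_days == bc[[arm]]$mean_icu_days))
    expect_true(all(sub$effect == bc[[arm]]$pct_no_complications))
  }
  s <- summarize_psa(draws)
  expect_true(all(s$summary$lower == s$summary$upper))
  expect_true(all(s$summary$lower == s$summary$mean))
})

test_that("PSA means converge to the base case when centred on it", {
  cfg <- default_model_config()
  bc <- base_case(cfg)
  n <- 4000
  draws <- run_psa(cfg, psa_config(n_draws = n, seed = 6))
  for (arm in c("intervention", "control")) {
    sub <- draws[draws$strategy == arm, ]
    mc_se <- stats::sd(sub$cost) / sqrt(n)
    # the only mean shift comes from Jeffreys-adjusted empty cells in the
    # intervention arm, bounded well inside 3 MC standard errors + shift
    shift <- abs(mean(sub$cost) - bc[[arm]]$expected_cost)
    allowance <- if (arm == "intervention") 150 else 0
    expect_lt(shift, 3 * mc_se + allowance)
    expect_true(all(sub$cost >= 0))
    expect_true(all(sub$effect >= 0 & sub$effect <= 100))
  }
})

test_that("PSA draws agree with the per-draw tree roll-back", {
  # re-evaluate a handful of draws through build_tree + rollback by pinning
  # every distribution at the drawn value via a fixed-parameter model
  cfg <- default_model_config()
  draws <- run_psa(cfg, psa_config(n_draws = 3, seed = 7), fixed = TRUE)
  bc_tree <- lapply(c("intervention", "control"), function(arm) {
    rollback(build_tree(cfg, arm))
  })
  names(bc_tree) <- c("intervention", "control")
  for (arm in c("intervention", "control")) {
    sub <- draws[draws$strategy == arm, ]
    expect_equal(sub$cost[1], bc_tree[[arm]]$expected_cost,
                 tolerance = 1e-9)
    expect_equal(sub$effect[1], bc_tree[[arm]]$pct_no_complications,
                 tolerance = 1e-12)
  }
})

test_that("the cost-effectiveness plane encodes incremental pairs", {
  cfg <- default_model_config()
  draws <- run_psa(cfg, psa_config(n_draws = 50, seed = 8))
  plane <- ce_plane(draws)
  expect_equal(nrow(plane), 50)
  i1 <- draws[draws$draw == 1, ]
  expect_equal(plane$d_cost[1],
               i1$cost[i1$strategy == "control"] -
                 i1$cost[i1$strategy == "intervention"])
  expect_equal(plane$d_effect[1],
               i1$effect[i1$strategy == "intervention"] -
                 i1$effect[i1$strategy == "control"])

  # identical strategies collapse to the origin
  degenerate <- draws
  degenerate$cost <- 1000
  degenerate$effect <- 50
  plane0 <- ce_plane(degenerate)
  expect_true(all(plane0$d_cost == 0 & plane0$d_effect == 0))
  expect_true(all(!plane0$dominant))
})

test_that("the dominance fraction counts cheaper-and-more-effective draws", {
  # constructed draw set: half dominant, half dominated
  n <- 400
  draws <- tibble::tibble(
    draw = rep(seq_len(n), 2),
    strategy = rep(c("intervention", "control"), each = n),
    cost = c(ifelse(seq_len(n) <= n / 2, 100, 300),
             rep(200, n)),
    icu_days = 1, ward_days = 1,
    effect = c(ifelse(seq_len(n) <= n / 2, 80, 20), rep(50, n))
  )
  s <- summarize_psa(draws, ci_level = 0.95)
  expect_equal(s$dominance_fraction, 0.5)
  # invariant to relabelling the draw order
  perm <- draws[sample(nrow(draws)), ]
  expect_equal(summarize_psa(perm, ci_level = 0.95)$dominance_fraction, 0.5)
})
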