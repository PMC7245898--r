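#' Deterministic sensitivity scenarios for the LCO incidence
#'
#' The univariate scenarios vary the arm-level incidence of postoperative
#' low cardiac output across values published for comparable cohorts under
#' alternative LCO definitions: 18% and 6% for the preconditioned arm,
#' 35% and 25% for standard care.
#'
#' @return Tibble with columns `label`, `arm`, `p_lco`, `source_note`.
#' @export
default_scenarios <- function() {
  tibble::tribble(
    ~label,     ~arm,           ~p_lco, ~source_note,
    "LCO 18%",  "intervention", 0.18,   "levosimendan CABG trial arm",
    "LCO 6%",   "intervention", 0.06,   "restrictive LCO definition",
    "LCO 35%",  "control",      0.35,   "broad LCO definition",
    "LCO 25%",  "control",      0.25,   "levosimendan CABG trial placebo"
  )
}

#' Load deterministic scenarios from CSV
#'
#' @param path CSV with columns `label`, `arm`, `p_lco` and optionally
#'   `source_note`; defaults to the packaged scenario file.
#' @return Scenario tibble.
#' @export
load_scenarios <- function(path = system.file("extdata",
                                              "dsa_scenarios.csv",
                                              package = "levoCEA")) {
  sc <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE)
  missing <- setdiff(c("label", "arm", "p_lco"), names(sc))
  if (length(missing) > 0) {
    abort_levo(sprintf("scenario file missing column(s): %s",
                       paste(missing, collapse = ", ")),
               "levoCEA_schema_error")
  }
  sc
}

# Override the arm-level LCO marginal by rescaling both conditionals
# (lco | noaf and lco | no noaf) by a common factor, preserving the
# NOAF -> LCO association structure.
override_p_lco <- function(probs_arm, target) {
  assert_probability(target, "p_lco override")
  p <- prob_points(probs_arm)
  current <- implied_marginals(probs_arm)[["lco"]]
  out <- probs_arm
  if (current == 0) {
    # no structure to preserve: set both conditionals to the target
    out$lco_given_noaf <- target
    out$lco_given_no_noaf <- target
    return(out)
  }
  f <- target / current
  for (nm in c("lco_given_noaf", "lco_given_no_noaf")) {
    v <- f * p[[nm]]
    if (v > 1) {
      abort_levo(sprintf(
        "LCO override %.3f would push %s to %.3f > 1", target, nm, v
      ), "levoCEA_validation_error")
    }
    out[[nm]] <- v
  }
  out
}

#' Univariate deterministic sensitivity analysis over the LCO incidence
#'
#' Re-evaluates the base case once per scenario with only the arm-level
#' probability of low cardiac output overridden (both conditionals rescaled
#' proportionally); all other parameters stay at their base-case values.
#' The base-case rows of both strategies are included for reference.
#'
#' @param config Model configuration.
#' @param scenarios Scenario tibble, see [default_scenarios()].
#' @param catalogue Unit-cost catalogue.
#' @return Tibble: `label`, `arm`, `p_lco`, `expected_cost`,
#'   `mean_icu_days`, `mean_ward_days`, `pct_no_complications`.
#' @export
#' @examples
#' run_dsa()
run_dsa <- function(config = default_model_config(),
                    scenarios = default_scenarios(),
                    catalogue = default_catalogue()) {
  config <- validate_model_config(config)
  if (any(!scenarios$arm %in% arm_levels)) {
    abort_levo("scenario arms must be intervention/control",
               "levoCEA_validation_error")
  }
  bc <- base_case(config, catalogue)
  base_rows <- purrr::map2_dfr(
    list(bc$intervention, bc$control), arm_levels,
    function(exp, arm) tibble(
      label = "Base case", arm = arm,
      p_lco = implied_marginals(config$probabilities[[arm]])[["lco"]],
      expected_cost = exp$expected_cost,
      mean_icu_days = exp$mean_icu_days,
      mean_ward_days = exp$mean_ward_days,
      pct_no_complications = exp$pct_no_complications
    )
  )
  scen_rows <- purrr::pmap_dfr(
    scenarios[, c("label", "arm", "p_lco")],
    function(label, arm, p_lco) {
      cfg <- config
      cfg$probabilities[[arm]] <- override_p_lco(cfg$probabilities[[arm]],
                                                 p_lco)
      exp <- base_case(cfg, catalogue)[[arm]]
      tibble(
        label = label, arm = arm, p_lco = p_lco,
        expected_cost = exp$expected_cost,
        mean_icu_days = exp$mean_icu_days,
        mean_ward_days = exp$mean_ward_days,
        pct_no_complications = exp$pct_no_complications
      )
    }
  )
  dplyr::bind_rows(base_rows, scen_rows)
}

#' Probabilistic sensitivity analysis settings
#'
#' @param n_draws Number of Monte Carlo draws (default 10,000).
#' @param seed Integer seed for the whole analysis.
#' @param ci_level Percentile-interval level (default 0.95).
#' @return List of class `psa_config`.
#' @export
psa_config <- function(n_draws = 10000, seed = 1, ci_level = 0.95) {
  if (n_draws < 1) {
    abort_levo("n_draws must be >= 1", "levoCEA_validation_error")
  }
  if (ci_level <= 0 || ci_level >= 1) {
    abort_levo("ci_level must be in (0, 1)", "levoCEA_validation_error")
  }
  structure(list(n_draws = as.integer(n_draws), seed = as.integer(seed),
                 ci_level = ci_level),
            class = "psa_config")
}

# Distribution assignment: probabilities -> beta scaled by the
# effective-sample multiplier, unit costs -> gamma, quantities and stay
# parameters -> uniform around the base value. fixed = TRUE degenerates
# every distribution to its base-case value.
psa_distributions <- function(config, catalogue = default_catalogue(),
                              fixed = FALSE) {
  config <- validate_model_config(config)
  catalogue <- validate_catalogue(catalogue)
  ess <- config$psa$ess
  ub <- config$psa$uniform_bound
  probs <- lapply(arm_levels, function(arm) {
    out <- lapply(prob_params, function(par) {
      entry <- config$probabilities[[arm]][[par]]
      value <- prob_value(entry)
      if (fixed) return(dist_fixed(value))
      if (is.list(entry)) {
        dist_beta(ess * entry$events, ess * (entry$n - entry$events))
      } else {
        # a bare override has no counts; treat it as known
        dist_fixed(value)
      }
    })
    names(out) <- prob_params
    out
  })
  names(probs) <- arm_levels
  costs <- lapply(seq_len(nrow(catalogue)), function(i) {
    m <- catalogue$unit_cost[i]
    if (fixed || m == 0) dist_fixed(m) else
      dist_gamma(m, config$psa$gamma_bound)
  })
  names(costs) <- catalogue$code
  unif_around <- function(q) {
    if (fixed || q == 0) dist_fixed(q) else
      dist_unif((1 - ub) * q, (1 + ub) * q)
  }
  los <- list(
    icu_base = lapply(as.list(config$los$icu_base[arm_levels]), unif_around),
    ward_base = lapply(as.list(config$los$ward_base[arm_levels]),
                       unif_around),
    icu_increment = lapply(
      as.list(config$los$icu_increment[c("noaf", "lco", "rf", "mv")]),
      unif_around),
    ward_increment = lapply(
      as.list(config$los$ward_increment[c("noaf", "lco", "rf", "mv")]),
      unif_around)
  )
  profiles <- lapply(config$profiles, function(q) lapply(as.list(q),
                                                         unif_around))
  list(probabilities = probs, costs = costs, los = los, profiles = profiles)
}

#' Run the Monte Carlo probabilistic sensitivity analysis
#'
#' Propagates parameter uncertainty through the decision model:
#' probabilities are drawn from beta distributions (occurrence and
#' non-occurrence counts scaled by the configured effective-sample
#' multiplier), unit costs from gamma distributions with a 10% central
#' interval around the mean, and resource quantities and stay parameters
#' from uniform distributions around their base values. Each draw evaluates
#' both strategies; parameters common to the two strategies (unit costs,
#' shared quantities, stay increments) share their draw, arm-specific
#' parameters do not.
#'
#' Draw order, for reproducibility, is parameter-major with all draws of one
#' parameter taken at once: intervention chain probabilities, control chain
#' probabilities, unit costs in catalogue order, stay bases and increments,
#' then profile quantities in profile order.
#'
#' @param config Model configuration.
#' @param psa A [psa_config()].
#' @param catalogue Unit-cost catalogue.
#' @param fixed If `TRUE`, degenerate all distributions to their base-case
#'   values (every draw then reproduces the base case exactly).
#' @return Tibble of class `psa_draws`: `draw`, `strategy`, `cost`,
#'   `icu_days`, `ward_days`, `effect` (percent complication-free), with
#'   the seed, draw count and interval level as attributes.
#' @export
#' @examples
#' run_psa(psa = psa_config(n_draws = 100, seed = 1))
run_psa <- function(config = default_model_config(),
                    psa = psa_config(),
                    catalogue = default_catalogue(),
                    fixed = FALSE) {
  config <- validate_model_config(config)
  stopifnot(inherits(psa, "psa_config"))
  n <- psa$n_draws
  dists <- psa_distributions(config, catalogue, fixed = fixed)
  set.seed(psa$seed)
  draw_block <- function(block) lapply(block, sample_dist, n = n)
  p_draws <- lapply(dists$probabilities, draw_block)
  cost_draws <- draw_block(dists$costs)
  if (!isTRUE(config$psa$shared_cost_draws)) {
    cost_draws <- list(intervention = cost_draws,
                       control = draw_block(dists$costs))
  }
  los_draws <- lapply(dists$los, draw_block)
  profile_draws <- lapply(dists$profiles, draw_block)
  arm_results <- lapply(arm_levels, function(arm) {
    costs_arm <- if (isTRUE(config$psa$shared_cost_draws)) {
      cost_draws
    } else {
      cost_draws[[arm]]
    }
    blocks <- model_blocks(profile_draws, costs_arm)
    los_arm <- list(
      icu_base = los_draws$icu_base[[arm]],
      ward_base = los_draws$ward_base[[arm]],
      icu_increment = los_draws$icu_increment,
      ward_increment = los_draws$ward_increment
    )
    eval_model(p_draws[[arm]], los_arm, blocks,
               upfront = arm == "intervention")
  })
  names(arm_results) <- arm_levels
  draws <- dplyr::bind_rows(lapply(arm_levels, function(arm) {
    tibble(
      draw = seq_len(n), strategy = arm,
      cost = arm_results[[arm]]$cost,
      icu_days = arm_results[[arm]]$icu,
      ward_days = arm_results[[arm]]$ward,
      effect = arm_results[[arm]]$eff
    )
  }))
  structure(draws, seed = psa$seed, n_draws = n, ci_level = psa$ci_level,
            class = c("psa_draws", class(draws)))
}

#' Summarize a probabilistic sensitivity analysis
#'
#' Means and percentile intervals per strategy for cost, ICU days, ward
#' days and percent complication-free, plus the dominance fraction: the
#' share of draws in which the intervention is simultaneously cheaper and
#' more effective than control.
#'
#' @param draws A [run_psa()] result.
#' @param ci_level Interval level; defaults to the level stored in `draws`.
#' @return List: `summary` tibble (`strategy`, `metric`, `mean`, `lower`,
#'   `upper`), `dominance_fraction`, `n_draws`, `seed`.
#' @export
summarize_psa <- function(draws, ci_level = NULL) {
  ci_level <- ci_level %||% attr(draws, "ci_level") %||% 0.95
  alpha <- (1 - ci_level) / 2
  long <- tidyr::pivot_longer(
    as_tibble(draws),
    cols = c("cost", "icu_days", "ward_days", "effect"),
    names_to = "metric", values_to = "value"
  )
  summary <- long |>
    dplyr::group_by(.data$strategy, .data$metric) |>
    dplyr::summarise(
      mean = mean(.data$value),
      lower = unname(quantile(.data$value, alpha)),
      upper = unname(quantile(.data$value, 1 - alpha)),
      .groups = "drop"
    )
  plane <- ce_plane(draws)
  list(
    summary = summary,
    dominance_fraction = mean(plane$dominant),
    n_draws = attr(draws, "n_draws") %||% max(draws$draw),
    seed = attr(draws, "seed")
  )
}

#' Cost-effectiveness plane points
#'
#' One point per draw: incremental effectiveness on the x axis
#' (intervention minus control, percentage points of complication-free
#' patients) and incremental cost saving on the y axis (control minus
#' intervention, euros). With these sign conventions the dominant quadrant
#' -- intervention cheaper and more effective -- is the upper-right one
#' (both coordinates positive).
#'
#' @param draws A [run_psa()] result.
#' @return Tibble: `draw`, `d_effect`, `d_cost`, `dominant`.
#' @export
ce_plane <- function(draws) {
  wide <- tidyr::pivot_wider(
    as_tibble(draws)[, c("draw", "strategy", "cost", "effect")],
    names_from = "strategy", values_from = c("cost", "effect")
  )
  tibble(
    draw = wide$draw,
    d_effect = wide$effect_intervention - wide$effect_control,
    d_cost = wide$cost_control - wide$cost_intervention,
    dominant = wide$cost_control > wide$cost_intervention &
      wide$effect_intervention > wide$effect_control
  )
}

#' Plot the cost-effectiveness plane
#'
#' Scatter of the per-draw incremental (effect, cost-saving) pairs; needs
#' ggplot2.
#'
#' @param plane A [ce_plane()] tibble.
#' @return A ggplot object.
#' @export
plot_ce_plane <- function(plane) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    abort_levo("ggplot2 is needed for plotting", "levoCEA_configuration_error")
  }
  ggplot2::ggplot(plane, ggplot2::aes(x = .data$d_effect,
                                      y = .data$d_cost)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.6) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(
      x = "Incremental effectiveness (percentage points complication-free)",
      y = "Incremental cost saving (EUR, control - intervention)"
    ) +
    ggplot2::theme_minimal()
}
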