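#' Estimate the complication chain probabilities from a cohort
#'
#' Empirical conditional probabilities of the decision-tree chain per arm:
#' NOAF first; low cardiac output conditional on NOAF; renal failure and
#' prolonged ventilation conditional on LCO (conditionally independent given
#' LCO in the tree). Each estimate is stored as an event count over a
#' denominator so downstream probabilistic analysis can parameterize beta
#' distributions by occurrence and non-occurrence. Cardiogenic shock given
#' LCO and death given shock are estimated too for use by the cohort
#' generator (they carry no cost or effectiveness in the tree).
#'
#' A conditional with an empty denominator (e.g. no NOAF patients in an arm)
#' falls back to the arm marginal of the outcome event, with a warning.
#'
#' @param records A two-arm cohort tibble with both arms non-empty.
#' @return Object of class `event_probabilities`: per arm, a named list of
#'   `list(events, n)` pairs.
#' @export
#' @examples
#' estimate_probabilities(reference_cohort())
estimate_probabilities <- function(records) {
  records <- validate_cohort(records)
  out <- lapply(arm_levels, function(arm) {
    sub <- records[records$arm == arm, ]
    n <- nrow(sub)
    if (n == 0) {
      abort_levo(sprintf("arm `%s` is empty", arm),
                 "levoCEA_estimation_error")
    }
    conditional <- function(outcome, given, label, quiet = FALSE) {
      denom <- sum(given)
      if (denom == 0) {
        if (!quiet) {
          warn(sprintf(
            "arm %s: empty denominator for %s; falling back to the arm marginal",
            arm, label
          ))
        }
        return(list(events = sum(outcome), n = n))
      }
      list(events = sum(outcome & given), n = denom)
    }
    list(
      noaf = list(events = sum(sub$noaf), n = n),
      lco_given_noaf = conditional(sub$lco, sub$noaf, "lco_given_noaf"),
      lco_given_no_noaf = conditional(sub$lco, !sub$noaf,
                                      "lco_given_no_noaf"),
      rf_given_lco = conditional(sub$renal_failure, sub$lco, "rf_given_lco"),
      rf_given_no_lco = conditional(sub$renal_failure, !sub$lco,
                                    "rf_given_no_lco"),
      mv_given_lco = conditional(sub$prolonged_mv, sub$lco, "mv_given_lco"),
      mv_given_no_lco = conditional(sub$prolonged_mv, !sub$lco,
                                    "mv_given_no_lco"),
      # auxiliary parameters for the generator; tree cost/effect unaffected,
      # so an empty denominator falls back silently
      shock_given_lco = conditional(sub$cardiogenic_shock, sub$lco,
                                    "shock_given_lco", quiet = TRUE),
      death_given_shock = conditional(sub$death, sub$cardiogenic_shock,
                                      "death_given_shock", quiet = TRUE)
    )
  })
  names(out) <- arm_levels
  structure(out, class = "event_probabilities")
}

# Point value of one probability entry: a counts pair or a bare numeric.
prob_value <- function(entry) {
  if (is.list(entry)) entry$events / entry$n else as.numeric(entry)
}

# Named point probabilities of the 7-parameter chain for one arm.
prob_points <- function(probs_arm) {
  vapply(prob_params, function(p) {
    v <- prob_value(probs_arm[[p]])
    assert_probability(v, p)
    v
  }, numeric(1))
}

#' Marginal event probabilities implied by the chain
#'
#' Closes the conditional chain into the four arm-level marginals:
#' `p_lco = p_noaf p(lco|noaf) + (1 - p_noaf) p(lco|no noaf)` and
#' analogously for renal failure and prolonged ventilation given LCO.
#'
#' @param probs_arm One arm of an [estimate_probabilities()] object (or a
#'   named list/vector of the seven chain parameters).
#' @return Named vector `c(noaf, lco, rf, mv)`.
#' @export
implied_marginals <- function(probs_arm) {
  p <- prob_points(probs_arm)
  lco <- p[["noaf"]] * p[["lco_given_noaf"]] +
    (1 - p[["noaf"]]) * p[["lco_given_no_noaf"]]
  c(noaf = p[["noaf"]],
    lco = lco,
    rf = lco * p[["rf_given_lco"]] + (1 - lco) * p[["rf_given_no_lco"]],
    mv = lco * p[["mv_given_lco"]] + (1 - lco) * p[["mv_given_no_lco"]])
}

# The 16 indicator combinations of one arm's subtree, in fixed order.
pathway_grid <- function() {
  expand.grid(noaf = c(FALSE, TRUE), lco = c(FALSE, TRUE),
              rf = c(FALSE, TRUE), mv = c(FALSE, TRUE),
              KEEP.OUT.ATTRS = FALSE)
}

# Chain probability of one indicator combination; vectorized over draws.
# Factor order (noaf, lco, rf, mv) is fixed so that scalar and vectorized
# evaluations agree bitwise.
pathway_probability <- function(w, p) {
  (if (w$noaf) p[["noaf"]] else 1 - p[["noaf"]]) *
    (if (w$lco) {
      if (w$noaf) p[["lco_given_noaf"]] else p[["lco_given_no_noaf"]]
    } else {
      if (w$noaf) 1 - p[["lco_given_noaf"]] else 1 - p[["lco_given_no_noaf"]]
    }) *
    (if (w$rf) {
      if (w$lco) p[["rf_given_lco"]] else p[["rf_given_no_lco"]]
    } else {
      if (w$lco) 1 - p[["rf_given_lco"]] else 1 - p[["rf_given_no_lco"]]
    }) *
    (if (w$mv) {
      if (w$lco) p[["mv_given_lco"]] else p[["mv_given_no_lco"]]
    } else {
      if (w$lco) 1 - p[["mv_given_lco"]] else 1 - p[["mv_given_no_lco"]]
    })
}

# Cost of one resource profile given unit costs; both may be per-draw
# vectors. Shared by the scalar and the vectorized evaluation paths so that
# a degenerate (all-fixed) probabilistic run equals the base case exactly.
block_cost <- function(quantities, costs) {
  total <- 0
  for (code in names(quantities)) {
    total <- total + quantities[[code]] * costs[[code]]
  }
  total
}

# Profile cost blocks for one arm. quantities/costs entries may be scalars
# or per-draw vectors (lists of vectors for profiles).
model_blocks <- function(profiles, costs) {
  blocks <- lapply(profiles, block_cost, costs = costs)
  needed <- c("base", "per_icu_day", "per_ward_day", "upfront_intervention",
              "noaf", "lco", "rf", "mv")
  missing <- setdiff(needed, names(blocks))
  if (length(missing) > 0) {
    abort_levo(sprintf("missing resource profile(s): %s",
                       paste(missing, collapse = ", ")),
               "levoCEA_configuration_error")
  }
  blocks
}

# Core model evaluation: rolled-back expectations for one arm, vectorized
# over parameter draws. p: named list/vector of chain probabilities;
# los: list(icu_base, ward_base, icu_increment, ward_increment), the
# increments indexable by event name; blocks: model_blocks() output.
eval_model <- function(p, los, blocks, upfront) {
  grid <- pathway_grid()
  events <- c("noaf", "lco", "rf", "mv")
  cost <- icu <- ward <- eff <- 0
  fixed_cost <- blocks$base + if (upfront) blocks$upfront_intervention else 0
  for (i in seq_len(nrow(grid))) {
    w <- grid[i, ]
    pp <- pathway_probability(w, p)
    icu_i <- los$icu_base
    ward_i <- los$ward_base
    cost_i <- fixed_cost
    for (ev in events) {
      if (w[[ev]]) {
        icu_i <- icu_i + los$icu_increment[[ev]]
        ward_i <- ward_i + los$ward_increment[[ev]]
        cost_i <- cost_i + blocks[[ev]]
      }
    }
    cost_i <- cost_i + icu_i * blocks$per_icu_day +
      ward_i * blocks$per_ward_day
    cost <- cost + pp * cost_i
    icu <- icu + pp * icu_i
    ward <- ward + pp * ward_i
    if (!w$noaf && !w$lco && !w$rf && !w$mv) eff <- eff + pp
  }
  list(cost = cost, icu = icu, ward = ward, eff = 100 * eff)
}

arm_los <- function(config, arm) {
  list(
    icu_base = config$los$icu_base[[arm]],
    ward_base = config$los$ward_base[[arm]],
    icu_increment = as.list(config$los$icu_increment),
    ward_increment = as.list(config$los$ward_increment)
  )
}

#' Enumerate the decision-tree pathways of one strategy
#'
#' Expands the 16 terminal pathways (all combinations of the four
#' complication indicators) of one arm's subtree: pathway probability from
#' the conditional chain, ICU/ward days from the arm base plus additive
#' per-complication increments, and cost from the composed resource profile
#' (fixed base resources, the upfront preconditioning profile in the
#' intervention arm, per-day stay resources, complication add-ons).
#'
#' @param config A model configuration, see [default_model_config()].
#' @param arm `"intervention"` or `"control"`.
#' @param catalogue Unit-cost catalogue.
#' @return 16-row tibble: indicators, `probability`, `icu_days`,
#'   `ward_days`, `cost`, `complication_free`.
#' @export
#' @examples
#' build_tree(default_model_config(), "intervention")
build_tree <- function(config, arm = arm_levels,
                       catalogue = default_catalogue()) {
  arm <- match.arg(arm)
  config <- validate_model_config(config)
  p <- prob_points(config$probabilities[[arm]])
  los <- arm_los(config, arm)
  costs <- unit_costs(validate_catalogue(catalogue))
  grid <- pathway_grid()
  events <- c("noaf", "lco", "rf", "mv")
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    w <- grid[i, ]
    quantities <- config$profiles$base
    if (arm == "intervention") {
      quantities <- c(quantities, config$profiles$upfront_intervention)
    }
    icu_i <- los$icu_base
    ward_i <- los$ward_base
    for (ev in events) {
      if (w[[ev]]) {
        icu_i <- icu_i + los$icu_increment[[ev]]
        ward_i <- ward_i + los$ward_increment[[ev]]
        quantities <- c(quantities, config$profiles[[ev]])
      }
    }
    quantities <- c(quantities,
                    icu_i * config$profiles$per_icu_day,
                    ward_i * config$profiles$per_ward_day)
    # merge duplicate codes before costing
    merged <- tapply(unname(quantities), names(quantities), sum)
    tibble(
      arm = arm,
      noaf = w$noaf, lco = w$lco, rf = w$rf, mv = w$mv,
      probability = pathway_probability(w, p),
      icu_days = icu_i, ward_days = ward_i,
      cost = pathway_cost(setNames(as.numeric(merged), names(merged)),
                          catalogue)$total,
      complication_free = !(w$noaf || w$lco || w$rf || w$mv)
    )
  })
  dplyr::bind_rows(rows)
}

#' Roll back pathway expectations for one strategy
#'
#' Probability-weighted expectations over the terminal pathways of a single
#' arm: expected cost, mean ICU and ward days, and the percentage of
#' patients free of all four complications (the model's effectiveness
#' measure).
#'
#' @param pathways Tibble from [build_tree()] (single arm); probabilities
#'   must sum to 1 within `tol`.
#' @param tol Probability-conservation tolerance, default `1e-9`.
#' @return Object of class `strategy_expectation`: `expected_cost`,
#'   `mean_icu_days`, `mean_ward_days`, `pct_no_complications`.
#' @export
rollback <- function(pathways, tol = 1e-9) {
  if (length(unique(pathways$arm)) > 1) {
    abort_levo("rollback expects pathways of a single arm",
               "levoCEA_validation_error")
  }
  total <- sum(pathways$probability)
  if (abs(total - 1) > tol) {
    abort_levo(sprintf(
      "pathway probabilities sum to %.12f, not 1 (tolerance %g)",
      total, tol
    ), "levoCEA_conservation_error")
  }
  structure(
    list(
      expected_cost = sum(pathways$probability * pathways$cost),
      mean_icu_days = sum(pathways$probability * pathways$icu_days),
      mean_ward_days = sum(pathways$probability * pathways$ward_days),
      pct_no_complications =
        100 * sum(pathways$probability[pathways$complication_free])
    ),
    class = "strategy_expectation"
  )
}

#' @export
print.strategy_expectation <- function(x, ...) {
  cat(sprintf(
    "strategy expectation: cost %.2f EUR, ICU %.2f d, ward %.2f d, %.2f%% complication-free\n",
    x$expected_cost, x$mean_icu_days, x$mean_ward_days,
    x$pct_no_complications
  ))
  invisible(x)
}

#' Incremental comparison of the two strategies
#'
#' Componentwise differences with the sign conventions of the base-case
#' table: `delta_cost` is control minus intervention (positive = the
#' intervention saves money), while `delta_icu`, `delta_ward` and
#' `delta_effect` (percentage points complication-free) are intervention
#' minus control. The intervention dominates when it is both cheaper and
#' more effective; otherwise the incremental cost-effectiveness ratio
#' (euros per additional complication-free patient) is reported.
#'
#' @param intervention,control `strategy_expectation` objects.
#' @return Object of class `incremental_result`.
#' @export
incremental <- function(intervention, control) {
  delta_cost <- control$expected_cost - intervention$expected_cost
  delta_effect <- intervention$pct_no_complications -
    control$pct_no_complications
  dominance <- delta_cost > 0 && delta_effect > 0
  icer <- if (!dominance && delta_effect != 0) {
    (-delta_cost) / (delta_effect / 100)
  } else {
    NA_real_
  }
  structure(
    list(
      delta_cost = delta_cost,
      delta_icu = intervention$mean_icu_days - control$mean_icu_days,
      delta_ward = intervention$mean_ward_days - control$mean_ward_days,
      delta_effect = delta_effect,
      dominance = dominance,
      icer = icer
    ),
    class = "incremental_result"
  )
}

#' @export
print.incremental_result <- function(x, ...) {
  cat(sprintf(
    "incremental: saving %.2f EUR, ICU %+.2f d, ward %+.2f d, effect %+.2f pts; %s\n",
    x$delta_cost, x$delta_icu, x$delta_ward, x$delta_effect,
    if (x$dominance) "intervention dominates" else
      sprintf("ICER %.2f EUR per complication-free patient", x$icer)
  ))
  invisible(x)
}

#' Base-case evaluation of both strategies
#'
#' Rolls back the decision tree of each arm at the point estimates of the
#' configuration and compares them.
#'
#' @param config Model configuration, see [default_model_config()].
#' @param catalogue Unit-cost catalogue.
#' @return Object of class `base_case`: `intervention` and `control`
#'   [rollback()] expectations plus the [incremental()] comparison.
#' @export
#' @examples
#' base_case()
base_case <- function(config = default_model_config(),
                      catalogue = default_catalogue()) {
  config <- validate_model_config(config)
  costs <- as.list(unit_costs(validate_catalogue(catalogue)))
  blocks <- model_blocks(config$profiles, costs)
  res <- lapply(arm_levels, function(arm) {
    ev <- eval_model(
      as.list(prob_points(config$probabilities[[arm]])),
      arm_los(config, arm), blocks,
      upfront = arm == "intervention"
    )
    structure(
      list(expected_cost = ev$cost, mean_icu_days = ev$icu,
           mean_ward_days = ev$ward, pct_no_complications = ev$eff),
      class = "strategy_expectation"
    )
  })
  names(res) <- arm_levels
  structure(
    list(intervention = res$intervention, control = res$control,
         incremental = incremental(res$intervention, res$control)),
    class = "base_case"
  )
}

#' Base-case results as a three-row table
#'
#' @param bc A [base_case()] object.
#' @return Tibble with rows intervention / control / difference and columns
#'   cost per patient, mean ICU and ward stay, percent complication-free.
#'   In the difference row the cost is control minus intervention and the
#'   other columns are intervention minus control.
#' @export
base_case_table <- function(bc = base_case()) {
  stopifnot(inherits(bc, "base_case"))
  tibble(
    strategy = c("intervention_levosimendan", "control", "difference"),
    cost_per_patient = c(bc$intervention$expected_cost,
                         bc$control$expected_cost,
                         bc$incremental$delta_cost),
    mean_icu_days = c(bc$intervention$mean_icu_days,
                      bc$control$mean_icu_days,
                      bc$incremental$delta_icu),
    mean_ward_days = c(bc$intervention$mean_ward_days,
                       bc$control$mean_ward_days,
                       bc$incremental$delta_ward),
    pct_no_complications = c(bc$intervention$pct_no_complications,
                             bc$control$pct_no_complications,
                             bc$incremental$delta_effect)
  )
}

#' @export
print.base_case <- function(x, ...) {
  print(base_case_table(x))
  invisible(x)
}
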