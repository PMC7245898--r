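#' Default (calibrated) model configuration
#'
#' The packaged configuration of the decision model:
#'
#' * `probabilities`: the conditional complication chain per arm as
#'   occurrence/denominator counts estimated from the reconstructed
#'   reference cohort ([reference_cohort()]).
#' * `los`: mean length-of-stay model. Per-complication additive increments
#'   are fixed at clinically motivated values (ICU: +1 day under NOAF,
#'   +4 under low cardiac output, +3 under renal failure, +2 under
#'   prolonged ventilation; ward: +0.5 under NOAF, +1 under renal failure)
#'   and the per-arm base days are solved so the rolled-back strategy means
#'   equal the observed per-strategy means (ICU 2.50 / 5.70 days, ward
#'   6.46 / 6.40 days).
#' * `profiles`: resource-use quantities, see [default_profiles()].
#' * `psa`: probabilistic-analysis settings -- draws, beta
#'   effective-sample-size multiplier `ess`, gamma/uniform spread
#'   fractions, whether unit-cost draws are shared between strategies, and
#'   the interval level. See the methods vignette for the calibration of
#'   `ess`.
#'
#' @return A validated configuration list.
#' @seealso [load_model_config()], [write_model_config()], [base_case()]
#' @export
default_model_config <- function() {
  probabilities <- unclass(estimate_probabilities(reference_cohort()))
  icu_increment <- c(noaf = 1, lco = 4, rf = 3, mv = 2)
  ward_increment <- c(noaf = 0.5, lco = 0, rf = 1, mv = 0)
  # strategy-level mean stays observed per cohort (calibration targets)
  icu_target <- c(intervention = 2.50, control = 5.70)
  ward_target <- c(intervention = 6.46, control = 6.40)
  base_for <- function(target, increment) {
    vapply(arm_levels, function(arm) {
      m <- implied_marginals(probabilities[[arm]])
      target[[arm]] - sum(m * increment[names(m)])
    }, numeric(1))
  }
  config <- list(
    probabilities = probabilities,
    los = list(
      icu_base = base_for(icu_target, icu_increment),
      ward_base = base_for(ward_target, ward_increment),
      icu_increment = icu_increment,
      ward_increment = ward_increment
    ),
    profiles = default_profiles(),
    psa = list(
      n_draws = 10000,
      ess = 75,
      gamma_bound = 0.10,
      uniform_bound = 0.10,
      shared_cost_draws = TRUE,
      ci_level = 0.95
    )
  )
  validate_model_config(config)
}

#' Validate a model configuration
#'
#' @param config A configuration list shaped like
#'   [default_model_config()].
#' @return The configuration, invisibly usable in a pipe.
#' @export
validate_model_config <- function(config) {
  needed <- c("probabilities", "los", "profiles", "psa")
  missing <- setdiff(needed, names(config))
  if (length(missing) > 0) {
    abort_levo(sprintf("model config is missing block(s): %s",
                       paste(missing, collapse = ", ")),
               "levoCEA_configuration_error")
  }
  for (arm in arm_levels) {
    if (is.null(config$probabilities[[arm]])) {
      abort_levo(sprintf("probabilities block missing arm `%s`", arm),
                 "levoCEA_configuration_error")
    }
    prob_points(config$probabilities[[arm]])  # validates range
  }
  for (blk in c("icu_base", "ward_base")) {
    v <- unlist(config$los[[blk]])[arm_levels]
    if (any(!is.finite(v)) || any(v < 0)) {
      abort_levo(sprintf("los$%s must be finite, >= 0, per arm", blk),
                 "levoCEA_configuration_error")
    }
  }
  for (blk in c("icu_increment", "ward_increment")) {
    v <- unlist(config$los[[blk]])[c("noaf", "lco", "rf", "mv")]
    if (any(!is.finite(v)) || any(v < 0)) {
      abort_levo(sprintf("los$%s must be finite, >= 0, per complication",
                         blk),
                 "levoCEA_configuration_error")
    }
  }
  for (prof in names(config$profiles)) {
    q <- config$profiles[[prof]]
    if (length(q) > 0 && (is.null(names(q)) || any(!is.finite(unlist(q))) ||
                          any(unlist(q) < 0))) {
      abort_levo(sprintf("profile `%s` must be named, finite, >= 0", prof),
                 "levoCEA_configuration_error")
    }
  }
  psa <- config$psa
  if (is.null(psa$n_draws) || psa$n_draws < 1) {
    abort_levo("psa$n_draws must be >= 1", "levoCEA_configuration_error")
  }
  if (is.null(psa$ess) || psa$ess <= 0) {
    abort_levo("psa$ess must be > 0", "levoCEA_configuration_error")
  }
  for (b in c("gamma_bound", "uniform_bound")) {
    if (is.null(psa[[b]]) || psa[[b]] < 0 || psa[[b]] >= 1) {
      abort_levo(sprintf("psa$%s must be in [0, 1)", b),
                 "levoCEA_configuration_error")
    }
  }
  if (is.null(psa$ci_level) || psa$ci_level <= 0 || psa$ci_level >= 1) {
    abort_levo("psa$ci_level must be in (0, 1)",
               "levoCEA_configuration_error")
  }
  invisible(config)
}

#' Write a model configuration to YAML
#'
#' @param config Configuration list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_config <- function(config, path) {
  validate_model_config(config)
  serializable <- config
  serializable$los <- lapply(config$los, as.list)
  serializable$profiles <- lapply(config$profiles, as.list)
  yaml::write_yaml(serializable, path, precision = 15)
  invisible(path)
}

#' Load a model configuration from YAML
#'
#' @param path YAML file; defaults to the packaged calibrated
#'   configuration, which mirrors [default_model_config()].
#' @return A validated configuration list.
#' @export
load_model_config <- function(path = system.file("extdata",
                                                 "model_config.yaml",
                                                 package = "levoCEA")) {
  raw <- yaml::read_yaml(path)
  for (blk in c("icu_base", "ward_base", "icu_increment",
                "ward_increment")) {
    raw$los[[blk]] <- unlist(raw$los[[blk]])
  }
  raw$profiles <- lapply(raw$profiles, unlist)
  validate_model_config(raw)
  raw
}
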