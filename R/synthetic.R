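#' Parameters for the synthetic-cohort generator
#'
#' Bundles the generating parameters of [generate_cohort()]: arm sizes, the
#' conditional complication chain per arm (new-onset atrial fibrillation
#' upstream of low cardiac output; renal failure and prolonged ventilation
#' conditionally independent given LCO; cardiogenic shock as the severe
#' extreme of LCO; death only among shock patients), the probability of the
#' LVEF < 35% stratum, and log-normal length-of-stay distributions per
#' (arm, complication-free) cell.
#'
#' Defaults are the conditions of the two-arm study the model describes:
#' 13 intervention vs 41 control patients, event probabilities equal to the
#' reference-cohort conditionals (see [reference_cohort()]), and stay
#' distributions whose cell means match the reference cohort.
#'
#' @param n_intervention,n_control Arm sizes.
#' @param probabilities Per-arm named list of conditional probabilities
#'   (`noaf`, `lco_given_noaf`, `lco_given_no_noaf`, `rf_given_lco`,
#'   `rf_given_no_lco`, `mv_given_lco`, `mv_given_no_lco`,
#'   `shock_given_lco`, `death_given_shock`).
#' @param lvef_lt35_probability Per-arm probability of the LVEF < 35%
#'   stratum.
#' @param los Per-arm, per-stay, per-cell log-normal `meanlog`/`sdlog`
#'   (see defaults for the structure).
#' @param seed Integer seed stored with the parameters; `NULL` to use the
#'   current RNG state.
#' @return List of class `cohort_gen_params`.
#' @export
cohort_gen_params <- function(n_intervention = 13,
                              n_control = 41,
                              probabilities = NULL,
                              lvef_lt35_probability = c(intervention = 8 / 13,
                                                        control = 8 / 41),
                              los = NULL,
                              seed = NULL) {
  if (n_intervention < 1 || n_control < 1) {
    abort_levo("arm sizes must be >= 1", "levoCEA_validation_error")
  }
  probabilities <- probabilities %||% list(
    intervention = list(
      noaf = 2 / 13, lco_given_noaf = 0, lco_given_no_noaf = 2 / 11,
      rf_given_lco = 0, rf_given_no_lco = 1 / 11,
      mv_given_lco = 0, mv_given_no_lco = 1 / 11,
      shock_given_lco = 0, death_given_shock = 0.5
    ),
    control = list(
      noaf = 9 / 41, lco_given_noaf = 7 / 9, lco_given_no_noaf = 18 / 32,
      rf_given_lco = 9 / 25, rf_given_no_lco = 1 / 16,
      mv_given_lco = 8 / 25, mv_given_no_lco = 1 / 16,
      shock_given_lco = 10 / 25, death_given_shock = 5 / 10
    )
  )
  for (arm in arm_levels) {
    for (p in names(probabilities[[arm]])) {
      assert_probability(probabilities[[arm]][[p]],
                         paste0(arm, "$", p))
    }
    assert_probability(lvef_lt35_probability[[arm]],
                       paste0("lvef_lt35_probability[", arm, "]"))
  }
  # cell means follow the reference cohort; location = log(mean) - scale^2/2
  lcell <- function(mean, sdlog) c(meanlog = log(mean) - sdlog^2 / 2,
                                   sdlog = sdlog)
  los <- los %||% list(
    intervention = list(
      icu = list(free = lcell(1.43, 0.35), complicated = lcell(3.67, 0.30)),
      ward = list(free = lcell(4.43, 0.20), complicated = lcell(8.83, 0.20))
    ),
    control = list(
      icu = list(free = lcell(2.85, 0.30), complicated = lcell(7.04, 0.35)),
      ward = list(free = lcell(4.46, 0.20), complicated = lcell(7.29, 0.25))
    )
  )
  for (arm in arm_levels) {
    for (stay in c("icu", "ward")) {
      for (cell in c("free", "complicated")) {
        s <- los[[arm]][[stay]][[cell]][["sdlog"]]
        if (!is.finite(s) || s <= 0) {
          abort_levo("log-normal scale parameters must be > 0",
                     "levoCEA_validation_error")
        }
      }
    }
  }
  structure(
    list(n_intervention = n_intervention, n_control = n_control,
         probabilities = probabilities,
         lvef_lt35_probability = lvef_lt35_probability,
         los = los, seed = seed),
    class = "cohort_gen_params"
  )
}

#' Generate a synthetic two-arm cohort
#'
#' Draws independent patients along the conditional chain
#' NOAF -> LCO -> \{renal failure, prolonged ventilation, shock\}, with
#' death only among shock patients, and log-normal ICU/ward stays per
#' (arm, complication-free) cell. Reproducible given the seed.
#'
#' @param params A [cohort_gen_params()] object.
#' @param seed Overrides `params$seed` when given.
#' @return A validated cohort tibble (see [read_cohort()] for the schema).
#' @export
#' @examples
#' generate_cohort(cohort_gen_params(seed = 1))
generate_cohort <- function(params = cohort_gen_params(), seed = NULL) {
  stopifnot(inherits(params, "cohort_gen_params"))
  seed <- seed %||% params$seed
  if (!is.null(seed)) set.seed(seed)
  arms <- lapply(arm_levels, function(arm) {
    n <- if (arm == "intervention") params$n_intervention else params$n_control
    p <- params$probabilities[[arm]]
    noaf <- rbinom(n, 1, p$noaf) == 1
    lco <- rbinom(n, 1, ifelse(noaf, p$lco_given_noaf,
                               p$lco_given_no_noaf)) == 1
    rf <- rbinom(n, 1, ifelse(lco, p$rf_given_lco, p$rf_given_no_lco)) == 1
    mv <- rbinom(n, 1, ifelse(lco, p$mv_given_lco, p$mv_given_no_lco)) == 1
    shock <- lco & rbinom(n, 1, p$shock_given_lco) == 1
    death <- shock & rbinom(n, 1, p$death_given_shock) == 1
    lt35 <- rbinom(n, 1, params$lvef_lt35_probability[[arm]]) == 1
    free <- !(noaf | lco | rf | mv)
    cell <- ifelse(free, "free", "complicated")
    draw_los <- function(stay) {
      pars <- params$los[[arm]][[stay]]
      rlnorm(n,
             meanlog = ifelse(free, pars$free[["meanlog"]],
                              pars$complicated[["meanlog"]]),
             sdlog = ifelse(free, pars$free[["sdlog"]],
                            pars$complicated[["sdlog"]]))
    }
    tibble(
      id = sprintf("%s%04d", toupper(substr(arm, 1, 1)), seq_len(n)),
      arm = arm,
      lvef_stratum = ifelse(lt35, "lvef_lt_35", "lvef_35_40"),
      noaf = noaf, lco = lco, cardiogenic_shock = shock,
      renal_failure = rf, prolonged_mv = mv, death = death,
      icu_los = draw_los("icu"), ward_los = draw_los("ward")
    )
  })
  validate_cohort(dplyr::bind_rows(arms))
}

#' Reconstructed 54-patient reference cohort
#'
#' A deterministic per-patient cohort consistent with every published
#' arm-level constraint of the two-arm study: arm sizes 13 vs 41; event
#' margins (NOAF 2 vs 9, LCO 2 vs 25, cardiogenic shock 0 vs 10, renal
#' failure 1 vs 10, prolonged ventilation 1 vs 9, deaths 0 vs 5); LVEF
#' strata 5/8 vs 33/8 with stratum-level LCO 0/2 vs 20/5; complication-free
#' counts 7 of 13 and 13 of 41; and integer stays matching the reported
#' medians and interquartile ranges (ICU 2 (1-4) vs 4 (3-6); ward 6 (4-8)
#' vs 5 (4-9)).
#'
#' The joint event assignment (which patients co-occur events) is
#' unpublished; this cohort is one canonical solution of the published
#' constraint system, labelled a reconstruction: in the intervention arm the
#' constraint counts force exactly one complication per complicated patient,
#' and in the control arm events are concentrated on low-cardiac-output
#' patients (shock on the first 10 LCO patients, deaths on the first 5).
#' Conditionals estimated from it are calibration artifacts, not published
#' values.
#'
#' @return A validated 54-row cohort tibble; byte-stable across calls.
#' @seealso [validate_fixture()]
#' @export
reference_cohort <- function() {
  int <- tibble(
    id = sprintf("I%02d", 1:13),
    arm = "intervention",
    lvef_stratum = rep(c("lvef_35_40", "lvef_lt_35"), c(5, 8)),
    noaf = sprintf("I%02d", 1:13) %in% c("I01", "I08"),
    lco = sprintf("I%02d", 1:13) %in% c("I06", "I07"),
    cardiogenic_shock = FALSE,
    renal_failure = sprintf("I%02d", 1:13) == "I02",
    prolonged_mv = sprintf("I%02d", 1:13) == "I09",
    death = FALSE,
    icu_los = c(2, 4, 1, 1, 1, 5, 4, 3, 4, 1, 2, 2, 2),
    ward_los = c(7, 8, 3, 4, 4, 12, 11, 7, 8, 4, 5, 5, 6)
  )
  k <- 1:41
  ctl <- tibble(
    id = sprintf("C%02d", k),
    arm = "control",
    lvef_stratum = ifelse(k <= 20 | (k >= 26 & k <= 38),
                          "lvef_35_40", "lvef_lt_35"),
    noaf = k %in% c(1:7, 26, 27),
    lco = k <= 25,
    cardiogenic_shock = k <= 10,
    renal_failure = k %in% c(1:9, 26),
    prolonged_mv = k %in% c(10:17, 28),
    death = k <= 5,
    icu_los = c(18, 14, 13, 12, 11, 10, 9, 8, 7, 7,
                6, 6, 6, 6, 6, 5, 5, 5, 4, 4, 4, 4, 4, 4, 4,
                5, 4, 6, 1, 2, 2, 3, 3, 3, 3, 3, 3, 3, 3, 4, 4),
    ward_los = c(2, 3, 3, 4, 4, 12, 12, 11, 10, 10,
                 10, 9, 9, 9, 9, 9, 8, 8, 8, 7, 7, 7, 6, 6, 6,
                 5, 5, 5, 4, 4, 4, 4, 4, 4, 4, 5, 5, 5, 5, 5, 5)
  )
  validate_cohort(dplyr::bind_rows(int, ctl))
}

fixture_constraints <- function() {
  tibble::tribble(
    ~constraint, ~expected,
    "n intervention", 13,
    "n control", 41,
    "noaf intervention", 2, "noaf control", 9,
    "lco intervention", 2, "lco control", 25,
    "cardiogenic_shock intervention", 0, "cardiogenic_shock control", 10,
    "renal_failure intervention", 1, "renal_failure control", 10,
    "prolonged_mv intervention", 1, "prolonged_mv control", 9,
    "death intervention", 0, "death control", 5,
    "shock without lco", 0,
    "lvef_35_40 intervention", 5, "lvef_lt_35 intervention", 8,
    "lvef_35_40 control", 33, "lvef_lt_35 control", 8,
    "lco in lvef_35_40 intervention", 0, "lco in lvef_35_40 control", 20,
    "lco in lvef_lt_35 intervention", 2, "lco in lvef_lt_35 control", 5,
    "complication-free intervention", 7, "complication-free control", 13
  )
}

#' Validate the reference cohort against its published constraints
#'
#' Checks every arm-level margin, stratum count, subset relation and
#' complication-free total the reconstruction must satisfy. Failures are
#' reported, not raised.
#'
#' @param cohort A cohort tibble, typically [reference_cohort()].
#' @return Tibble with one row per constraint: `constraint`, `expected`,
#'   `observed`, `pass`.
#' @export
validate_fixture <- function(cohort) {
  missing <- setdiff(cohort_columns, names(cohort))
  if (length(missing) > 0) {
    abort_levo(sprintf("cohort is missing column(s): %s",
                       paste(missing, collapse = ", ")),
               "levoCEA_schema_error")
  }
  observe <- function(what) {
    parts <- strsplit(what, " ")[[1]]
    if (what == "shock without lco") {
      return(sum(cohort$cardiogenic_shock & !cohort$lco))
    }
    if (parts[1] == "n") {
      return(sum(cohort$arm == parts[2]))
    }
    if (parts[1] == "lvef_35_40" || parts[1] == "lvef_lt_35") {
      return(sum(cohort$arm == parts[2] & cohort$lvef_stratum == parts[1]))
    }
    if (parts[1] == "lco" && parts[2] == "in") {
      return(sum(cohort$arm == parts[4] & cohort$lvef_stratum == parts[3] &
                   cohort$lco))
    }
    if (parts[1] == "complication-free") {
      sub <- cohort[cohort$arm == parts[2], ]
      return(sum(!(sub$noaf | sub$lco | sub$renal_failure |
                     sub$prolonged_mv)))
    }
    sum(cohort$arm == parts[2] & cohort[[parts[1]]])
  }
  checks <- fixture_constraints()
  checks$observed <- vapply(checks$constraint, observe, numeric(1))
  checks$pass <- checks$observed == checks$expected
  checks
}
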