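catalogue_categories <- c("procedure", "test", "medication", "stay")

#' Default hospital unit-cost catalogue
#'
#' The 23-item unit-cost catalogue from hospital accounting, in euros:
#' procedures (surgery, hemofilter kit, mechanical ventilation at ICU),
#' supplemental tests (laboratory profile, electrocardiogram,
#' echocardiogram), medications (including the levosimendan vial-course at
#' 581.63) and stay day rates (coronary care unit, ICU, hospital ward).
#'
#' @return A tibble with columns `code`, `label`, `category`, `unit_cost`.
#' @seealso [load_catalogue()], [pathway_cost()]
#' @export
default_catalogue <- function() {
  tibble::tribble(
    ~code,                ~label,                                        ~category,    ~unit_cost,
    "surgery",            "Surgery",                                     "procedure",  6269.20,
    "hemofilter_kit",     "Hemofilter kit",                              "procedure",  173.82,
    "mech_vent_icu",      "Mechanical ventilation at ICU (day)",         "procedure",  460.00,
    "lab_profile",        "Laboratory profile",                          "test",       85.96,
    "ecg",                "Electrocardiogram",                           "test",       20.37,
    "echo",               "Echocardiogram",                              "test",       120.36,
    "amiodarone_tab",     "Amiodarone prophylaxis (tablet)",             "medication", 0.11,
    "amiodarone_iv",      "Amiodarone 150 mg (IV ampoule)",              "medication", 0.25,
    "furosemide_iv",      "Furosemide 20 mg (IV ampoule)",               "medication", 0.13,
    "atorvastatin",       "Atorvastatin 20 mg (tablet)",                 "medication", 0.07,
    "bisoprolol",         "Bisoprolol 5 mg (tablet)",                    "medication", 0.08,
    "asa",                "Acetylsalicylic acid 100 mg (tablet)",        "medication", 0.03,
    "dalteparin",         "Dalteparin 5000 IU (SC, prefilled syringe)",  "medication", 0.31,
    "acetaminophen_iv",   "Acetaminophen 1 g IV (vial)",                 "medication", 0.53,
    "norepinephrine",     "Norepinephrine 10 mg (1 vial)",               "medication", 0.95,
    "dobutamine",         "Dobutamine 250 mg (1 vial)",                  "medication", 1.38,
    "levosimendan",       "Levosimendan (vial-course)",                  "medication", 581.63,
    "oral_paste",         "Oral paste/day",                              "medication", 5.50,
    "decontam_solution",  "Decontaminating solution",                    "medication", 10.00,
    "effluent_bag",       "Effluent bag",                                "medication", 8.98,
    "ccu_day",            "Coronary care unit (day)",                    "stay",       909.79,
    "icu_day",            "ICU (day)",                                   "stay",       1266.95,
    "ward_day",           "Hospital ward (day)",                         "stay",       234.12
  )
}

validate_catalogue <- function(cat) {
  required <- c("code", "label", "category", "unit_cost")
  missing <- setdiff(required, names(cat))
  if (length(missing) > 0) {
    abort_levo(sprintf("catalogue is missing column(s): %s",
                       paste(missing, collapse = ", ")),
               "levoCEA_schema_error")
  }
  dup <- cat$code[duplicated(cat$code)]
  if (length(dup) > 0) {
    abort_levo(sprintf("duplicate catalogue code(s): %s",
                       paste(unique(dup), collapse = ", ")),
               "levoCEA_validation_error")
  }
  if (any(!cat$category %in% catalogue_categories)) {
    abort_levo(sprintf("catalogue categories must be one of %s",
                       paste(catalogue_categories, collapse = ", ")),
               "levoCEA_validation_error")
  }
  if (any(!is.finite(cat$unit_cost)) || any(cat$unit_cost < 0)) {
    abort_levo("unit costs must be finite and >= 0",
               "levoCEA_validation_error")
  }
  cat
}

#' Load a unit-cost catalogue
#'
#' Reads a catalogue CSV (columns `code`, `label`, `category`, `unit_cost`)
#' and overlays it on the packaged defaults: listed codes override the
#' default entry, codes outside the default catalogue are rejected, and
#' omitted codes keep their default cost.
#'
#' @param path CSV file; defaults to the packaged catalogue.
#' @return A validated catalogue tibble.
#' @export
load_catalogue <- function(path = system.file("extdata",
                                              "cost_catalogue.csv",
                                              package = "levoCEA")) {
  cat <- readr::read_csv(path, col_types = "cccd", progress = FALSE)
  cat <- validate_catalogue(cat)
  base <- default_catalogue()
  unknown <- setdiff(cat$code, base$code)
  if (length(unknown) > 0) {
    abort_levo(sprintf("unknown catalogue code(s): %s",
                       paste(unknown, collapse = ", ")),
               "levoCEA_validation_error")
  }
  idx <- match(cat$code, base$code)
  base[idx, c("label", "category", "unit_cost")] <-
    cat[, c("label", "category", "unit_cost")]
  base
}

#' Write a unit-cost catalogue
#'
#' Costs are written with two decimals so that a write/load round trip is the
#' identity on euro amounts.
#'
#' @param cat A catalogue tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_catalogue <- function(cat, path) {
  cat <- validate_catalogue(cat)
  out <- cat
  out$unit_cost <- sprintf("%.2f", out$unit_cost)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

unit_costs <- function(cat) setNames(cat$unit_cost, cat$code)

#' Cost of a resource-use profile
#'
#' A resource profile is a named vector of non-negative quantities keyed by
#' catalogue code (stays expressed in days). The cost is the quantity-
#' weighted sum of unit costs, so it is linear in every quantity; the
#' breakdown is reported per catalogue category.
#'
#' @param profile Named numeric vector of quantities.
#' @param catalogue A catalogue tibble.
#' @return List of class `pathway_cost` with elements `total` (euros) and
#'   `breakdown` (named vector by category).
#' @export
#' @examples
#' pathway_cost(c(icu_day = 2, surgery = 1), default_catalogue())
pathway_cost <- function(profile, catalogue = default_catalogue()) {
  catalogue <- validate_catalogue(catalogue)
  if (length(profile) == 0) {
    return(structure(
      list(total = 0,
           breakdown = setNames(rep(0, length(catalogue_categories)),
                                catalogue_categories)),
      class = "pathway_cost"
    ))
  }
  if (is.null(names(profile)) || any(names(profile) == "")) {
    abort_levo("profile quantities must be named by catalogue code",
               "levoCEA_validation_error")
  }
  if (any(!is.finite(profile)) || any(profile < 0)) {
    abort_levo("profile quantities must be finite and >= 0",
               "levoCEA_validation_error")
  }
  unknown <- setdiff(names(profile), catalogue$code)
  if (length(unknown) > 0) {
    abort_levo(sprintf("unknown catalogue code(s) in profile: %s",
                       paste(unknown, collapse = ", ")),
               "levoCEA_lookup_error")
  }
  idx <- match(names(profile), catalogue$code)
  item_cost <- profile * catalogue$unit_cost[idx]
  breakdown <- vapply(catalogue_categories, function(cg) {
    sum(item_cost[catalogue$category[idx] == cg])
  }, numeric(1))
  structure(list(total = sum(item_cost), breakdown = breakdown),
            class = "pathway_cost")
}

#' @export
print.pathway_cost <- function(x, ...) {
  cat(sprintf("pathway cost: %.2f EUR\n", x$total))
  print(round(x$breakdown, 2))
  invisible(x)
}

#' Upfront preconditioning resource profile
#'
#' The add-on consumed only by the intervention arm: the 24-h levosimendan
#' infusion started 48 h before surgery under coronary-care-unit monitoring,
#' followed by an extra pre-operative ward day. Defaults: one vial-course,
#' one coronary-care-unit day, one ward day (1725.54 EUR at default unit
#' costs). `extra` appends further quantities, e.g. monitoring tests during
#' the preconditioning admission.
#'
#' @param levosimendan_courses,coronary_days,ward_days Quantities.
#' @param extra Optional named vector of additional quantities.
#' @return Named quantity vector.
#' @export
#' @examples
#' pathway_cost(intervention_upfront_profile())$total # 1725.54
intervention_upfront_profile <- function(levosimendan_courses = 1,
                                         coronary_days = 1,
                                         ward_days = 1,
                                         extra = NULL) {
  prof <- c(levosimendan = levosimendan_courses,
            ccu_day = coronary_days,
            ward_day = ward_days)
  if (!is.null(extra)) prof <- c(prof, extra)
  prof
}

#' Default resource-use profiles
#'
#' The per-pathway resource quantities of the packaged model. These are not
#' tabulated in any source: they are reconstructed from the narrative
#' description of routine post-operative care (daily laboratory profile,
#' blood gases and ECG in the ICU, at least one echocardiogram, a
#' pre-discharge ECG, usual ward medication) and of the complication
#' add-ons (daily echocardiography and amines under low cardiac output,
#' hemofilter consumables under renal replacement, ventilation and selective
#' digestive decontamination under prolonged ventilation), then calibrated so
#' the rolled-back strategy expectations reproduce the observed per-strategy
#' costs; see the methods vignette. Every quantity is config-overridable.
#'
#' Profiles: `base` (fixed per patient, both arms), `per_icu_day` and
#' `per_ward_day` (multiplied by the pathway stay), `upfront_intervention`
#' (intervention arm only), and the complication add-ons `noaf`, `lco`,
#' `rf`, `mv`.
#'
#' @return Named list of named quantity vectors.
#' @export
default_profiles <- function() {
  list(
    base = c(surgery = 1, lab_profile = 1, ecg = 2, echo = 2),
    per_icu_day = c(icu_day = 1, lab_profile = 1.75, ecg = 1,
                    acetaminophen_iv = 3, furosemide_iv = 2, dalteparin = 1),
    per_ward_day = c(ward_day = 1, atorvastatin = 1, bisoprolol = 1,
                     asa = 1, dalteparin = 1),
    upfront_intervention = intervention_upfront_profile(
      extra = c(lab_profile = 3, ecg = 2, echo = 2)
    ),
    noaf = c(amiodarone_iv = 6, amiodarone_tab = 30),
    lco = c(echo = 4, dobutamine = 12, norepinephrine = 8),
    rf = c(hemofilter_kit = 1, effluent_bag = 10),
    mv = c(mech_vent_icu = 2, oral_paste = 2, decontam_solution = 1)
  )
}
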