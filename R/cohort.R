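#' Read a per-patient cohort table
#'
#' Reads the documented cohort CSV schema: one row per patient with columns
#' `id`, `arm` (`intervention`/`control`), `lvef_stratum` (`lvef_35_40` for
#' LVEF 35--40%, `lvef_lt_35` for LVEF < 35%), the six binary complication
#' flags `noaf`, `lco`, `cardiogenic_shock`, `renal_failure`, `prolonged_mv`,
#' `death` coded 0/1, and non-negative lengths of stay `icu_los`, `ward_los`
#' in days. Cardiogenic shock is the severe extreme of the low cardiac output
#' definition, so `cardiogenic_shock = 1` requires `lco = 1`.
#'
#' @param path Path to a CSV file with a header row.
#' @return A tibble with one validated patient record per row; flags as
#'   logicals.
#' @seealso [write_cohort()], [validate_cohort()], [reference_cohort()]
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) {
    abort_levo(sprintf("cohort file not found: %s", path), "levoCEA_io_error")
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  missing <- setdiff(cohort_columns, names(raw))
  if (length(missing) > 0) {
    abort_levo(
      sprintf("cohort file is missing column(s): %s",
              paste(missing, collapse = ", ")),
      "levoCEA_schema_error"
    )
  }
  if (nrow(raw) == 0) {
    return(empty_cohort())
  }
  flags <- lapply(cohort_flags, function(fl) {
    v <- raw[[fl]]
    bad <- which(!v %in% c("0", "1"))
    if (length(bad) > 0) {
      abort_levo(
        sprintf("column `%s` must be 0/1; offending row(s): %s", fl,
                paste(bad, collapse = ", ")),
        "levoCEA_parse_error"
      )
    }
    v == "1"
  })
  names(flags) <- cohort_flags
  records <- tibble(
    id = raw$id,
    arm = raw$arm,
    lvef_stratum = raw$lvef_stratum,
    !!!flags,
    icu_los = suppressWarnings(as.numeric(raw$icu_los)),
    ward_los = suppressWarnings(as.numeric(raw$ward_los))
  )
  validate_cohort(records)
}

empty_cohort <- function() {
  tibble(
    id = character(), arm = character(), lvef_stratum = character(),
    noaf = logical(), lco = logical(), cardiogenic_shock = logical(),
    renal_failure = logical(), prolonged_mv = logical(), death = logical(),
    icu_los = numeric(), ward_los = numeric()
  )
}

#' Validate a cohort table
#'
#' Checks the enum fields, the non-negativity of the stays, and the
#' consistency invariant that cardiogenic shock implies low cardiac output.
#'
#' @param records A cohort tibble as returned by [read_cohort()].
#' @return The validated records, invisibly usable in a pipe.
#' @export
validate_cohort <- function(records) {
  missing <- setdiff(cohort_columns, names(records))
  if (length(missing) > 0) {
    abort_levo(
      sprintf("cohort is missing column(s): %s",
              paste(missing, collapse = ", ")),
      "levoCEA_schema_error"
    )
  }
  bad_arm <- which(!records$arm %in% arm_levels)
  if (length(bad_arm) > 0) {
    abort_levo(
      sprintf("`arm` must be one of %s; offending row(s): %s",
              paste(arm_levels, collapse = "/"),
              paste(bad_arm, collapse = ", ")),
      "levoCEA_parse_error"
    )
  }
  bad_str <- which(!records$lvef_stratum %in% lvef_levels)
  if (length(bad_str) > 0) {
    abort_levo(
      sprintf("`lvef_stratum` must be one of %s; offending row(s): %s",
              paste(lvef_levels, collapse = "/"),
              paste(bad_str, collapse = ", ")),
      "levoCEA_parse_error"
    )
  }
  shock_no_lco <- which(records$cardiogenic_shock & !records$lco)
  if (length(shock_no_lco) > 0) {
    abort_levo(
      sprintf(paste0("cardiogenic shock without low cardiac output in ",
                     "row(s): %s (shock is the severe extreme of LCO)"),
              paste(shock_no_lco, collapse = ", ")),
      "levoCEA_consistency_error"
    )
  }
  for (col in c("icu_los", "ward_los")) {
    v <- records[[col]]
    bad <- which(!is.finite(v) | v < 0)
    if (length(bad) > 0) {
      abort_levo(
        sprintf("`%s` must be finite and >= 0; offending row(s): %s", col,
                paste(bad, collapse = ", ")),
        "levoCEA_parse_error"
      )
    }
  }
  records
}

#' Write a cohort table
#'
#' Inverse of [read_cohort()]: flags are written as 0/1.
#'
#' @param records A validated cohort tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(records, path) {
  records <- validate_cohort(records)
  out <- records
  for (fl in cohort_flags) out[[fl]] <- as.integer(out[[fl]])
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
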