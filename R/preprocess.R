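#' Inclusion criteria for the analysis sample
#'
#' Young-adult never cigarette smokers who are never or current e-cigarette
#' users: age within `[age_min, age_max]`, strictly fewer than
#' `lifetime_cigarette_threshold` cigarettes smoked lifetime, and an
#' e-cigarette status among `eligible_ecig_statuses` (former users are
#' excluded from the table entirely).
#'
#' @param age_min,age_max Age bounds in years (inclusive).
#' @param lifetime_cigarette_threshold Lifetime-cigarette count defining a
#'   never-smoker (strictly fewer).
#' @param eligible_ecig_statuses E-cigarette statuses retained.
#' @return An `inclusion_criteria` object.
#' @export
inclusion_criteria <- function(age_min = 18, age_max = 34,
                               lifetime_cigarette_threshold = 100,
                               eligible_ecig_statuses = c("never", "current")) {
  if (age_min > age_max || lifetime_cigarette_threshold <= 0) {
    abort("Invalid inclusion criteria.", class = "svystab_config_error")
  }
  structure(list(age_min = age_min, age_max = age_max,
                 lifetime_cigarette_threshold = lifetime_cigarette_threshold,
                 eligible_ecig_statuses = eligible_ecig_statuses),
            class = "inclusion_criteria")
}

#' Apply the inclusion criteria
#'
#' Keeps records satisfying all three criteria, preserving row order.
#' Idempotent: applying it twice equals applying it once.
#'
#' @param data Respondent tibble with `age`, `cigarettes_lifetime` and
#'   `ecig_status` columns.
#' @param criteria An [inclusion_criteria()].
#' @return The filtered tibble.
#' @export
apply_inclusion <- function(data, criteria = inclusion_criteria()) {
  check_columns(data, c("age", "cigarettes_lifetime", "ecig_status"),
                "apply_inclusion")
  keep <- data$age >= criteria$age_min & data$age <= criteria$age_max &
    data$cigarettes_lifetime < criteria$lifetime_cigarette_threshold &
    as_level_chr(data$ecig_status) %in% criteria$eligible_ecig_statuses
  out <- data[which(keep), , drop = FALSE]
  attr(out, "roles") <- attr(data, "roles")
  out
}

#' Derive the disability profile
#'
#' Appends `any_disability`: `"yes"` if at least one of the six type columns
#' is `"yes"`; `"no"` if all six are `"no"`; otherwise `"Missing"` (some
#' answers missing and none affirmative), in which case the record cannot be
#' classified for the any-disability subgroup.
#'
#' @param data Respondent tibble carrying the six [disability_types()]
#'   columns with values `"yes"`, `"no"` or `"Missing"`.
#' @return The tibble with an `any_disability` factor column appended.
#' @export
derive_disability <- function(data) {
  check_columns(data, disability_types(), "derive_disability")
  mat <- vapply(disability_types(), function(dt) as_level_chr(data[[dt]]),
                character(nrow(data)))
  mat <- matrix(mat, nrow = nrow(data))
  ok <- mat %in% c("yes", "no", MISSING_LEVEL) | is.na(mat)
  if (!all(ok)) {
    abort(sprintf("Unknown disability level(s): %s",
                  paste(unique(mat[!ok]), collapse = ", ")),
          class = "svystab_schema_error")
  }
  mat[is.na(mat)] <- MISSING_LEVEL
  any_yes <- rowSums(mat == "yes") > 0
  all_no <- rowSums(mat == "no") == length(disability_types())
  data$any_disability <- factor(
    dplyr::case_when(any_yes ~ "yes", all_no ~ "no", TRUE ~ MISSING_LEVEL),
    levels = c("no", "yes", MISSING_LEVEL)
  )
  data
}

#' Collapse refused/not-sure/don't-know codes into the explicit Missing level
#'
#' All declared sentinel codes of a column become the single category
#' `"Missing"`; `NA` entries in declared columns are collapsed too.
#' Optional gate-question backfill rules run first: when a record was never
#' asked a question (it is missing/sentinel) but the answer is implied by a
#' fully observed gate question, the implied value is filled in instead.
#'
#' @param data Respondent tibble.
#' @param sentinels Named list: for each column, the character vector of
#'   sentinel codes (e.g. `list(income = c("7", "9"))`).
#' @param backfill List of rules `list(variable=, gate=, gate_level=, value=)`:
#'   where `gate == gate_level` and `variable` is missing or sentinel, set
#'   `variable` to `value`.
#' @param genuine_levels Optional named list of each column's genuine
#'   (non-sentinel) levels; a sentinel also listed as genuine raises a
#'   configuration error.
#' @return The recoded tibble; factor columns gain a `"Missing"` level.
#' @export
recode_missing <- function(data, sentinels = list(), backfill = list(),
                           genuine_levels = list()) {
  check_columns(data, names(sentinels), "recode_missing")
  for (nm in names(sentinels)) {
    clash <- intersect(sentinels[[nm]], genuine_levels[[nm]])
    if (length(clash) > 0) {
      abort(sprintf("Sentinel code(s) %s for '%s' collide with genuine levels.",
                    paste(clash, collapse = ", "), nm),
            class = "svystab_config_error")
    }
  }
  is_missing_code <- function(x, nm) {
    is.na(x) | x %in% sentinels[[nm]] | x == MISSING_LEVEL
  }
  for (rule in backfill) {
    check_columns(data, c(rule$variable, rule$gate), "recode_missing")
    x <- as_level_chr(data[[rule$variable]])
    gate <- as_level_chr(data[[rule$gate]])
    fill <- is_missing_code(x, rule$variable) & !is.na(gate) &
      gate == rule$gate_level
    x[fill] <- rule$value
    data[[rule$variable]] <- x
  }
  for (nm in names(sentinels)) {
    x <- as_level_chr(data[[nm]])
    x[is_missing_code(x, nm)] <- MISSING_LEVEL
    kept <- setdiff(unique(x[!is.na(x)]), MISSING_LEVEL)
    data[[nm]] <- factor(x, levels = c(kept, MISSING_LEVEL))
  }
  data
}

#' Adjust weights for combined survey years
#'
#' Each analysis weight is divided by the number of combined years (the
#' equal-allocation variant for full-size annual samples), and the year
#' label is folded into the stratum identifier so that variance strata
#' never span years.  Relative weights within a year are preserved exactly.
#'
#' @param data Respondent tibble with `weight`, `stratum` and `year`.
#' @param n_years Number of combined survey years.
#' @return The tibble with adjusted `weight` and year-unique `stratum`.
#' @export
adjust_weights_for_combined_years <- function(data, n_years) {
  check_columns(data, c("weight", "stratum", "year"), "adjust_weights")
  if (n_years < 1) {
    abort("n_years must be >= 1.", class = "svystab_config_error")
  }
  data$weight <- data$weight / n_years
  if (n_years > 1) {
    data$stratum <- paste(data$year, data$stratum, sep = ":")
  }
  data
}

#' Build a disability subgroup
#'
#' Returns records who report the disability of interest plus records who
#' report no disability at all; records with other disabilities only, or
#' whose missing answers block classification, are excluded.  Appends
#' `exposure_flag` (1 = has the disability of interest, 0 = no disability).
#'
#' @param data Respondent tibble after [derive_disability()].
#' @param disability `"any"` or one of [disability_types()].
#' @return The subgroup tibble with an `exposure_flag` column.
#' @export
build_subgroup <- function(data, disability) {
  if (!disability %in% c("any", disability_types())) {
    abort(sprintf("Unknown disability '%s'.", disability),
          class = "svystab_config_error")
  }
  check_columns(data, "any_disability", "build_subgroup")
  any_d <- as_level_chr(data$any_disability)
  if (disability == "any") {
    keep <- any_d %in% c("yes", "no")
    flag <- as.integer(any_d == "yes")
  } else {
    check_columns(data, disability, "build_subgroup")
    d <- as_level_chr(data[[disability]])
    keep <- d == "yes" | any_d == "no"
    flag <- as.integer(d == "yes")
  }
  out <- data[which(keep), , drop = FALSE]
  out$exposure_flag <- flag[which(keep)]
  attr(out, "roles") <- attr(data, "roles")
  out
}
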