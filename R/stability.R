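#' Stability-selection configuration
#'
#' Settings for repeated-subsample LASSO selection: the number of
#' iterations, the subsample fraction, the CV fold count used to pick the
#' penalty within each iteration, and the selection-frequency threshold
#' (strict `>`).  The defaults are the full-scale settings (300 iterations,
#' 80% subsamples, 10-fold CV, threshold 0.95).
#'
#' @param n_iterations Number of subsample LASSO iterations.
#' @param subsample_fraction Fraction of records drawn without replacement
#'   per iteration (exactly `ceiling(fraction * n)` records).
#' @param cv_folds Folds for within-iteration cross-validation.
#' @param selection_threshold Frequency a variable must strictly exceed.
#' @param seed Master seed; each iteration gets its own derived stream.
#' @param cv_seed Optional fixed CV seed shared by all iterations (with
#'   `subsample_fraction = 1` this makes every iteration identical).
#' @param max_redraws Retries when a subsample loses a response class.
#' @return A `stability_config` object.
#' @export
stability_config <- function(n_iterations = 300, subsample_fraction = 0.8,
                             cv_folds = 10, selection_threshold = 0.95,
                             seed = 1, cv_seed = NULL, max_redraws = 25) {
  if (subsample_fraction <= 0 || subsample_fraction > 1 ||
      selection_threshold <= 0 || selection_threshold >= 1 || cv_folds < 2 ||
      n_iterations < 1) {
    abort("Invalid stability configuration.", class = "svystab_config_error")
  }
  structure(list(n_iterations = n_iterations,
                 subsample_fraction = subsample_fraction,
                 cv_folds = cv_folds,
                 selection_threshold = selection_threshold,
                 seed = seed, cv_seed = cv_seed, max_redraws = max_redraws),
            class = "stability_config")
}

#' Stability selection for one endpoint
#'
#' Repeats, `n_iterations` times: draw a subsample without replacement,
#' build the one-hot design over the candidate variables, pick the penalty
#' by stratified cross-validation, and record which variables have a
#' nonzero non-missing-level coefficient at that penalty.  Reports each
#' variable's selection frequency and the set exceeding the threshold.
#'
#' @param data Respondent tibble.
#' @param endpoint Name of the binary endpoint column (0/1, or yes/no
#'   factor); candidates must not include it.
#' @param candidates Candidate variable names (design columns, the endpoint
#'   and the opposite endpoint excluded by the caller).
#' @param config A [stability_config()].
#' @return A `stability_report`: tibble with `variable`, `frequency`,
#'   `selected`, carrying the endpoint and config as attributes.
#' @export
stability_select <- function(data, endpoint, candidates,
                             config = stability_config()) {
  check_columns(data, c(endpoint, candidates), "stability_select")
  if (endpoint %in% candidates) {
    abort("The endpoint cannot be one of its own candidates.",
          class = "svystab_config_error")
  }
  y <- endpoint_binary(data[[endpoint]], endpoint)
  if (length(unique(y)) < 2) {
    abort(sprintf("Endpoint '%s' has a single class.", endpoint),
          class = "svystab_degenerate_error")
  }
  n <- nrow(data)
  n_sub <- ceiling(config$subsample_fraction * n)
  counts <- setNames(numeric(length(candidates)), candidates)

  for (it in seq_len(config$n_iterations)) {
    set.seed(seed_stream(config$seed, "subsample", it))
    idx <- sample.int(n, n_sub)
    tries <- 0
    while (length(unique(y[idx])) < 2 && tries < config$max_redraws) {
      idx <- sample.int(n, n_sub)
      tries <- tries + 1
    }
    if (length(unique(y[idx])) < 2) {
      abort("Subsample lost a response class after repeated redraws.",
            class = "svystab_degenerate_error")
    }
    dm <- build_design_matrix(data[idx, , drop = FALSE], candidates)
    cv_seed <- config$cv_seed %||% seed_stream(config$seed, "cv", it)
    cv <- select_lambda_min(dm$x, y[idx], nfolds = config$cv_folds,
                            seed = cv_seed)
    sel <- variable_selected_at(cv$coef_min, dm$map)
    hit <- sel$variable[sel$selected]
    counts[hit] <- counts[hit] + 1
  }

  out <- tibble::tibble(
    variable = candidates,
    frequency = unname(counts[candidates]) / config$n_iterations
  ) |>
    dplyr::mutate(selected = .data$frequency > config$selection_threshold) |>
    dplyr::arrange(dplyr::desc(.data$frequency))
  structure(out, endpoint = endpoint, config = config,
            class = c("stability_report", class(out)))
}

# accept 0/1, logical, or yes/no-style factors as a binary endpoint
endpoint_binary <- function(x, name) {
  if (is.numeric(x) || is.logical(x)) {
    v <- as.numeric(x)
    if (!all(v %in% c(0, 1))) {
      abort(sprintf("Endpoint '%s' must be binary 0/1.", name),
            class = "svystab_schema_error")
    }
    return(v)
  }
  v <- as_level_chr(x)
  if (MISSING_LEVEL %in% v) {
    abort(sprintf("Endpoint '%s' contains Missing values.", name),
          class = "svystab_schema_error")
  }
  lv <- sort(unique(v))
  if (identical(lv, c("no", "yes"))) return(as.numeric(v == "yes"))
  if (length(lv) == 2) return(as.numeric(v == lv[2]))
  abort(sprintf("Endpoint '%s' is not binary.", name),
        class = "svystab_schema_error")
}

#' Intersect the two endpoints' stability selections into a confounder set
#'
#' A variable is a potential confounder when it exceeds the selection
#' threshold for BOTH the disability endpoint and the e-cigarette endpoint
#' in the same subgroup.  The final adjustment set is the union of that
#' intersection with the forced demographics, which are always adjusted for
#' regardless of their selection frequencies.
#'
#' @param report_disability,report_outcome `stability_report`s for the
#'   disability-of-interest and outcome endpoints of one subgroup.
#' @param forced Character vector of forced demographics (default age,
#'   gender, race/ethnicity).
#' @param disability Label stored on the result.
#' @return A `confounder_set`: list with `confounders` (the intersection),
#'   `forced`, and `adjustment` (their union).
#' @export
intersect_confounders <- function(report_disability, report_outcome,
                                  forced = c("age", "gender", "race_ethnicity"),
                                  disability = NA_character_) {
  sel <- function(r) r$variable[r$selected]
  confounders <- intersect(sel(report_disability), sel(report_outcome))
  structure(list(disability = disability,
                 confounders = confounders,
                 forced = forced,
                 adjustment = union(forced, confounders)),
            class = "confounder_set")
}

#' @exportS3Method base::print
print.confounder_set <- function(x, ...) {
  cat("Confounder set", if (!is.na(x$disability)) paste0("(", x$disability, ")"),
      "\n  selected for both endpoints:",
      if (length(x$confounders)) paste(x$confounders, collapse = ", ") else "(none)",
      "\n  forced demographics:", paste(x$forced, collapse = ", "), "\n")
  invisible(x)
}
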