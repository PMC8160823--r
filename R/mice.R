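#' Multiple-imputation configuration
#'
#' @param m Number of imputed datasets (full-scale default 50).
#' @param n_chain_iterations Chained-equation sweeps per imputation stream
#'   (full-scale default 30).
#' @param seed Master seed; each stream gets a derived seed.
#' @param ridge Weight-decay penalty applied to every conditional model for
#'   separation robustness (well below estimation noise).
#' @return An `imputation_config` object.
#' @export
imputation_config <- function(m = 50, n_chain_iterations = 30, seed = 1,
                              ridge = 1e-6) {
  if (m < 1 || n_chain_iterations < 1) {
    abort("m and n_chain_iterations must be >= 1.",
          class = "svystab_config_error")
  }
  structure(list(m = m, n_chain_iterations = n_chain_iterations,
                 seed = seed, ridge = ridge),
            class = "imputation_config")
}

#' Multiple imputation by chained equations for explicit-Missing categories
#'
#' Imputes the `"Missing"` category of each listed categorical variable.
#' For each of `m` streams: missing cells are initialized by random draws
#' from the variable's observed marginal, then `n_chain_iterations` sweeps
#' refit each incomplete variable's conditional model -- a polytomous
#' (multinomial) regression for more than two observed categories, logistic
#' for binary -- on the currently completed data, with all other listed
#' variables plus the always-observed `extra_predictors` (outcome and
#' exposure) as predictors, and redraw the missing cells from the fitted
#' predictive distribution.  Variables are visited in increasing order of
#' missingness.  Observed cells are never altered, so they are identical
#' across all `m` completed datasets and equal to the input.
#'
#' @param data Respondent tibble.
#' @param variables Variables eligible for imputation (those without a
#'   `"Missing"` category pass through unchanged).
#' @param extra_predictors Fully observed columns used as predictors in
#'   every conditional model but never imputed (the outcome and exposure).
#' @param config An [imputation_config()].
#' @return An `imputation_set`: list with `datasets` (list of `m` completed
#'   tibbles), `trace` (per-stream, per-iteration imputed-category
#'   frequencies), and the config.
#' @export
impute_chained <- function(data, variables, extra_predictors = character(),
                           config = imputation_config()) {
  check_columns(data, c(variables, extra_predictors), "impute_chained")
  masks <- list()
  obs_levels <- list()
  for (v in variables) {
    x <- as_level_chr(data[[v]])
    if (is.numeric(data[[v]])) next  # continuous variables are complete
    miss <- x == MISSING_LEVEL | is.na(x)
    if (all(miss)) {
      abort(sprintf("Variable '%s' is 100%% missing; cannot impute.", v),
            class = "svystab_degenerate_error")
    }
    if (any(miss)) {
      masks[[v]] <- miss
      obs_levels[[v]] <- setdiff(
        if (is.factor(data[[v]])) {
          intersect(levels(data[[v]]), unique(x[!miss]))
        } else unique(x[!miss]),
        MISSING_LEVEL)
    }
  }
  incomplete <- names(masks)[order(vapply(masks, mean, 0))]

  for (p in extra_predictors) {
    x <- as_level_chr(data[[p]])
    if (!is.numeric(data[[p]]) && any(x == MISSING_LEVEL, na.rm = TRUE)) {
      abort(sprintf("Predictor '%s' must be fully observed.", p),
            class = "svystab_schema_error")
    }
  }

  if (length(incomplete) == 0) {
    return(structure(list(
      datasets = replicate(config$m, data, simplify = FALSE),
      trace = tibble::tibble(stream = integer(), iteration = integer(),
                             variable = character(), level = character(),
                             prop = numeric()),
      variables = variables, config = config),
      class = "imputation_set"))
  }

  set.seed(seed_stream(config$seed, "mice-streams"))
  stream_seeds <- sample.int(2147483629, config$m)

  # working copy with Missing-free factors over observed levels
  predictors_of <- function(v) {
    setdiff(union(variables, extra_predictors), v)
  }

  datasets <- vector("list", config$m)
  trace <- list()
  for (s in seq_len(config$m)) {
    set.seed(stream_seeds[s])
    work <- data
    for (v in incomplete) {
      x <- as_level_chr(work[[v]])
      pool <- x[!masks[[v]]]
      x[masks[[v]]] <- sample(pool, sum(masks[[v]]), replace = TRUE)
      work[[v]] <- factor(x, levels = obs_levels[[v]])
    }
    for (it in seq_len(config$n_chain_iterations)) {
      for (v in incomplete) {
        miss <- masks[[v]]
        rhs <- predictors_of(v)
        form <- reformulate(rhs, response = v)
        fit <- nnet::multinom(form, data = work[!miss, , drop = FALSE],
                              decay = config$ridge, trace = FALSE,
                              maxit = 200, MaxNWts = 5000)
        probs <- predict(fit, newdata = work[miss, , drop = FALSE],
                         type = "probs")
        levs <- obs_levels[[v]]
        if (length(levs) == 2) {
          # binary: predict() returns P(second level)
          probs <- cbind(1 - probs, probs)
        }
        probs <- matrix(probs, nrow = sum(miss), ncol = length(levs))
        draw <- apply(probs, 1, function(p) sample(levs, 1, prob = pmax(p, 0)))
        x <- as_level_chr(work[[v]])
        x[miss] <- draw
        work[[v]] <- factor(x, levels = levs)
        trace[[length(trace) + 1]] <- tibble::tibble(
          stream = s, iteration = it, variable = v, level = levs,
          prop = as.numeric(table(factor(draw, levels = levs))) / sum(miss))
      }
    }
    datasets[[s]] <- work
  }

  structure(list(datasets = datasets, trace = dplyr::bind_rows(trace),
                 variables = variables, config = config),
            class = "imputation_set")
}

#' Convergence diagnostics for a chained-equation run
#'
#' Summarises, per imputed variable, the trajectory of imputed-category
#' frequencies across chain iterations: the across-stream mean trajectory
#' and the between-stream spread.  A variable is flagged when its mean
#' between-stream spread over the last third of iterations exceeds 1.5
#' times its spread over the first two-thirds (growing spread indicates a
#' non-mixing, diverging chain).
#'
#' @param set An `imputation_set` from [impute_chained()].
#' @return A tibble with one row per variable: `variable`,
#'   `spread_early`, `spread_late`, `flagged`; empty when nothing was
#'   imputed.
#' @export
convergence_diagnostics <- function(set) {
  stopifnot(inherits(set, "imputation_set"))
  tr <- set$trace
  if (nrow(tr) == 0) {
    return(tibble::tibble(variable = character(), spread_early = numeric(),
                          spread_late = numeric(), flagged = logical()))
  }
  n_it <- max(tr$iteration)
  cut <- ceiling(2 * n_it / 3)
  tr |>
    dplyr::group_by(.data$variable, .data$iteration, .data$level) |>
    dplyr::summarise(spread = sd(.data$prop), .groups = "drop") |>
    dplyr::group_by(.data$variable) |>
    dplyr::summarise(
      spread_early = mean(.data$spread[.data$iteration <= cut], na.rm = TRUE),
      spread_late = mean(.data$spread[.data$iteration > cut], na.rm = TRUE),
      .groups = "drop") |>
    dplyr::mutate(flagged = is.finite(.data$spread_late) &
                    .data$spread_late > 1.5 * pmax(.data$spread_early, 1e-12))
}
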