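#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a design-weighted logistic fit
#'
#' @param x A `svyfit` from [fit_survey_logistic()].
#' @param conf_level Confidence level for the t interval at the design df.
#' @param exponentiate Report odds ratios instead of log-odds.
#' @param ... Unused.
#' @return A tibble: `term`, `estimate`, `std_error`, `statistic`,
#'   `p_value`, `conf_low`, `conf_high`.
#' @export
tidy.svyfit <- function(x, conf_level = 0.95, exponentiate = FALSE, ...) {
  beta <- coef(x)
  se <- sqrt(diag(x$vcov))
  stat <- beta / se
  dfd <- max(x$df_design, 1)
  tq <- qt(1 - (1 - conf_level) / 2, df = dfd)
  out <- tibble::tibble(
    term = names(beta), estimate = unname(beta), std_error = unname(se),
    statistic = unname(stat),
    p_value = 2 * stats::pt(abs(stat), df = dfd, lower.tail = FALSE),
    conf_low = unname(beta - tq * se), conf_high = unname(beta + tq * se)
  )
  if (exponentiate) {
    out <- dplyr::mutate(out, dplyr::across(
      c("estimate", "conf_low", "conf_high"), exp))
  }
  out
}

#' @rdname tidy.svyfit
#' @export
glance.svyfit <- function(x, ...) {
  tibble::tibble(n = x$n, df_design = x$df_design,
                 converged = x$converged,
                 gvif_flagged = !is.null(x$gvif) && any(x$gvif$flagged))
}

#' Tidy a stability-selection report
#'
#' @param x A `stability_report` from [stability_select()].
#' @param ... Unused.
#' @return The frequency tibble with the endpoint attached as a column.
#' @export
tidy.stability_report <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::mutate(endpoint = attr(x, "endpoint"), .before = 1)
}

#' @rdname tidy.stability_report
#' @export
glance.stability_report <- function(x, ...) {
  cfg <- attr(x, "config")
  tibble::tibble(endpoint = attr(x, "endpoint"),
                 n_iterations = cfg$n_iterations,
                 subsample_fraction = cfg$subsample_fraction,
                 selection_threshold = cfg$selection_threshold,
                 n_selected = sum(x$selected))
}

#' Tidy a pooled effect
#'
#' @param x A `pooled_effect` from [pool_rubin()].
#' @param ... Unused.
#' @return A one-row tibble on the odds-ratio scale.
#' @export
tidy.pooled_effect <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::select("disability", "model", "or", "conf_low", "conf_high",
                  "n_mean", "m")
}

#' @rdname tidy.pooled_effect
#' @export
glance.pooled_effect <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::select("m", "q_bar", "W", "B", "T", "df")
}

#' Tidy / summarise a full pipeline run
#'
#' @param x An `svystab_analysis` from [run_analysis()].
#' @param ... Unused.
#' @return `tidy()`: the pooled results table. `glance()`: one row with
#'   counts of analyzed and failed disabilities and any collinearity flags.
#' @export
tidy.svystab_analysis <- function(x, ...) x$results

#' @rdname tidy.svystab_analysis
#' @export
glance.svystab_analysis <- function(x, ...) {
  tibble::tibble(
    n_disabilities = length(x$confounders),
    n_failed = length(x$errors),
    any_gvif_flagged = nrow(x$gvif_flags) > 0 && any(x$gvif_flags$flagged),
    profile = x$profile$profile
  )
}
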