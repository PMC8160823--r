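#' Combine multiply-imputed estimates by Rubin's rules
#'
#' Pools `m` per-imputation log-odds estimates: the pooled point estimate is
#' the mean `q_bar`; within-imputation variance `W` is the mean of the
#' squared standard errors; between-imputation variance `B` is the sample
#' variance of the estimates; total variance `T = W + (1 + 1/m) B`.
#' Degrees of freedom follow the Barnard-Rubin small-sample adjustment,
#' which is bounded above by the complete-data (design) degrees of freedom.
#' The odds ratio and its confidence interval are obtained by
#' exponentiating the pooled log-odds and its t interval.
#'
#' @param estimates Numeric vector of `m` log-odds estimates.
#' @param variances Numeric vector of `m` squared standard errors.
#' @param df_complete Complete-data degrees of freedom (the design df from
#'   [fit_survey_logistic()]).
#' @param conf_level Confidence level.
#' @param disability,model Optional labels stored on the result.
#' @param n_mean Mean analyzed records across imputations (label only).
#' @return A `pooled_effect`: one-row tibble with `q_bar`, `W`, `B`, `T`,
#'   `df`, `or`, `conf_low`, `conf_high` (plus any labels).
#' @export
pool_rubin <- function(estimates, variances, df_complete = Inf,
                       conf_level = 0.95, disability = NA_character_,
                       model = NA_character_, n_mean = NA_real_) {
  if (length(estimates) != length(variances)) {
    abort("estimates and variances must have the same length.",
          class = "svystab_config_error")
  }
  m <- length(estimates)
  if (m < 1) abort("Need at least one estimate.", class = "svystab_config_error")
  q_bar <- mean(estimates)
  W <- mean(variances)
  if (m == 1) {
    warn("Single imputation: between-imputation variance is unavailable.")
    B <- 0
  } else {
    B <- var(estimates)
  }
  T_total <- W + (1 + 1 / m) * B
  df <- barnard_rubin_df(m, B, T_total, df_complete)
  tq <- qt(1 - (1 - conf_level) / 2, df = df)
  out <- tibble::tibble(
    disability = disability, model = model, n_mean = n_mean, m = m,
    q_bar = q_bar, W = W, B = B, T = T_total, df = df,
    or = exp(q_bar),
    conf_low = exp(q_bar - tq * sqrt(T_total)),
    conf_high = exp(q_bar + tq * sqrt(T_total))
  )
  structure(out, class = c("pooled_effect", class(out)))
}

# Barnard-Rubin adjusted degrees of freedom; equals df_complete when B = 0
barnard_rubin_df <- function(m, B, T_total, df_complete) {
  if (!is.finite(df_complete)) df_complete <- 1e8
  lambda <- (1 + 1 / m) * B / T_total
  if (m < 2 || lambda < .Machine$double.eps) {
    return(df_complete)
  }
  df_old <- (m - 1) / lambda^2
  df_obs <- (df_complete + 1) / (df_complete + 3) * df_complete * (1 - lambda)
  df_old * df_obs / (df_old + df_obs)
}
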