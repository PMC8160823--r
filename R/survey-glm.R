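#' Design-weighted logistic regression with linearized variance
#'
#' Solves the weighted score equations
#' `sum_i w_i x_i (y_i - p_i(beta)) = 0` by iteratively reweighted least
#' squares, then estimates the coefficient covariance by Taylor-series
#' linearization: bread = inverse weighted information; meat = the
#' between-PSU covariance of stratum-centered PSU totals of the score
#' residuals, with the with-replacement stratum factor `n_h / (n_h - 1)`.
#' Strata reduced to a single PSU (possible after subgroup construction)
#' are handled by centering the lonely PSU total at the grand mean of all
#' PSU totals, with a warning.  Design degrees of freedom are
#' `(#PSUs) - (#strata)`.  Generalized variance-inflation factors of each
#' model term are computed on the weighted predictor correlation matrix
#' and `GVIF^(1/(2 df))` is flagged above 1.4.
#'
#' @param data Completed respondent tibble (no `"Missing"` categories among
#'   the model variables).
#' @param formula Model formula, e.g. `ecig_use ~ exposure_flag + age + ...`.
#' @param weight,stratum,psu Names of the design columns.
#' @param gvif_threshold Collinearity flag threshold on `GVIF^(1/(2 df))`.
#' @param max_iter IRLS iteration cap.
#' @return A `svyfit`: coefficients, design-based `vcov`, `n`, `df_design`,
#'   `gvif` table, convergence flag.  Methods: [tidy()], [glance()],
#'   `print()`, `confint()`.
#' @export
fit_survey_logistic <- function(data, formula, weight = "weight",
                                stratum = "stratum", psu = "psu",
                                gvif_threshold = 1.4, max_iter = 100) {
  check_columns(data, c(weight, stratum, psu), "fit_survey_logistic")
  w <- data[[weight]]
  if (any(w <= 0)) {
    abort("Analysis weights must be strictly positive.",
          class = "svystab_schema_error")
  }
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  if (!all(y %in% c(0, 1))) {
    abort("Outcome must be binary 0/1 and complete.",
          class = "svystab_schema_error")
  }
  # Both the point estimate and the linearized variance are invariant to
  # rescaling the weights, so normalize to mean 1 for IRLS stability.
  w <- w / mean(w)
  # weights are evaluated inside `data`, so pass them as a column
  data$.svyw <- w
  fit <- suppressWarnings(
    glm(formula, family = quasibinomial(), data = data, weights = .svyw,
        control = list(maxit = max_iter, epsilon = 1e-12))
  )
  if (!fit$converged) {
    abort("Weighted IRLS did not converge.", class = "svystab_fit_error")
  }
  beta <- coef(fit)
  if (any(is.na(beta))) {
    abort(sprintf("Aliased term(s) in the model: %s",
                  paste(names(beta)[is.na(beta)], collapse = ", ")),
          class = "svystab_fit_error")
  }
  if (any(abs(beta) > 15)) {
    abort(sprintf("Probable separation; offending term(s): %s",
                  paste(names(beta)[abs(beta) > 15], collapse = ", ")),
          class = "svystab_fit_error")
  }
  x <- model.matrix(fit)
  mu <- fit$fitted.values
  # score residual contributions u_i = w_i (y_i - mu_i) x_i
  u <- x * (w * (y - mu))
  info <- crossprod(x, x * (w * mu * (1 - mu)))
  bread <- solve(info)
  meat <- linearized_meat(u, data[[stratum]], data[[psu]])
  vc <- bread %*% meat$meat %*% bread
  vc <- (vc + t(vc)) / 2
  dimnames(vc) <- list(names(beta), names(beta))

  gvif <- tryCatch(
    compute_gvif(x, term_grouping = attr(x, "assign"),
                 terms_labels = attr(terms(fit), "term.labels"),
                 weights = w, threshold = gvif_threshold),
    error = function(e) NULL
  )

  structure(list(coefficients = beta, vcov = vc, n = nrow(x),
                 df_design = meat$df_design, gvif = gvif,
                 formula = formula, converged = fit$converged,
                 lonely_psu = meat$lonely, glm_fit = fit),
            class = "svyfit")
}

# stratum/PSU sandwich meat from per-record score contributions
linearized_meat <- function(u, stratum, psu) {
  k <- ncol(u)
  meat <- matrix(0, k, k)
  psu_key <- paste(stratum, psu, sep = "\r")
  z <- rowsum(u, psu_key, reorder = FALSE)
  z_stratum <- stratum[match(rownames(z), psu_key)]
  grand <- colMeans(z)
  lonely <- FALSE
  for (h in unique(z_stratum)) {
    zh <- z[z_stratum == h, , drop = FALSE]
    nh <- nrow(zh)
    if (nh == 1) {
      dev <- zh[1, ] - grand
      meat <- meat + tcrossprod(dev)
      lonely <- TRUE
    } else {
      ctr <- sweep(zh, 2, colMeans(zh))
      meat <- meat + (nh / (nh - 1)) * crossprod(ctr)
    }
  }
  if (lonely) {
    warn("Stratum with a single PSU: lonely-PSU totals centered at the grand mean.")
  }
  list(meat = meat, df_design = nrow(z) - length(unique(z_stratum)),
       lonely = lonely)
}

#' Generalized variance-inflation factors
#'
#' For each model term (group of design-matrix columns), the GVIF is the
#' determinant ratio `det(R_term) det(R_others) / det(R)` over the
#' (optionally weighted) correlation matrix of the predictors, intercept
#' excluded.  `GVIF^(1/(2 df))`, with `df` the term's column count, is
#' comparable across dimensions and flagged above the threshold.
#'
#' @param x Design matrix (with or without an intercept column).
#' @param term_grouping Integer vector mapping columns to terms (the
#'   `assign` attribute of a model matrix; 0 marks the intercept).
#' @param terms_labels Optional term labels.
#' @param weights Optional observation weights for the correlation matrix.
#' @param threshold Flag threshold on `GVIF^(1/(2 df))`.
#' @return A tibble: `term`, `gvif`, `df`, `gvif_adj`, `flagged`.
#' @export
compute_gvif <- function(x, term_grouping = NULL, terms_labels = NULL,
                         weights = NULL, threshold = 1.4) {
  term_grouping <- term_grouping %||% attr(x, "assign") %||%
    seq_len(ncol(x))
  keep <- term_grouping != 0
  xp <- x[, keep, drop = FALSE]
  grp <- term_grouping[keep]
  if (ncol(xp) < 2 || length(unique(grp)) < 2) {
    # a single term cannot be collinear with others
    ids <- unique(grp)
    return(tibble::tibble(
      term = terms_labels[ids] %||% as.character(ids),
      gvif = rep(1, length(ids)),
      df = as.integer(table(factor(grp, levels = ids))),
      gvif_adj = rep(1, length(ids)),
      flagged = rep(FALSE, length(ids))))
  }
  R <- if (is.null(weights)) {
    cor(xp)
  } else {
    cov.wt(xp, wt = weights / sum(weights), cor = TRUE)$cor
  }
  det_all <- det(R)
  if (!is.finite(det_all) || det_all < .Machine$double.eps^0.9) {
    abort("Singular predictor correlation matrix (aliased columns).",
          class = "svystab_fit_error")
  }
  ids <- unique(grp)
  rows <- purrr::map(ids, function(id) {
    sel <- grp == id
    gvif <- det(R[sel, sel, drop = FALSE]) *
      det(R[!sel, !sel, drop = FALSE]) / det_all
    df <- sum(sel)
    tibble::tibble(
      term = terms_labels[id] %||% as.character(id),
      gvif = gvif, df = df, gvif_adj = gvif^(1 / (2 * df)))
  })
  dplyr::bind_rows(rows) |>
    dplyr::mutate(flagged = .data$gvif_adj > threshold)
}

#' Design-weighted prevalence with a linearized confidence interval
#'
#' The ratio estimator `sum(w * 1[x = level]) / sum(w)` with a design-based
#' standard error from Taylor linearization of the ratio over strata and
#' PSUs (same stratum-centered PSU-total machinery as the regression
#' variance), and a Wald 95% interval truncated to `[0, 1]`.
#'
#' @param data Respondent tibble.
#' @param variable Binary or categorical column.
#' @param level Level whose prevalence is estimated (default: each level).
#' @param weight,stratum,psu Design column names.
#' @param conf_level Confidence level.
#' @return A tibble: `variable`, `level`, `estimate`, `se`, `conf_low`,
#'   `conf_high`.
#' @export
weighted_prevalence <- function(data, variable, level = NULL,
                                weight = "weight", stratum = "stratum",
                                psu = "psu", conf_level = 0.95) {
  check_columns(data, c(variable, weight, stratum, psu),
                "weighted_prevalence")
  w <- data[[weight]]
  if (sum(w) <= 0) {
    abort("Total weight must be positive.", class = "svystab_schema_error")
  }
  x <- data[[variable]]
  levs <- level %||% (if (is.numeric(x)) sort(unique(x)) else
    setdiff(unique(as_level_chr(x)), NA))
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  rows <- purrr::map(levs, function(lv) {
    ind <- if (is.numeric(x)) as.numeric(x == lv) else
      as.numeric(as_level_chr(x) == lv)
    est <- sum(w * ind) / sum(w)
    # linearized residuals of the ratio estimator
    z <- matrix(w * (ind - est) / sum(w), ncol = 1)
    v <- linearized_meat(z, data[[stratum]], data[[psu]])$meat[1, 1]
    se <- sqrt(v)
    tibble::tibble(variable = variable, level = as.character(lv),
                   estimate = est, se = se,
                   conf_low = max(0, est - zq * se),
                   conf_high = min(1, est + zq * se))
  })
  dplyr::bind_rows(rows)
}

#' @exportS3Method base::print
print.svyfit <- function(x, ...) {
  cat("Design-weighted logistic regression\n")
  cat(sprintf("  n = %d records, design df = %d\n", x$n, x$df_design))
  print(tidy.svyfit(x), n = Inf)
  if (!is.null(x$gvif) && any(x$gvif$flagged)) {
    cat("  Collinearity flag: GVIF^(1/(2df)) > threshold for",
        paste(x$gvif$term[x$gvif$flagged], collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
vcov.svyfit <- function(object, ...) object$vcov

#' @export
coef.svyfit <- function(object, ...) object$coefficients

#' @export
confint.svyfit <- function(object, parm = NULL, level = 0.95, ...) {
  beta <- coef(object)
  se <- sqrt(diag(object$vcov))
  tq <- qt(1 - (1 - level) / 2, df = max(object$df_design, 1))
  ci <- cbind(beta - tq * se, beta + tq * se)
  colnames(ci) <- c("low", "high")
  if (!is.null(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}
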