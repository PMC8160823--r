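#' One-hot design matrix with a coding map
#'
#' Expands candidate variables into a numeric matrix for penalized
#' regression.  Categorical variables are dummy-coded against a reference
#' level (the first observed non-`"Missing"` level); the explicit
#' `"Missing"` category always gets its own dummy column so that the
#' selection rule can ignore it.  Continuous variables enter as single
#' columns.  Zero-variance columns are dropped.
#'
#' @param data Respondent tibble.
#' @param vars Candidate variable names.
#' @return A list with `x` (matrix) and `map`, a tibble linking each column
#'   to its `(variable, level)`; `level` is `NA` for continuous variables.
#' @export
build_design_matrix <- function(data, vars) {
  check_columns(data, vars, "build_design_matrix")
  cols <- list()
  map <- list()
  for (v in vars) {
    col <- data[[v]]
    if (is.numeric(col)) {
      cols[[v]] <- as.numeric(col)
      map[[v]] <- tibble::tibble(column = v, variable = v, level = NA_character_)
    } else {
      x <- as_level_chr(col)
      levs <- if (is.factor(col)) {
        intersect(levels(col), unique(x))
      } else {
        unique(x)
      }
      ref <- setdiff(levs, MISSING_LEVEL)[1]
      if (is.na(ref)) next  # column is entirely Missing
      for (lv in setdiff(levs, ref)) {
        cn <- paste0(v, "=", lv)
        cols[[cn]] <- as.numeric(x == lv)
        map[[cn]] <- tibble::tibble(column = cn, variable = v, level = lv)
      }
    }
  }
  x <- do.call(cbind, cols)
  map <- dplyr::bind_rows(map)
  keep <- apply(x, 2, function(cc) stats::sd(cc) > 0)
  list(x = x[, keep, drop = FALSE], map = map[keep, , drop = FALSE])
}

#' L1-penalized logistic path
#'
#' Fits the lasso-penalized logistic regression path: for each penalty
#' `lambda`, the minimizer of `(1/n) binomial deviance + lambda * sum(|b_j|)`
#' with an unpenalized intercept and internally standardized columns.  At
#' and above the critical penalty `max_j |x_j'(y - ybar)| / n` (standardized
#' scale) every penalized coefficient is exactly zero.  A constant response
#' yields a degenerate all-zero path with a warning.
#'
#' @param x Numeric predictor matrix (e.g. from [build_design_matrix()]).
#' @param y Binary response (0/1).
#' @param lambda Optional decreasing penalty grid; by default 100
#'   log-spaced values from the critical penalty down by a factor 10^-4.
#' @param nlambda,lambda_min_ratio Grid size and ratio when `lambda` is NULL.
#' @return A `lasso_path`: list with `lambda` and `beta` (coefficients
#'   matrix, columns per lambda, excluding the intercept) plus `a0`.
#' @export
fit_lasso_path <- function(x, y, lambda = NULL, nlambda = 100,
                           lambda_min_ratio = 1e-4) {
  y <- as.numeric(y)
  if (length(unique(y)) < 2) {
    warn("Response is constant; returning an all-zero path.")
    lam <- lambda %||% 1
    beta <- matrix(0, ncol(x), length(lam),
                   dimnames = list(colnames(x), NULL))
    return(structure(list(lambda = lam, beta = beta,
                          a0 = rep(stats::qlogis(mean(c(y, 0.5))), length(lam)),
                          degenerate = TRUE),
                     class = "lasso_path"))
  }
  fit <- glmnet::glmnet(x, y, family = "binomial", standardize = TRUE,
                        lambda = lambda, nlambda = nlambda,
                        lambda.min.ratio = lambda_min_ratio)
  structure(list(lambda = fit$lambda, beta = as.matrix(fit$beta),
                 a0 = fit$a0, glmnet_fit = fit, degenerate = FALSE),
            class = "lasso_path")
}

# stratified fold assignment: every fold sees both classes
stratified_folds <- function(y, nfolds) {
  foldid <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    foldid[idx] <- sample(rep_len(seq_len(nfolds), length(idx)))
  }
  foldid
}

#' Cross-validated penalty selection
#'
#' Ten-fold (by default) cross-validation of the penalized logistic path,
#' with folds stratified on the response; returns the penalty minimizing
#' mean held-out binomial deviance (ties resolved toward the larger,
#' sparser penalty).  Deterministic given `seed`.
#'
#' @param x,y As in [fit_lasso_path()].
#' @param nfolds Number of CV folds.
#' @param seed Integer seed for the fold assignment.
#' @param lambda_min_ratio Lower end of the penalty grid relative to the
#'   critical penalty.
#' @return A `cv_result`: list with `lambda` (grid), `cvm` (mean CV binomial
#'   deviance), `lambda_min`, and `coef_min` (named coefficient vector at
#'   `lambda_min`, intercept excluded).
#' @export
select_lambda_min <- function(x, y, nfolds = 10, seed = 1,
                              lambda_min_ratio = 1e-4) {
  y <- as.numeric(y)
  if (length(unique(y)) < 2) {
    abort("Response has a single class; cannot cross-validate.",
          class = "svystab_degenerate_error")
  }
  set.seed(as.integer(seed))
  foldid <- stratified_folds(y, nfolds)
  fit <- glmnet::cv.glmnet(x, y, family = "binomial", foldid = foldid,
                           type.measure = "deviance",
                           lambda.min.ratio = lambda_min_ratio)
  coef_min <- as.matrix(coef(fit, s = "lambda.min"))[, 1]
  structure(list(lambda = fit$lambda, cvm = fit$cvm, cvsd = fit$cvsd,
                 lambda_min = fit$lambda.min,
                 coef_min = coef_min[setdiff(names(coef_min), "(Intercept)")]),
            class = "cv_result")
}

#' Map nonzero dummy coefficients back to selected variables
#'
#' A variable is selected iff at least one of its NON-missing-level dummy
#' columns has a nonzero coefficient; a variable whose only nonzero dummy
#' is its `"Missing"` category is not selected.  Continuous variables are
#' selected iff their single coefficient is nonzero.
#'
#' @param coefs Named coefficient vector (intercept excluded).
#' @param map Coding map from [build_design_matrix()].
#' @return A tibble with `variable` and logical `selected`.
#' @export
variable_selected_at <- function(coefs, map) {
  unmapped <- setdiff(names(coefs), map$column)
  if (length(unmapped) > 0) {
    abort(sprintf("Coefficient column(s) not in coding map: %s",
                  paste(unmapped, collapse = ", ")),
          class = "svystab_schema_error")
  }
  map |>
    dplyr::mutate(coef = unname(coefs[.data$column])) |>
    dplyr::group_by(.data$variable) |>
    dplyr::summarise(selected = any(
      .data$coef != 0 & (is.na(.data$level) | .data$level != MISSING_LEVEL)
    ), .groups = "drop")
}
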