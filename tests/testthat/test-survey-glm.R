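srs_fixture <- function(n = 200, seed = 42) {
  set.seed(seed)
  df <- tibble::tibble(
    x1 = rnorm(n),
    x2 = factor(sample(c("a", "b", "c"), n, TRUE))
  )
  df$y <- rbinom(n, 1, plogis(-0.4 + 0.7 * df$x1 + 0.5 * (df$x2 == "b")))
  add_srs_design(df)
}

test_that("SRS limit: coefficients match ML and vcov matches the record-level sandwich", {
  df <- srs_fixture()
  fit <- fit_survey_logistic(df, y ~ x1 + x2)
  ml <- glm(y ~ x1 + x2, family = binomial(), data = df,
            control = list(epsilon = 1e-12))
  expect_equal(coef(fit), coef(ml), tolerance = 1e-8)
  # independent oracle: record-level sandwich evaluated at the ML fit --
  # expected-information bread, sandwich::estfun meat, and the
  # with-replacement factor n/(n-1) of singleton-PSU linearization
  n <- nrow(df)
  X <- model.matrix(ml)
  mu <- ml$fitted.values
  bread <- solve(crossprod(X, X * (mu * (1 - mu))))
  scores <- X * (df$y - mu)
  meat <- crossprod(scores) * n / (n - 1)
  oracle <- bread %*% meat %*% bread
  expect_equal(unname(fit$vcov), unname(oracle), tolerance = 1e-8)
  # cross-package check (looser: vcovHC carries glm working-weight lag)
  hc0 <- sandwich::vcovHC(ml, type = "HC0") * n / (n - 1)
  expect_equal(unname(fit$vcov), unname(hc0), tolerance = 1e-4)
  expect_equal(fit$df_design, n - 1)
})

test_that("saturated weighted 2x2 model returns the closed-form weighted OR", {
  df <- make_weighted_2x2(20, 80, 10, 90)
  fit <- fit_survey_logistic(df, y ~ x)
  expect_equal(exp(coef(fit)[["x"]]), (20 * 90) / (80 * 10), tolerance = 1e-8)
  expect_equal(exp(coef(fit)[["x"]]), 2.25, tolerance = 1e-8)
})

test_that("crude weighted OR implied by published-style column percentages", {
  # weighted percentages of any-disability among current users (20.8 vs 78.4)
  # and never users (11.5 vs 88.0) per 100 weighted respondents
  df <- make_weighted_2x2(20.8, 78.4, 11.5, 88.0)
  fit <- fit_survey_logistic(df, y ~ x)
  closed_form <- (20.8 / 78.4) / (11.5 / 88.0)
  expect_equal(exp(coef(fit)[["x"]]), closed_form, tolerance = 1e-8)
  expect_equal(closed_form, 2.03, tolerance = 0.005)
})

test_that("estimates and linearized variances are invariant to weight scaling", {
  set.seed(8)
  df <- srs_fixture(150, seed = 9)
  df$weight <- runif(150, 0.5, 4)
  df$stratum <- sample(c("S1", "S2", "S3"), 150, TRUE)
  df$psu <- paste0(df$stratum, "_", sample(1:4, 150, TRUE))
  f1 <- fit_survey_logistic(df, y ~ x1 + x2)
  df2 <- df; df2$weight <- df$weight * 1000
  f2 <- fit_survey_logistic(df2, y ~ x1 + x2)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-10)
  expect_equal(f1$vcov, f2$vcov, tolerance = 1e-10)

  prev1 <- weighted_prevalence(df, "y", level = 1)
  prev2 <- weighted_prevalence(df2, "y", level = 1)
  expect_equal(prev1$estimate, prev2$estimate, tolerance = 1e-12)
  expect_equal(prev1$se, prev2$se, tolerance = 1e-12)
})

test_that("linearized variance agrees with the jackknife-by-PSU oracle on a clustered fixture", {
  set.seed(33)
  n <- 600
  df <- tibble::tibble(
    stratum = rep(c("S1", "S2", "S3"), each = n / 3),
    psu = paste0(rep(c("S1", "S2", "S3"), each = n / 3), "_",
                 rep(rep(1:4, each = n / 12), 3)),
    weight = runif(n, 1, 3),
    x = rnorm(n)
  )
  # mild PSU-level random effect so clustering matters
  re <- rnorm(12, 0, 0.3)
  df$y <- rbinom(n, 1, plogis(-0.2 + 0.6 * df$x + re[as.integer(factor(df$psu))]))
  fit <- fit_survey_logistic(df, y ~ x)
  v_lin <- fit$vcov["x", "x"]
  v_jack <- jackknife_psu_var(df, y ~ x, "x")
  expect_lt(abs(v_lin - v_jack) / v_jack, 0.15)
  expect_equal(fit$df_design, 12 - 3)
})

test_that("lonely PSU strata warn and separation errors name the term", {
  df <- srs_fixture(80, seed = 2)
  df$stratum <- c("S1", rep("S2", 79))
  df$psu <- c("P1", paste0("P", rep(2:9, length.out = 79)))
  expect_warning(fit_survey_logistic(df, y ~ x1), "single PSU")

  sep <- add_srs_design(tibble::tibble(x = c(rep(0, 20), rep(1, 20)),
                                       y = c(rep(0, 20), rep(1, 20))))
  expect_error(fit_survey_logistic(sep, y ~ x), class = "svystab_fit_error")
})

test_that("GVIF closed forms: orthogonal design, r = 0.8 pair, recoding invariance", {
  # exactly orthogonal predictors -> every GVIF = 1
  n <- 64
  x1 <- rep(c(-1, 1), n / 2)
  x2 <- rep(c(-1, -1, 1, 1), n / 4)
  x3 <- rnorm(n)
  x3 <- lm(x3 ~ x1 + x2)$residuals  # orthogonalize
  X <- cbind(x1 = x1, x2 = x2, x3 = x3)
  g <- compute_gvif(X, term_grouping = c(1, 2, 3),
                    terms_labels = colnames(X))
  expect_equal(g$gvif, rep(1, 3), tolerance = 1e-8)
  expect_false(any(g$flagged))

  # two predictors with sample correlation exactly 0.8
  set.seed(1)
  a <- scale(rnorm(100))[, 1]
  e <- scale(lm(rnorm(100) ~ a)$residuals)[, 1]  # unit sd, orthogonal to a
  b <- 0.8 * a + sqrt(1 - 0.64) * e              # sample cor(a, b) = 0.8 exactly
  g2 <- compute_gvif(cbind(p = a, q = b), term_grouping = c(1, 2),
                     terms_labels = c("p", "q"))
  expect_equal(g2$gvif[1], 1 / (1 - 0.8^2), tolerance = 1e-3)
  expect_equal(g2$gvif[1], 2.778, tolerance = 1e-3)
  expect_true(all(g2$flagged))  # GVIF^(1/2) ~ 1.667 > 1.4

  # cross-check against the standard GVIF implementation on a fitted model
  set.seed(3)
  df <- data.frame(y = rnorm(120), u = rnorm(120),
                   f = factor(sample(c("a", "b", "c"), 120, TRUE)))
  df$v <- df$u * 0.6 + rnorm(120)
  lmfit <- lm(y ~ u + v + f, data = df)
  mine <- compute_gvif(model.matrix(lmfit),
                       terms_labels = attr(terms(lmfit), "term.labels"))
  theirs <- car::vif(lmfit)
  theirs_gvif <- if (is.matrix(theirs)) theirs[, "GVIF"] else theirs
  expect_equal(unname(mine$gvif), unname(theirs_gvif[mine$term]),
               tolerance = 1e-8)

  # determinant-ratio property: GVIF of a term is invariant to invertible
  # recoding of the other terms' columns
  set.seed(4)
  A <- matrix(rnorm(200 * 2), 200, 2)
  B <- matrix(rnorm(200 * 3), 200, 3) + A[, 1] * 0.3
  M <- matrix(c(2, 0.5, 0, 1, 1, 0, 0.3, 0, 1), 3, 3)  # invertible
  g_orig <- compute_gvif(cbind(A, B), term_grouping = c(1, 1, 2, 2, 2))
  g_rec <- compute_gvif(cbind(A, B %*% M), term_grouping = c(1, 1, 2, 2, 2))
  expect_equal(g_orig$gvif[1], g_rec$gvif[1], tolerance = 1e-8)

  # aliased columns are a singular-correlation error
  expect_error(compute_gvif(cbind(a = x1, b = x1, c = x3),
                            term_grouping = c(1, 2, 3)),
               class = "svystab_fit_error")
})

test_that("weighted prevalence: hand summation and the SRS closed form", {
  df <- tibble::tibble(x = c(1, 0, 1), weight = c(1, 2, 3),
                       stratum = "S1", psu = c("P1", "P2", "P3"))
  wp <- weighted_prevalence(df, "x", level = 1)
  expect_equal(wp$estimate, 4 / 6, tolerance = 1e-12)

  set.seed(12)
  n <- 500
  df2 <- add_srs_design(tibble::tibble(x = rbinom(n, 1, 0.3)))
  wp2 <- weighted_prevalence(df2, "x", level = 1)
  p <- mean(df2$x)
  expect_equal(wp2$estimate, p, tolerance = 1e-12)
  expect_equal(wp2$se, sqrt(p * (1 - p) / (n - 1)), tolerance = 1e-10)
  expect_true(wp2$conf_low >= 0 && wp2$conf_high <= 1)

  df0 <- df; df0$weight <- c(0, 0, 0)
  expect_error(weighted_prevalence(df0, "x"), class = "svystab_schema_error")
})

test_that("tidy and glance methods expose the fit in broom shape", {
  df <- srs_fixture(150, seed = 77)
  fit <- fit_survey_logistic(df, y ~ x1 + x2)
  td <- tidy(fit)
  expect_setequal(names(td), c("term", "estimate", "std_error", "statistic",
                               "p_value", "conf_low", "conf_high"))
  expect_equal(nrow(td), 4)
  td_or <- tidy(fit, exponentiate = TRUE)
  expect_equal(td_or$estimate, exp(td$estimate))
  gl <- glance(fit)
  expect_equal(gl$n, 150)
  expect_true(gl$converged)
})
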