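# MCAR fixture: binary covariate with known truth, unrelated predictor
mcar_fixture <- function(n = 2000, p_yes = 0.3, p_miss = 0.2, seed = 31) {
  set.seed(seed)
  truth <- sample(c("no", "yes"), n, TRUE, prob = c(1 - p_yes, p_yes))
  obs <- truth
  miss <- runif(n) < p_miss
  obs[miss] <- "Missing"
  tibble::tibble(
    x = factor(obs, levels = c("no", "yes", "Missing")),
    z = factor(sample(c("u", "v"), n, TRUE)),
    y = rbinom(n, 1, 0.4)
  )
}

test_that("complete data yield m identical copies of the input", {
  df <- tibble::tibble(
    a = factor(sample(c("p", "q"), 50, TRUE)),
    y = rbinom(50, 1, 0.5)
  )
  set <- impute_chained(df, variables = "a", extra_predictors = "y",
                        config = imputation_config(m = 3, n_chain_iterations = 2,
                                                   seed = 1))
  expect_length(set$datasets, 3)
  for (d in set$datasets) expect_identical(d, df)
  expect_equal(nrow(set$trace), 0L)
  expect_equal(nrow(convergence_diagnostics(set)), 0L)
})

test_that("MCAR binary imputation recovers the marginal within Monte-Carlo error", {
  df <- mcar_fixture()
  cfg <- imputation_config(m = 5, n_chain_iterations = 5, seed = 7)
  set <- impute_chained(df, variables = c("x", "z"),
                        extra_predictors = "y", config = cfg)
  miss <- df$x == "Missing"
  p_obs <- mean(df$x[!miss] == "yes")
  imp_freq <- mean(vapply(set$datasets,
                          function(d) mean(d$x[miss] == "yes"), 0))
  # observed-marginal sampling error plus imputation draw error, 3 SE
  tol <- 3 * (sqrt(p_obs * (1 - p_obs) / sum(!miss)) +
                sqrt(p_obs * (1 - p_obs) / (cfg$m * sum(miss))))
  expect_lt(abs(imp_freq - 0.3), tol)

  # observed cells are bit-identical across datasets and to the input
  for (d in set$datasets) {
    expect_identical(as.character(d$x[!miss]), as.character(df$x[!miss]))
    expect_identical(d$y, df$y)
  }
  # no Missing levels remain in imputed columns
  expect_false(any(vapply(set$datasets,
                          function(d) any(d$x == "Missing"), TRUE)))
})

test_that("imputation is reproducible given the seed and supports m = 1, one sweep", {
  df <- mcar_fixture(n = 300, seed = 5)
  cfg <- imputation_config(m = 2, n_chain_iterations = 2, seed = 11)
  s1 <- impute_chained(df, c("x"), extra_predictors = c("y"), config = cfg)
  s2 <- impute_chained(df, c("x"), extra_predictors = c("y"), config = cfg)
  expect_identical(s1$datasets, s2$datasets)
  expect_identical(s1$trace, s2$trace)

  # single stochastic regression imputation as the degenerate case
  s3 <- impute_chained(df, c("x"), extra_predictors = c("y"),
                       config = imputation_config(m = 1, n_chain_iterations = 1,
                                                  seed = 2))
  expect_length(s3$datasets, 1)
  expect_false(any(s3$datasets[[1]]$x == "Missing"))
})

test_that("MAR imputation matches per-stratum observed frequencies", {
  set.seed(17)
  n <- 3000
  z <- sample(c("lo", "hi"), n, TRUE)
  # 3-level covariate whose distribution depends on z
  x <- ifelse(z == "lo",
              sample(c("a", "b", "c"), n, TRUE, prob = c(0.6, 0.3, 0.1)),
              sample(c("a", "b", "c"), n, TRUE, prob = c(0.1, 0.3, 0.6)))
  miss <- runif(n) < ifelse(z == "lo", 0.25, 0.05)  # MAR driven by z
  xo <- ifelse(miss, "Missing", x)
  df <- tibble::tibble(x = factor(xo, levels = c("a", "b", "c", "Missing")),
                       z = factor(z), y = rbinom(n, 1, 0.3))
  set <- impute_chained(df, c("x", "z"), extra_predictors = "y",
                        config = imputation_config(m = 5, n_chain_iterations = 5,
                                                   seed = 23))
  for (zz in c("lo", "hi")) {
    sel_obs <- !miss & z == zz
    sel_imp <- miss & z == zz
    p_obs <- mean(x[sel_obs] == "a")
    p_imp <- mean(vapply(set$datasets,
                         function(d) mean(d$x[sel_imp] == "a"), 0))
    tol <- 3 * (sqrt(p_obs * (1 - p_obs) / sum(sel_obs)) +
                  sqrt(p_obs * (1 - p_obs) / (5 * sum(sel_imp))))
    expect_lt(abs(p_imp - p_obs), tol)
  }
})

test_that("diagnostics report flat traces for MCAR chains and errors are raised", {
  df <- mcar_fixture(n = 800, seed = 13)
  set <- impute_chained(df, c("x"), extra_predictors = "y",
                        config = imputation_config(m = 4, n_chain_iterations = 9,
                                                   seed = 3))
  diag <- convergence_diagnostics(set)
  expect_equal(nrow(diag), 1L)
  expect_false(diag$flagged)

  all_miss <- tibble::tibble(x = factor(rep("Missing", 20)), y = rbinom(20, 1, 0.5))
  expect_error(impute_chained(all_miss, "x", extra_predictors = "y"),
               class = "svystab_degenerate_error")
  part <- tibble::tibble(x = factor(c("a", "Missing", "b")),
                         w = factor(c("Missing", "u", "u")))
  expect_error(impute_chained(part, "x", extra_predictors = "w",
                              config = imputation_config(m = 1, n_chain_iterations = 1)),
               class = "svystab_schema_error")
})
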