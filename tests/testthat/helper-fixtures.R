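# Shared fixtures and independent oracles, all built in code at test time.

# A weighted 2x2 table as respondent records: cell totals W11 (x=1,y=1),
# W10 (x=1,y=0), W01, W00, split over two records per cell, each record its
# own PSU in a single stratum.
make_weighted_2x2 <- function(w11, w10, w01, w00) {
  cells <- data.frame(
    x = c(1, 1, 0, 0),
    y = c(1, 0, 1, 0),
    w = c(w11, w10, w01, w00)
  )
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    data.frame(x = rep(cells$x[i], 2), y = rep(cells$y[i], 2),
               weight = rep(cells$w[i] / 2, 2))
  }))
  out$stratum <- "S1"
  out$psu <- sprintf("P%02d", seq_len(nrow(out)))
  tibble::as_tibble(out)
}

# Independent-records SRS design columns (weight 1, one stratum, each
# record its own PSU).
add_srs_design <- function(data) {
  data$weight <- 1
  data$stratum <- "S1"
  data$psu <- sprintf("P%05d", seq_len(nrow(data)))
  data
}

# Mantel-Haenszel odds ratio from records: conditional-on-C oracle built by
# brute-force 2x2xK tabulation.
mh_odds_ratio <- function(d, e, strata) {
  num <- 0; den <- 0
  for (s in unique(strata)) {
    i <- strata == s
    a <- sum(d[i] == 1 & e[i] == 1); b <- sum(d[i] == 1 & e[i] == 0)
    c_ <- sum(d[i] == 0 & e[i] == 1); dd <- sum(d[i] == 0 & e[i] == 0)
    n <- sum(i)
    num <- num + a * dd / n
    den <- den + b * c_ / n
  }
  num / den
}

# Crude odds ratio by direct tabulation.
crude_odds_ratio <- function(d, e) {
  (sum(d == 1 & e == 1) * sum(d == 0 & e == 0)) /
    (sum(d == 1 & e == 0) * sum(d == 0 & e == 1))
}

# Minimal truth model: one binary confounder C affecting both the focal
# disability and the outcome, no missingness, no extra covariates beyond
# the forced demographics needed by the pipeline surface.
tiny_truth <- function(beta_d = 0, alpha_c = 1, beta_c = 1,
                       alpha0 = -1.2, beta0 = -1.5) {
  truth_model(
    covariates = list(cov_binary("c1", 0.4)),
    alpha0 = alpha0, alpha = list(c1 = c(yes = alpha_c)),
    beta0 = beta0, beta = list(c1 = c(yes = beta_c)),
    beta_d = beta_d,
    focal_disability = "cognitive",
    missingness = list()
  )
}

# Stratified jackknife-by-PSU variance oracle for the exposure coefficient
# of a weighted logistic fit: delete one PSU at a time, reweight its
# stratum-mates by n_h / (n_h - 1).
jackknife_psu_var <- function(data, formula, coef_name) {
  full <- fit_survey_logistic(data, formula)
  theta <- coef(full)[[coef_name]]
  keys <- unique(data[, c("stratum", "psu")])
  v <- 0
  for (h in unique(keys$stratum)) {
    psus <- keys$psu[keys$stratum == h]
    nh <- length(psus)
    for (p in psus) {
      dat <- data[!(data$stratum == h & data$psu == p), , drop = FALSE]
      dat$weight <- ifelse(dat$stratum == h,
                           dat$weight * nh / (nh - 1), dat$weight)
      fit <- fit_survey_logistic(dat, formula)
      v <- v + (nh - 1) / nh * (coef(fit)[[coef_name]] - theta)^2
    }
  }
  v
}

# glmnet-convention standardization (population sd) used by the KKT oracle.
lambda_max_kkt <- function(x, y) {
  n <- nrow(x)
  xs <- scale(x, center = TRUE,
              scale = apply(x, 2, function(c) sqrt(mean((c - mean(c))^2))))
  max(abs(crossprod(xs, y - mean(y)))) / n
}
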