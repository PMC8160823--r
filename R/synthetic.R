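#' Covariate specifications for the synthetic survey generator
#'
#' Describe one covariate of the synthetic population: a categorical
#' variable with named levels and marginal frequencies, a yes/no binary
#' variable, or a continuous variable.
#'
#' @param name Column name.
#' @param levels Character vector of category labels.
#' @param probs Marginal frequencies, same length as `levels`; must sum to 1.
#' @param prob_yes For `cov_binary()`, the marginal probability of `"yes"`.
#' @param dist For `cov_continuous()`, `"uniform"` or `"normal"`.
#' @param min,max Bounds of the uniform distribution.
#' @param mean,sd Moments of the normal distribution.
#'
#' @return A covariate spec (a classed list) consumed by [truth_model()].
#' @export
cov_categorical <- function(name, levels, probs) {
  if (length(levels) != length(probs) || any(probs < 0)) {
    abort("Invalid categorical spec: levels/probs mismatch or negative probability.",
          class = "svystab_config_error")
  }
  if (abs(sum(probs) - 1) > 1e-8) {
    abort(sprintf("Marginal distribution for '%s' must sum to 1 (got %g).",
                  name, sum(probs)),
          class = "svystab_config_error")
  }
  structure(list(name = name, type = "categorical",
                 levels = as.character(levels), probs = probs),
            class = "svystab_cov_spec")
}

#' @rdname cov_categorical
#' @export
cov_binary <- function(name, prob_yes) {
  cov_categorical(name, c("no", "yes"), c(1 - prob_yes, prob_yes))
}

#' @rdname cov_categorical
#' @export
cov_continuous <- function(name, dist = c("uniform", "normal"),
                           min = 0, max = 1, mean = 0, sd = 1) {
  dist <- match.arg(dist)
  if (dist == "uniform" && min >= max) {
    abort("Uniform spec needs min < max.", class = "svystab_config_error")
  }
  if (dist == "normal" && sd <= 0) {
    abort("Normal spec needs sd > 0.", class = "svystab_config_error")
  }
  structure(list(name = name, type = "continuous", dist = dist,
                 min = min, max = max, mean = mean, sd = sd),
            class = "svystab_cov_spec")
}

spec_mean <- function(spec) {
  if (spec$dist == "uniform") (spec$min + spec$max) / 2 else spec$mean
}

#' Missing-at-random rule for one covariate
#'
#' The probability that `variable` is recorded as the explicit `"Missing"`
#' category is a function of a fully observed categorical variable `by`:
#' rows whose `by` value appears in `names(probs)` use that probability,
#' all other rows use `default`.
#'
#' @param variable Covariate made incomplete (categorical only).
#' @param by Fully observed categorical driver of missingness.
#' @param probs Named numeric vector of missingness probabilities per
#'   `by`-level, each in `[0, 1)`.
#' @param default Probability for `by`-levels not named in `probs`.
#'
#' @return A MAR rule (classed list) for [truth_model()].
#' @export
mar_rule <- function(variable, by, probs, default = 0) {
  p <- c(probs, default)
  if (any(p < 0) || any(p >= 1)) {
    abort("Missingness probabilities must lie in [0, 1).",
          class = "svystab_config_error")
  }
  structure(list(variable = variable, by = by, probs = probs,
                 default = default),
            class = "svystab_mar_rule")
}

#' Ground-truth data-generating model for the synthetic survey
#'
#' Defines the joint law of the synthetic respondents: independent
#' covariates, a focal disability indicator drawn from
#' `logit P(D = 1) = alpha0 + alpha' C`, a current-e-cigarette outcome drawn
#' from `logit P(E = 1) = beta0 + beta_d * D + beta' C`, non-focal disability
#' types as independent background prevalences, and MAR missingness applied
#' to categorical covariates only (never to the exposure, outcome or design
#' columns).  Covariates with nonzero entries in both `alpha` and `beta` are
#' the true confounders; `exp(beta_d)` is the conditional odds ratio the
#' pipeline must recover.
#'
#' Effects are given per covariate: a single slope for continuous variables
#' (centered at the spec mean) or a named vector of log-odds offsets per
#' non-reference level for categorical variables (first level = reference).
#'
#' @param covariates List of covariate specs ([cov_categorical()] etc.).
#' @param alpha0,beta0 Intercepts (log-odds) of the disability and outcome
#'   models.
#' @param alpha,beta Named lists of effects on the disability and outcome.
#' @param beta_d Log-odds ratio of the focal disability on the outcome.
#' @param focal_disability Which of [disability_types()] the truth model
#'   drives; the others are independent noise.
#' @param other_disability_prev Named prevalences for the non-focal types.
#' @param missingness List of [mar_rule()]s.
#'
#' @return A `truth_model` object.
#' @seealso [generate_population()], [default_truth_model()]
#' @export
truth_model <- function(covariates,
                        alpha0 = -2.5, alpha = list(),
                        beta0 = -3.1, beta = list(),
                        beta_d = log(1.5),
                        focal_disability = "cognitive",
                        other_disability_prev = c(
                          vision = 0.021, hearing = 0.013, cognitive = 0.076,
                          mobility = 0.023, independent_living = 0.028,
                          self_care = 0.008),
                        missingness = list()) {
  stopifnot(focal_disability %in% disability_types())
  names(covariates) <- vapply(covariates, `[[`, "", "name")
  check_effects <- function(effects, what) {
    bad <- setdiff(names(effects), names(covariates))
    if (length(bad) > 0) {
      abort(sprintf("%s names a covariate not in the spec: %s",
                    what, paste(bad, collapse = ", ")),
            class = "svystab_config_error")
    }
  }
  check_effects(alpha, "alpha"); check_effects(beta, "beta")
  for (rule in missingness) {
    for (v in c(rule$variable, rule$by)) {
      if (!v %in% names(covariates)) {
        abort(sprintf("MAR rule references unknown covariate '%s'.", v),
              class = "svystab_config_error")
      }
    }
    if (covariates[[rule$variable]]$type != "categorical") {
      abort("MAR rules apply to categorical covariates only.",
            class = "svystab_config_error")
    }
  }
  nonzero <- function(effects) {
    names(effects)[vapply(effects, function(e) any(e != 0), TRUE)]
  }
  structure(list(
    covariates = covariates,
    alpha0 = alpha0, alpha = alpha,
    beta0 = beta0, beta = beta, beta_d = beta_d,
    focal_disability = focal_disability,
    other_disability_prev = other_disability_prev,
    missingness = missingness,
    confounder_names = intersect(nonzero(alpha), nonzero(beta))
  ), class = "truth_model")
}

#' True conditional odds ratio of the truth model
#'
#' @param truth A [truth_model()].
#' @return `exp(beta_d)`, the estimand the pipeline targets.
#' @export
truth_conditional_or <- function(truth) {
  stopifnot(inherits(truth, "truth_model"))
  exp(truth$beta_d)
}

#' Default synthetic truth: three strong confounders, seven noise covariates
#'
#' A ready-made [truth_model()] emulating survey microdata on young-adult
#' never-smokers: forced demographics (continuous age 18-34, gender,
#' race/ethnicity), three covariates that confound the disability-outcome
#' association (employment status, days of poor mental health, history of
#' depressive disorder; per-level effects of magnitude 0.7-1.3 on the
#' log-odds scale, i.e. odds ratios near 2-3.5, the order of the stronger
#' covariate contrasts seen in surveillance data), and seven null
#' covariates.  Background outcome prevalence is near
#' 4-5% and focal (cognitive) disability prevalence near 8%.  Two covariates
#' carry MAR missingness driven by gender (income heavily, mental-health
#' days lightly).
#'
#' @param beta_d Log-odds ratio of the focal disability on the outcome.
#' @param missingness Optional replacement list of [mar_rule()]s; the
#'   default makes income ~17% and mental-health days ~4% missing.
#' @return A `truth_model`.
#' @export
default_truth_model <- function(beta_d = log(1.5), missingness = NULL) {
  covs <- list(
    cov_continuous("age", "uniform", min = 18, max = 34),
    cov_categorical("gender", c("female", "male"), c(0.55, 0.45)),
    cov_categorical("race_ethnicity",
                    c("white_nh", "black_nh", "other_nh", "multi_nh", "hispanic"),
                    c(0.48, 0.14, 0.10, 0.02, 0.26)),
    # true confounders
    cov_categorical("employment", c("employed", "not_employed", "student"),
                    c(0.61, 0.16, 0.23)),
    cov_categorical("mental_health_days", c("0", "1-13", "14+"),
                    c(0.59, 0.30, 0.11)),
    cov_binary("depression", 0.12),
    # noise covariates
    cov_categorical("income", c("lt25k", "25-50k", "50k+"), c(0.29, 0.25, 0.46)),
    cov_categorical("marital", c("married", "never_married", "other"),
                    c(0.30, 0.60, 0.10)),
    cov_binary("veteran", 0.043),
    cov_binary("seatbelt_always", 0.83),
    cov_categorical("checkup", c("lt2y", "2-5y", "5y+"), c(0.78, 0.11, 0.11)),
    cov_binary("internet_use", 0.95),
    cov_binary("alcohol_30d", 0.48)
  )
  if (is.null(missingness)) {
    missingness <- list(
      mar_rule("income", by = "gender", probs = c(female = 0.20), default = 0.14),
      mar_rule("mental_health_days", by = "gender",
               probs = c(female = 0.05), default = 0.03)
    )
  }
  truth_model(
    covariates = covs,
    alpha0 = -3.0,
    alpha = list(
      employment = c(not_employed = 1.1, student = 0.3),
      mental_health_days = c("1-13" = 0.7, "14+" = 1.3),
      depression = c(yes = 1.1)
    ),
    beta0 = -3.6,
    beta = list(
      age = -0.06,
      gender = c(male = 0.6),
      employment = c(not_employed = -0.7, student = 0.9),
      mental_health_days = c("1-13" = 0.5, "14+" = 1.0),
      depression = c(yes = 0.9)
    ),
    beta_d = beta_d,
    focal_disability = "cognitive",
    missingness = missingness
  )
}

#' Stratified unequal-weight sampling design for the generator
#'
#' Records are allocated uniformly to `n_strata` strata, each holding
#' `psu_per_stratum` primary sampling units; analysis weights are drawn
#' lognormal with a stratum-specific location (so strata differ in average
#' weight, a disproportionate design) and are independent of the outcome
#' given stratum.  Survey-year labels are assigned by `year_fractions`.
#'
#' @param n_strata Number of design strata.
#' @param psu_per_stratum PSUs per stratum.
#' @param weight_meanlog Either a single lognormal meanlog or one per
#'   stratum; the default spreads mean weights about tenfold across strata.
#' @param weight_sdlog Lognormal sdlog of weights within stratum.
#' @param years Survey-year labels.
#' @param year_fractions Expected share of records per year; sums to 1.
#'
#' @return A `design_spec` object.
#' @export
design_spec <- function(n_strata = 8, psu_per_stratum = 6,
                        weight_meanlog = NULL, weight_sdlog = 0.5,
                        years = c("2016", "2017"),
                        year_fractions = c(0.5, 0.5)) {
  if (n_strata < 1 || psu_per_stratum < 1) {
    abort("n_strata and psu_per_stratum must be >= 1.",
          class = "svystab_config_error")
  }
  if (length(years) != length(year_fractions) ||
      abs(sum(year_fractions) - 1) > 1e-8) {
    abort("year_fractions must match years and sum to 1.",
          class = "svystab_config_error")
  }
  if (is.null(weight_meanlog)) {
    weight_meanlog <- seq(log(150), log(1500), length.out = n_strata)
  }
  if (length(weight_meanlog) == 1) {
    weight_meanlog <- rep(weight_meanlog, n_strata)
  }
  stopifnot(length(weight_meanlog) == n_strata, weight_sdlog >= 0)
  structure(list(n_strata = n_strata, psu_per_stratum = psu_per_stratum,
                 weight_meanlog = weight_meanlog, weight_sdlog = weight_sdlog,
                 years = years, year_fractions = year_fractions),
            class = "design_spec")
}

# accumulate the linear predictor contribution of one effect list
lp_from_effects <- function(data, effects, covariates) {
  lp <- rep(0, nrow(data))
  for (v in names(effects)) {
    ef <- effects[[v]]
    spec <- covariates[[v]]
    if (spec$type == "continuous") {
      lp <- lp + ef[[1]] * (data[[v]] - spec_mean(spec))
    } else {
      hit <- match(as_level_chr(data[[v]]), names(ef))
      lp <- lp + ifelse(is.na(hit), 0, ef[hit])
    }
  }
  lp
}

#' Generate a synthetic respondent table
#'
#' Draws `n` records from a [truth_model()] under a [design_spec()]:
#' design columns (`stratum`, `psu`, `weight`, `year`), covariates,
#' the six disability indicators, the binary outcome `ecig_use` with its
#' status label `ecig_status`, and inclusion-screen columns
#' (`cigarettes_lifetime` below the never-smoker threshold for eligible
#' records).  MAR missingness is applied last, to categorical covariates
#' only.  Optionally appends `n_ineligible` records violating the
#' age/smoking/e-cigarette-status inclusion criteria so that the inclusion
#' filter has something to remove.
#'
#' @param truth A [truth_model()].
#' @param design A [design_spec()].
#' @param n Number of eligible records.
#' @param seed Integer seed; generation is reproducible given the seed.
#' @param n_ineligible Extra ineligible records appended (default 0).
#'
#' @return A tibble with one row per respondent and a `"roles"` attribute
#'   naming each column's role (design / outcome / exposure / candidate /
#'   forced demographic); see [variable_roles()].
#' @export
generate_population <- function(truth, design, n, seed, n_ineligible = 0) {
  stopifnot(inherits(truth, "truth_model"), inherits(design, "design_spec"),
            n >= 1)
  set.seed(as.integer(seed))

  draw_block <- function(n) {
    stratum_i <- sample.int(design$n_strata, n, replace = TRUE)
    out <- tibble::tibble(
      stratum = sprintf("S%02d", stratum_i),
      psu = sprintf("S%02d_P%02d", stratum_i,
                    sample.int(design$psu_per_stratum, n, replace = TRUE)),
      weight = rlnorm(n, meanlog = design$weight_meanlog[stratum_i],
                      sdlog = design$weight_sdlog),
      year = sample(design$years, n, replace = TRUE,
                    prob = design$year_fractions)
    )
    for (spec in truth$covariates) {
      out[[spec$name]] <- switch(
        spec$type,
        continuous = if (spec$dist == "uniform") {
          runif(n, spec$min, spec$max)
        } else {
          rnorm(n, spec$mean, spec$sd)
        },
        categorical = factor(sample(spec$levels, n, replace = TRUE,
                                    prob = spec$probs),
                             levels = spec$levels)
      )
    }
    out
  }

  pop <- draw_block(n)
  # focal disability and independent background disability types
  p_dis <- plogis(truth$alpha0 + lp_from_effects(pop, truth$alpha, truth$covariates))
  d_focal <- rbinom(n, 1, p_dis)
  for (dt in disability_types()) {
    ind <- if (dt == truth$focal_disability) {
      d_focal
    } else {
      rbinom(n, 1, truth$other_disability_prev[[dt]])
    }
    pop[[dt]] <- factor(ifelse(ind == 1, "yes", "no"), levels = c("no", "yes"))
  }
  # outcome
  p_out <- plogis(truth$beta0 + truth$beta_d * d_focal +
                    lp_from_effects(pop, truth$beta, truth$covariates))
  pop$ecig_use <- rbinom(n, 1, p_out)
  pop$ecig_status <- factor(ifelse(pop$ecig_use == 1, "current", "never"),
                            levels = c("never", "current", "former"))
  pop$cigarettes_lifetime <- sample(0:99, n, replace = TRUE)

  if (n_ineligible > 0) {
    bad <- draw_block(n_ineligible)
    for (dt in disability_types()) {
      bad[[dt]] <- factor(sample(c("no", "yes"), n_ineligible, replace = TRUE,
                                 prob = c(0.9, 0.1)), levels = c("no", "yes"))
    }
    bad$ecig_use <- rbinom(n_ineligible, 1, 0.05)
    bad$ecig_status <- factor(ifelse(bad$ecig_use == 1, "current", "never"),
                              levels = c("never", "current", "former"))
    bad$cigarettes_lifetime <- sample(0:99, n_ineligible, replace = TRUE)
    # violate one criterion per record: too old, heavy smoker, or former user
    mode <- sample.int(3, n_ineligible, replace = TRUE)
    bad$age[mode == 1] <- runif(sum(mode == 1), 35, 60)
    bad$cigarettes_lifetime[mode == 2] <- sample(100:5000, sum(mode == 2),
                                                 replace = TRUE)
    if (any(mode == 3)) {
      bad$ecig_status[mode == 3] <- "former"
      bad$ecig_use[mode == 3] <- 0L
    }
    pop <- dplyr::bind_rows(pop, bad)
  }

  # MAR missingness: categorical covariates only, never outcome/exposure/design
  for (rule in truth$missingness) {
    by_val <- as_level_chr(pop[[rule$by]])
    p <- ifelse(by_val %in% names(rule$probs),
                unname(rule$probs[by_val]), rule$default)
    hit <- runif(nrow(pop)) < p
    col <- pop[[rule$variable]]
    levels(col) <- c(levels(col), MISSING_LEVEL)
    col[hit] <- MISSING_LEVEL
    pop[[rule$variable]] <- col
  }

  attr(pop, "roles") <- variable_roles(truth)
  pop
}

#' Column roles of a generated respondent table
#'
#' @param truth The [truth_model()] used for generation.
#' @return A tibble with columns `variable` and `role` (`design`, `outcome`,
#'   `exposure`, `forced_demographic`, `candidate`, `auxiliary`).
#' @export
variable_roles <- function(truth) {
  forced <- c("age", "gender", "race_ethnicity")
  cand <- setdiff(names(truth$covariates), forced)
  tibble::tibble(
    variable = c("stratum", "psu", "weight", "year",
                 "ecig_use", "ecig_status", "cigarettes_lifetime",
                 disability_types(),
                 intersect(forced, names(truth$covariates)), cand),
    role = c(rep("design", 4), "outcome", "auxiliary", "auxiliary",
             rep("exposure", length(disability_types())),
             rep("forced_demographic",
                 length(intersect(forced, names(truth$covariates)))),
             rep("candidate", length(cand)))
  )
}

#' Write / read a respondent table as CSV plus a JSON schema sidecar
#'
#' The sidecar (`<path>.schema.json`) records each column's role, type and
#' factor levels so that a round-trip restores the table exactly, including
#' the explicit `"Missing"` category.
#'
#' @param data Respondent tibble (with a `"roles"` attribute, if available).
#' @param path CSV path.
#' @param roles Optional roles tibble overriding the attribute.
#' @return `write_respondent_table()` returns `path` invisibly;
#'   `read_respondent_table()` returns the tibble with roles reattached.
#' @export
write_respondent_table <- function(data, path, roles = NULL) {
  roles <- roles %||% attr(data, "roles")
  schema <- list(
    columns = purrr::map(names(data), function(nm) {
      col <- data[[nm]]
      list(name = nm,
           type = if (is.factor(col)) "factor" else class(col)[1],
           levels = if (is.factor(col)) levels(col) else NULL,
           role = if (!is.null(roles) && nm %in% roles$variable) {
             roles$role[match(nm, roles$variable)]
           } else "unspecified")
    })
  )
  readr::write_csv(data, path)
  jsonlite::write_json(schema, paste0(path, ".schema.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_respondent_table
#' @export
read_respondent_table <- function(path) {
  schema <- jsonlite::read_json(paste0(path, ".schema.json"))
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  roles <- tibble::tibble(
    variable = purrr::map_chr(schema$columns, "name"),
    role = purrr::map_chr(schema$columns, "role")
  )
  for (colspec in schema$columns) {
    if (identical(colspec$type, "factor")) {
      data[[colspec$name]] <- factor(data[[colspec$name]],
                                     levels = unlist(colspec$levels))
    } else if (identical(colspec$type, "integer")) {
      data[[colspec$name]] <- as.integer(data[[colspec$name]])
    } else if (identical(colspec$type, "character")) {
      data[[colspec$name]] <- as.character(data[[colspec$name]])
    }
  }
  attr(data, "roles") <- roles
  data
}
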