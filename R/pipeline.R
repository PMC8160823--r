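#' Analysis profiles
#'
#' Bundled settings for the stochastic stages.  The `"full"` profile uses
#' the full-scale settings (300 stability iterations, 10-fold CV, 50
#' imputations with 30 chain sweeps); the `"test"` profile scales them down
#' (100 iterations, m = 10, 10 sweeps) for desk-scale runs.
#'
#' @param profile `"full"` or `"test"`.
#' @param seed Master seed propagated to every stochastic stage.
#' @param ... Overrides for individual settings (`n_iterations`,
#'   `subsample_fraction`, `cv_folds`, `selection_threshold`, `m`,
#'   `n_chain_iterations`).
#' @return A list with a [stability_config()] and an [imputation_config()].
#' @export
analysis_profile <- function(profile = c("test", "full"), seed = 1, ...) {
  profile <- match.arg(profile)
  dots <- list(...)
  defaults <- if (profile == "full") {
    list(n_iterations = 300, subsample_fraction = 0.8, cv_folds = 10,
         selection_threshold = 0.95, m = 50, n_chain_iterations = 30)
  } else {
    list(n_iterations = 100, subsample_fraction = 0.8, cv_folds = 10,
         selection_threshold = 0.95, m = 10, n_chain_iterations = 10)
  }
  p <- utils::modifyList(defaults, dots)
  list(
    profile = profile,
    stability = stability_config(
      n_iterations = p$n_iterations, subsample_fraction = p$subsample_fraction,
      cv_folds = p$cv_folds, selection_threshold = p$selection_threshold,
      seed = seed_stream(seed, "stability")),
    imputation = imputation_config(
      m = p$m, n_chain_iterations = p$n_chain_iterations,
      seed = seed_stream(seed, "imputation")),
    seed = seed
  )
}

#' Run the full confounder-selection / imputation / pooling analysis
#'
#' For each requested disability: build the subgroup (reporters of that
#' disability plus reporters of no disability); run stability selection
#' twice -- endpoint = the disability of interest, endpoint = the outcome --
#' over the candidate covariates; intersect the two selected sets and add
#' the forced demographics; multiply impute the explicit-Missing categories
#' of the adjustment variables; fit the design-weighted logistic regression
#' on each completed dataset for Model 1 (forced demographics only) and
#' Model 2 (forced demographics plus selected confounders); and pool the
#' per-imputation exposure effects by Rubin's rules.
#'
#' A failed disability aborts only its own rows (with the reason recorded
#' in `errors`); other disabilities proceed.
#'
#' @param data Respondent tibble (design columns `weight`, `stratum`,
#'   `psu`, the six disability indicators, and the outcome).
#' @param outcome Name of the binary outcome column.
#' @param candidates Candidate confounder variables for stability
#'   selection (must exclude design columns, the outcome and the
#'   disability indicators).
#' @param forced Forced demographic adjustment variables.
#' @param disabilities Disabilities to analyze (`"any"` and/or types).
#' @param profile An [analysis_profile()].
#' @param derive Run [derive_disability()] first (default TRUE when
#'   `any_disability` is absent).
#' @return An `svystab_analysis`: list with `results` (one row per
#'   disability x model: pooled OR, CI, Rubin internals, n_mean),
#'   `confounders` (per-disability [intersect_confounders()] output),
#'   `stability` (the per-endpoint reports), `gvif_flags`, `diagnostics`
#'   (imputation convergence), and `errors`.
#' @export
run_analysis <- function(data, outcome = "ecig_use",
                         candidates, forced = c("age", "gender", "race_ethnicity"),
                         disabilities = c("any", disability_types()),
                         profile = analysis_profile("test"),
                         derive = !("any_disability" %in% names(data))) {
  check_columns(data, c(outcome, candidates, forced,
                        "weight", "stratum", "psu"), "run_analysis")
  if (derive) data <- derive_disability(data)
  overlap <- intersect(candidates, c(outcome, disability_types(),
                                     "weight", "stratum", "psu"))
  if (length(overlap) > 0) {
    abort(sprintf("Candidates may not include outcome/exposure/design columns: %s",
                  paste(overlap, collapse = ", ")),
          class = "svystab_config_error")
  }

  results <- list(); conf_sets <- list(); reports <- list()
  gvif_flags <- list(); diagnostics <- list(); errors <- list()

  for (dis in disabilities) {
    res <- tryCatch(
      analyze_one_disability(data, dis, outcome, candidates, forced, profile),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      errors[[dis]] <- conditionMessage(res)
      next
    }
    results[[dis]] <- res$rows
    conf_sets[[dis]] <- res$confounders
    reports[[dis]] <- res$stability
    gvif_flags[[dis]] <- res$gvif_flags
    diagnostics[[dis]] <- res$diagnostics
  }

  structure(list(
    results = dplyr::bind_rows(results),
    confounders = conf_sets,
    stability = reports,
    gvif_flags = dplyr::bind_rows(gvif_flags),
    diagnostics = dplyr::bind_rows(diagnostics),
    errors = errors,
    profile = profile
  ), class = "svystab_analysis")
}

analyze_one_disability <- function(data, dis, outcome, candidates, forced,
                                   profile) {
  sub <- build_subgroup(data, dis)
  # per-disability deterministic sub-seeds
  stab_cfg <- profile$stability
  stab_cfg$seed <- seed_stream(stab_cfg$seed, paste0("dis-", dis))
  imp_cfg <- profile$imputation
  imp_cfg$seed <- seed_stream(imp_cfg$seed, paste0("dis-", dis))

  rep_dis <- stability_select(sub, "exposure_flag", candidates, stab_cfg)
  stab_cfg_out <- stab_cfg
  stab_cfg_out$seed <- seed_stream(stab_cfg$seed, "outcome-endpoint")
  rep_out <- stability_select(sub, outcome, candidates, stab_cfg_out)
  cs <- intersect_confounders(rep_dis, rep_out, forced = forced,
                              disability = dis)

  imp <- impute_chained(sub, variables = cs$adjustment,
                        extra_predictors = c(outcome, "exposure_flag"),
                        config = imp_cfg)
  diag <- convergence_diagnostics(imp)
  if (nrow(diag) > 0) diag$disability <- dis

  model_terms <- list(
    `Model 1` = union("exposure_flag", forced),
    `Model 2` = union("exposure_flag", cs$adjustment)
  )
  rows <- list(); flags <- list()
  for (mod in names(model_terms)) {
    form <- reformulate(model_terms[[mod]], response = outcome)
    ests <- numeric(0); vars <- numeric(0); dfc <- Inf; ns <- numeric(0)
    for (k in seq_along(imp$datasets)) {
      fit <- fit_survey_logistic(imp$datasets[[k]], form)
      ests <- c(ests, coef(fit)[["exposure_flag"]])
      vars <- c(vars, fit$vcov["exposure_flag", "exposure_flag"])
      dfc <- min(dfc, fit$df_design)
      ns <- c(ns, fit$n)
      if (!is.null(fit$gvif)) {
        flags[[paste(mod, k)]] <- dplyr::mutate(fit$gvif, disability = dis,
                                                model = mod, imputation = k)
      }
    }
    rows[[mod]] <- pool_rubin(ests, vars, df_complete = dfc,
                              disability = dis, model = mod,
                              n_mean = mean(ns))
  }
  list(rows = dplyr::bind_rows(rows), confounders = cs,
       stability = list(disability = rep_dis, outcome = rep_out),
       gvif_flags = dplyr::bind_rows(flags), diagnostics = diag)
}

#' @exportS3Method base::print
print.svystab_analysis <- function(x, ...) {
  cat("Stability-selected survey analysis\n")
  res <- x$results |>
    dplyr::mutate(`OR (95% CI)` = sprintf("%.2f (%.2f-%.2f)", .data$or,
                                          .data$conf_low, .data$conf_high)) |>
    dplyr::select("disability", "model", "n_mean", "OR (95% CI)") |>
    tidyr::pivot_wider(names_from = "model", values_from = "OR (95% CI)")
  print(res, n = Inf)
  if (length(x$errors) > 0) {
    cat("Failed disabilities:", paste(names(x$errors), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write the analysis report files
#'
#' Emits the pooled results as TSV and JSON (ORs, CIs and Rubin internals
#' per disability and model), the per-endpoint stability frequencies as
#' JSON, and the confounder sets as JSON, into `dir`.
#'
#' @param analysis An `svystab_analysis`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_analysis_report <- function(analysis, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(analysis$results, file.path(dir, "pooled_effects.tsv"))
  jsonlite::write_json(analysis$results, file.path(dir, "pooled_effects.json"),
                       auto_unbox = TRUE, digits = NA)
  freq <- purrr::imap(analysis$stability, function(reps, dis) {
    list(disability = as.list(setNames(reps$disability$frequency,
                                       reps$disability$variable)),
         outcome = as.list(setNames(reps$outcome$frequency,
                                    reps$outcome$variable)))
  })
  jsonlite::write_json(freq, file.path(dir, "stability_frequencies.json"),
                       auto_unbox = TRUE, digits = NA)
  conf <- purrr::map(analysis$confounders, function(cs) {
    list(confounders = cs$confounders, forced = cs$forced,
         adjustment = cs$adjustment)
  })
  jsonlite::write_json(conf, file.path(dir, "confounder_sets.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' Simulation study: repeat generate-and-analyze and score recovery
#'
#' Repeats, `replicates` times: generate a synthetic population from the
#' truth model, run the full pipeline for the focal disability, and score
#' the replicate against the known truth -- does the pooled Model 2
#' confidence interval cover the true conditional odds ratio, is the null
#' `OR = 1` rejected, and how well does the stability stage recover the
#' true confounders (sensitivity) while excluding the noise covariates
#' (false-selection rate)?
#'
#' @param truth A [truth_model()].
#' @param design A [design_spec()].
#' @param n Records per replicate.
#' @param replicates Number of replicates.
#' @param profile An [analysis_profile()]; its seed is re-derived per
#'   replicate.
#' @param seed Master seed.
#' @return A `simulation_study`: list with `replicates` (per-replicate
#'   tibble) and `summary` (coverage, rejection rate, mean selection
#'   sensitivity and noise false-selection rate).
#' @export
run_simulation_study <- function(truth, design, n, replicates,
                                 profile = analysis_profile("test"),
                                 seed = 1) {
  stopifnot(replicates >= 1)
  true_or <- truth_conditional_or(truth)
  true_conf <- truth$confounder_names
  forced <- c("age", "gender", "race_ethnicity")
  noise <- setdiff(names(truth$covariates), c(true_conf, forced))
  rows <- purrr::map(seq_len(replicates), function(r) {
    pop <- generate_population(truth, design, n,
                               seed = seed_stream(seed, "replicate", r))
    prof <- profile
    prof$stability$seed <- seed_stream(seed, "rep-stab", r)
    prof$imputation$seed <- seed_stream(seed, "rep-imp", r)
    an <- run_analysis(pop, candidates = setdiff(names(truth$covariates), forced),
                       forced = forced,
                       disabilities = truth$focal_disability,
                       profile = prof)
    if (length(an$errors) > 0 || nrow(an$results) == 0) {
      # a failed replicate (e.g. separation in a sparse cell) is recorded
      # as missing, not silently dropped
      return(tibble::tibble(replicate = r, or = NA_real_,
                            conf_low = NA_real_, conf_high = NA_real_,
                            covered = NA, rejected = NA,
                            sensitivity = NA_real_, false_selection = NA_real_))
    }
    m2 <- dplyr::filter(an$results, .data$model == "Model 2")
    found <- an$confounders[[truth$focal_disability]]$confounders
    tibble::tibble(
      replicate = r,
      or = m2$or, conf_low = m2$conf_low, conf_high = m2$conf_high,
      covered = m2$conf_low <= true_or & true_or <= m2$conf_high,
      rejected = m2$conf_low > 1 | m2$conf_high < 1,
      sensitivity = if (length(true_conf)) {
        length(intersect(found, true_conf)) / length(true_conf)
      } else NA_real_,
      false_selection = if (length(noise)) {
        length(intersect(found, noise)) / length(noise)
      } else NA_real_
    )
  })
  rows <- dplyr::bind_rows(rows)
  structure(list(
    replicates = rows,
    summary = tibble::tibble(
      n_replicates = replicates,
      n_completed = sum(!is.na(rows$or)),
      true_or = true_or,
      coverage = mean(rows$covered, na.rm = TRUE),
      rejection_rate = mean(rows$rejected, na.rm = TRUE),
      mean_or = mean(rows$or, na.rm = TRUE),
      selection_sensitivity = mean(rows$sensitivity, na.rm = TRUE),
      noise_false_selection = mean(rows$false_selection, na.rm = TRUE)
    )
  ), class = "simulation_study")
}

#' @exportS3Method base::print
print.simulation_study <- function(x, ...) {
  cat("Simulation study\n")
  print(x$summary)
  invisible(x)
}
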