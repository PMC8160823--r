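---
title: "Methods: stability-selected confounder adjustment for survey logistic regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stability-selected confounder adjustment for survey logistic regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

svystab estimates the association between a reported disability and a binary
behavioural outcome (current e-cigarette use) in complex survey microdata,
using a four-stage procedure: data-driven confounder selection by stability
LASSO, multiple imputation of explicit missing-response categories, design-
weighted logistic regression with linearized variances, and Rubin's-rules
pooling. This vignette documents the statistical model behind each stage, the
tunable parameters and their defaults, what the synthetic generator does and
does not emulate, and the numerical choices made where the design was open.

## The estimand and the subgroup construction

For each disability type $d$ (vision, hearing, cognitive, mobility,
independent living, self-care, or "any"), the analysis subgroup contains the
respondents who report $d$ plus the respondents who report *no* disability at
all; respondents with only other disabilities, or whose missing answers
prevent classification, are excluded from that subgroup. Within the
subgroup, the target is the conditional odds ratio $\exp(\beta_D)$ in

$$\operatorname{logit} P(E = 1 \mid D, C) = \beta_0 + \beta_D D + \beta^T C,$$

where $E$ is current e-cigarette use, $D$ the disability indicator and $C$
the adjustment covariates. Model 1 adjusts only for the forced demographics
(age, gender, race/ethnicity, treated as non-modifiable exposures and always
included regardless of selection frequencies); Model 2 additionally adjusts
for the selected confounders. Respondent age enters as a continuous
covariate; no age banding is applied.

Subgroup membership is decided on the reported disability answers
themselves, never by imputation: the imputation stage fills in covariate
answers only, so each subgroup's sample size is fixed across imputations in
the package (the pooled table still reports `n_mean` for generality).

## Stage 1: stability-LASSO confounder selection

A variable is treated as a potential confounder when it is associated with
*both* the disability endpoint and the outcome endpoint in the same
subgroup — the operational intersection rule. Each endpoint's associations
are found by stability selection over L1-penalized logistic regressions:

1. Draw a subsample of $\lceil 0.8 n \rceil$ records without replacement.
2. One-hot-code the candidate covariates (first observed non-missing level
   as reference; the explicit `"Missing"` category always gets its own
   dummy column).
3. Fit the penalized logistic path and pick $\lambda_m$, the penalty
   minimizing 10-fold cross-validated binomial deviance, with folds
   stratified on the endpoint so each fold sees both classes.
4. Record a variable as selected when at least one of its *non-missing*
   dummy columns has a nonzero coefficient at $\lambda_m$. A variable whose
   only signal is "who refused to answer" is not a substantive association,
   so a nonzero coefficient on the `"Missing"` dummy alone does not count.

Repeating this 300 times (the full-scale default) gives per-variable
selection frequencies; variables exceeding the strict threshold 0.95 are
kept, and the two endpoints' kept sets are intersected.

Open choices resolved here: subsampling is *without* replacement (the
conventional reading of "random samples comprising 80%", and the standard
stability-selection construction); the penalty grid (100 log-spaced values
down to $10^{-4}\lambda_{\max}$) is rebuilt inside every subsample, since
each iteration is a self-contained fit with its own standardization; CV
ties resolve toward the larger (sparser) penalty. The LASSO stage is
unweighted — the survey design enters only the final inference model, the
selection step being a screening device, not an estimator.

Properties worth knowing: selection frequencies are invariant to the
labelling and order of other candidates; raising the threshold can only
shrink the kept set; with a subsample fraction of 1 and a fixed CV seed all
iterations coincide and every frequency is 0 or 1.

## Stage 2: multiple imputation by chained equations

Item nonresponse ("refused / not sure / don't know / missing") is an
explicit category of each categorical covariate. The adjustment variables
of each subgroup are multiply imputed within that subgroup: $m$ streams,
each initialized by random draws from the observed marginal, then swept
`n_chain_iterations` times; each sweep refits every incomplete variable's
conditional model — multinomial (polytomous) regression for more than two
observed categories, logistic for binary, both with a mild weight-decay
ridge of $10^{-6}$ for separation robustness — on the currently completed
data and redraws the missing cells from the fitted predictive distribution.
The outcome and the exposure indicator are always predictors and are never
imputed; survey weights and design identifiers stay out of the conditional
models (imputation is a measurement model for answers, not a population
estimator). Variables are visited in increasing order of missingness.
Full-scale defaults are $m = 50$ and 30 sweeps; convergence can be
inspected with `convergence_diagnostics()` or `autoplot()` of the per-
stream trace of imputed-category frequencies, which flags a variable whose
between-stream spread grows over the last third of the chain.

Only categorical covariates are imputed; continuous covariates (age) are
complete by construction in the supported data dialect. Imputation is run
per subgroup, on exactly the variables entering that subgroup's models,
because the adjustment set is subgroup-specific.

## Stage 3: design-weighted logistic regression

On each completed dataset the coefficients solve the weighted score
equations $\sum_i w_i x_i (y_i - p_i(\beta)) = 0$ (IRLS; weights are
internally normalized to mean 1, which changes nothing statistically — both
the estimator and the linearized variance are scale-invariant — but keeps
IRLS numerically stable with weights in the hundreds). The covariance is
the Taylor-linearization sandwich: the bread is the inverse weighted
information; the meat sums, over design strata, $n_h/(n_h-1)$ times the
covariance of stratum-centered PSU totals of the score residuals (PSUs
treated as drawn with replacement). Design degrees of freedom are
(number of PSUs) − (number of strata). Wald intervals use a $t$ reference
on those df.

Numerical and degenerate-input policies:

* **Lonely PSUs.** Subgroup construction can leave a stratum with a single
  PSU; its total is centered at the grand mean of all PSU totals (a
  conservative contribution), with a warning.
* **Separation.** Coefficients beyond ±15 on the logit scale abort the fit
  with an error naming the offending terms; in the pipeline this aborts
  only the affected disability's rows. At full survey scale this
  essentially never triggers; at small simulation sizes a rare covariate
  level with zero events can.
* **Collinearity.** Each fitted model reports generalized variance-
  inflation factors per term, computed as the determinant ratio
  $\det(R_{t})\det(R_{-t})/\det(R)$ over the weighted predictor correlation
  matrix (intercept excluded), and $\mathrm{GVIF}^{1/(2\,\mathrm{df})}$ is
  flagged above 1.4.

Weighted prevalences use the ratio estimator with the same stratum/PSU
linearization, and Wald intervals truncated to $[0, 1]$.

## Stage 4: Rubin's rules

Per-imputation exposure log-odds $\hat q_k$ with squared standard errors
$U_k$ pool as $\bar q = m^{-1}\sum \hat q_k$, $W = m^{-1}\sum U_k$,
$B = \operatorname{var}(\hat q_k)$, $T = W + (1 + 1/m)B$. Degrees of
freedom follow the Barnard–Rubin small-sample adjustment with the design df
as the complete-data df — the adjusted df never exceed the design df, which
matters because survey df are modest. Pooling happens on the log-odds
scale (where approximate normality is defensible) and the OR and its
interval are exponentiated last. When $B = 0$ the interval reduces exactly
to the single-fit $t$ interval.

## The synthetic generator and what passing tests show

`generate_population()` draws independent covariates, a focal disability
from $\operatorname{logit} P(D=1) = \alpha_0 + \alpha^T C$, the outcome
from $\operatorname{logit} P(E=1) = \beta_0 + \beta_D D + \beta^T C$, the
five non-focal disability types as independent background prevalences
matching young-adult surveillance levels (0.8%–7.6%), a stratified design
(8 strata × 6 PSUs, lognormal weights whose stratum means span roughly a
tenfold range, two year labels), and missing-at-random nonresponse applied
only to categorical covariates. Because weights depend only on the design
columns, the weighted estimator targets the same $\exp(\beta_D)$ as the
unweighted one, giving recovery tests a single known truth. The default
truth (`default_truth_model()`) carries three true confounders (employment
status, days of poor mental health, depressive disorder) with per-level
effects of magnitude 0.7–1.3 log-odds on both endpoints — the order of the
stronger covariate contrasts seen in surveillance data — seven null
covariates, ~4–6% outcome prevalence and ~8–11% focal disability
prevalence, and income ~17% / mental-health-days ~4% missing, driven by
gender.

The generator deliberately does *not* emulate: dependence among covariates
(independence keeps the confounding structure analytically known),
telephone-frame nonresponse or weight raking, PSU-level intra-cluster
correlation of the outcome beyond what the design columns induce, or the
joint distribution of a real 40-variable codebook. Passing recovery tests
therefore demonstrates the *inference machinery* — selection, imputation,
weighting, pooling — not robustness to correlated-covariate selection
behaviour, which is a known limitation of any LASSO-based screen.

## Problem sizes used by the tests and the acceptance script

The full-scale profile (300 stability iterations, 10-fold CV, $m = 50$,
30 sweeps; `analysis_profile("full")`) is impractical for a test suite, so
the package's own validation uses its scaled test profile: selection-
recovery checks run 100 iterations at $n = 2{,}000$ over 5 replicates, and
the end-to-end coverage study runs 15–20 replicates at $n = 4{,}000$ with
25 stability iterations, 5-fold CV, $m = 5$ and 5 sweeps. These sizes were
chosen so that a full run completes in minutes on one CPU while keeping the
binomial bounds on coverage and rejection informative; the full-scale
profile remains available for real analyses.

## Known limitations

* The intersection rule inherits LASSO's behaviour under correlated
  candidates: of two highly correlated true confounders, one may be
  selected unstably, depressing its frequency below the threshold.
* Confounders identified by the screen may in truth be mediators or
  colliders; the package implements the operational rule, not a causal
  discovery procedure.
* Variance estimation treats PSUs as sampled with replacement; replicate-
  weight methods are out of scope.
* Imputation conditionals assume each incomplete variable's answers are
  missing at random given the other model variables and the outcome.
* Intervals are Wald-type on the log-odds scale; at simulation sizes with
  only a few dozen exposed events they are mildly anti-conservative (the
  usual small-count Wald behaviour), which surfaces as null rejection
  rates somewhat above nominal in small replicate studies. At survey
  scale (tens of thousands of records, thousands of events) this
  vanishes.
* Combined-year weighting divides by the number of years (equal
  allocation), appropriate when each year contributes a full-size annual
  sample; per-year sample-fraction ratios are not implemented.
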