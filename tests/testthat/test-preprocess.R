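toy_inclusion_fixture <- function() {
  # hand-enumerated: rows 2, 3, 8, 10 are eligible
  tibble::tibble(
    id = 1:10,
    age = c(17, 18, 34, 35, 25, 25, 25, 30, 30, 19),
    cigarettes_lifetime = c(0, 99, 0, 0, 100, 250, 0, 50, 99, 0),
    ecig_status = c("never", "current", "never", "current", "never",
                    "never", "former", "current", "former", "never")
  )
}

test_that("apply_inclusion keeps exactly the hand-enumerated subset, idempotently", {
  toy <- toy_inclusion_fixture()
  kept <- apply_inclusion(toy)
  expect_identical(kept$id, c(2L, 3L, 8L, 10L))
  expect_identical(apply_inclusion(kept), kept)
  # empty table in, empty table out
  expect_identical(nrow(apply_inclusion(toy[0, ])), 0L)
  # missing required column is a schema error
  expect_error(apply_inclusion(toy[, c("id", "age")]),
               class = "svystab_schema_error")
})

test_that("derive_disability obeys the any-disability invariants", {
  types <- disability_types()
  fix <- tibble::as_tibble(setNames(as.list(rep("no", 6)), types))
  fix <- fix[rep(1, 4), ]
  fix$vision[2] <- "yes"
  fix$hearing[3] <- "Missing"
  fix$hearing[4] <- "Missing"; fix$mobility[4] <- "yes"
  out <- derive_disability(fix)
  # all no -> no; one yes -> yes; missing + rest no -> Missing;
  # missing + another yes -> yes (at least one affirmative)
  expect_equal(as.character(out$any_disability),
               c("no", "yes", "Missing", "yes"))
  bad <- fix; bad$vision[1] <- "maybe"
  expect_error(derive_disability(bad), class = "svystab_schema_error")
})

test_that("recode_missing collapses sentinels and backfills gated skips", {
  df <- tibble::tibble(
    smokeless = c("yes", "7", "9", NA, "no", "9"),
    tobacco_any = c("yes", "yes", "no", "no", "yes", "yes"),
    untouched = c("1", "2", "1", "2", "1", "2")
  )
  out <- recode_missing(
    df,
    sentinels = list(smokeless = c("7", "9")),
    backfill = list(list(variable = "smokeless", gate = "tobacco_any",
                         gate_level = "no", value = "no"))
  )
  # rows 3 and 4 were skipped because the gate says no tobacco at all
  expect_equal(as.character(out$smokeless),
               c("yes", "Missing", "no", "no", "no", "Missing"))
  expect_true("Missing" %in% levels(out$smokeless))
  # column without sentinels passes through unchanged
  expect_identical(out$untouched, df$untouched)
  # sentinel colliding with a declared genuine level is a config error
  expect_error(
    recode_missing(df, sentinels = list(smokeless = "no"),
                   genuine_levels = list(smokeless = c("yes", "no"))),
    class = "svystab_config_error")
})

test_that("combined-year weight adjustment halves weights and splits strata", {
  df <- tibble::tibble(
    weight = c(840.5, 100, 200, 300),
    stratum = c("S1", "S1", "S1", "S2"),
    year = c("2016", "2016", "2017", "2017")
  )
  out <- adjust_weights_for_combined_years(df, n_years = 2)
  expect_equal(out$weight[1], 420.25)
  # total weighted count = sum of both years' weighted counts / 2
  expect_equal(sum(out$weight), sum(df$weight) / 2)
  # relative weights within a year preserved exactly
  expect_equal(out$weight[2] / out$weight[1], df$weight[2] / df$weight[1])
  # strata never span years
  expect_equal(length(unique(out$stratum)), 3L)
  one <- adjust_weights_for_combined_years(df, n_years = 1)
  expect_identical(one$weight, df$weight)
  expect_error(adjust_weights_for_combined_years(df, 0),
               class = "svystab_config_error")
})

test_that("build_subgroup keeps the disability of interest plus the no-disability group", {
  types <- disability_types()
  n <- 100
  fix <- tibble::as_tibble(setNames(
    replicate(6, rep("no", n), simplify = FALSE), types))
  fix$self_care[1:5] <- "yes"
  fix$cognitive[6:20] <- "yes"     # 15 cognitive-only records
  fix <- derive_disability(fix)

  sc <- build_subgroup(fix, "self_care")
  expect_equal(nrow(sc), 85L)  # 5 self-care + 80 no-disability
  expect_equal(sum(sc$exposure_flag), 5L)

  # subsets of the input; "any" is the largest of the seven subgroups
  sizes <- vapply(c("any", types), function(d)
    nrow(build_subgroup(fix, d)), 0L)
  expect_true(all(sizes <= n))
  expect_equal(unname(sizes["any"]), max(sizes))

  # records with an unclassifiable profile are dropped from "any"
  fix2 <- fix
  fix2$vision[21] <- "Missing"
  fix2 <- derive_disability(fix2)
  expect_equal(nrow(build_subgroup(fix2, "any")), 99L)

  expect_error(build_subgroup(fix, "psychic"),
               class = "svystab_config_error")
})
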