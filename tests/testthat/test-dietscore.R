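test_that("quintile scoring follows the percentile bins and tie rule", {
  expect_equal(quintileScores(1:10), as.integer(rep(1:5, each = 2)))
  expect_equal(quintileScores(1:100)[100], 5L)
  expect_equal(quintileScores(1:100, reverse = TRUE)[100], 1L)
  # degenerate constant vector: everyone in the lowest quintile
  expect_true(all(quintileScores(rep(3, 10)) == 1L))
  expect_true(all(quintileScores(rep(3, 10), reverse = TRUE) == 5L))
  expect_error(quintileScores(1:4), "at least 5")
  # equivariance: permuting participants permutes scores identically
  set.seed(3)
  x <- rnorm(40)
  perm <- sample(40)
  expect_equal(quintileScores(x)[perm], quintileScores(x[perm]))
})

test_that("PDI family scores respect ranges and the reflection identity", {
  prep <- smallPrepared()
  fg <- prep$diet$foodgroups
  for (v in c("PDI", "hPDI", "uPDI")) {
    s <- scorePdiFamily(fg, v)
    expect_true(all(s >= 18 & s <= 90))
  }
  # flipping every scoring direction reflects the score about 18 * 6 = 108
  defs <- loadIndexDefinitions()
  flipped <- defs
  flipped$pdi <- list(healthy_plant = defs$pdi$animal,
                      less_healthy_plant = character(),
                      animal = c(defs$pdi$healthy_plant,
                                 defs$pdi$less_healthy_plant))
  expect_equal(scorePdiFamily(fg, "PDI") +
                 scorePdiFamily(fg, "PDI", defs = flipped),
               rep(108L, nrow(fg)))
  expect_error(scorePdiFamily(fg[, 1:3], "PDI"), "missing index component")
})

test_that("DASH and aMED scores match hand tallies on a toy cohort", {
  set.seed(4)
  n <- 10
  groups <- foodGroupMeta()$group
  fg <- matrix(rlnorm(n * length(groups)), n,
               dimnames = list(NULL, groups))
  nut <- data.frame(sodium_mg = rlnorm(n, 7))
  dash <- scoreDash(fg, nut)
  expect_true(all(dash >= 8 & dash <= 40))
  # hand tally of one encouraged and one discouraged component
  manual <- quintileScores(fg[, "fruits"]) +
    quintileScores(fg[, "vegetables"]) +
    quintileScores(fg[, "nuts_seeds"] + fg[, "legumes"]) +
    quintileScores(fg[, "wholegrains"]) +
    quintileScores(fg[, "low_fat_dairy"]) +
    quintileScores(fg[, "red_meat"] + fg[, "processed_meat"], reverse = TRUE) +
    quintileScores(fg[, "sugar_sweetened_beverages"], reverse = TRUE) +
    quintileScores(nut$sodium_mg, reverse = TRUE)
  expect_equal(dash, manual)

  amed <- scoreAmed(fg, sex = rep(0, n))
  expect_true(all(amed >= 0 & amed <= 9))
  manual_amed <- as.integer(fg[, "vegetables"] > median(fg[, "vegetables"])) +
    as.integer(fg[, "fruits"] > median(fg[, "fruits"])) +
    as.integer(fg[, "nuts_seeds"] > median(fg[, "nuts_seeds"])) +
    as.integer(fg[, "legumes"] > median(fg[, "legumes"])) +
    as.integer(fg[, "wholegrains"] > median(fg[, "wholegrains"])) +
    as.integer(fg[, "fish_seafood"] > median(fg[, "fish_seafood"])) +
    as.integer(fg[, "vegetable_oils"] > median(fg[, "vegetable_oils"])) +
    as.integer(fg[, "red_meat"] + fg[, "processed_meat"] <
                 median(fg[, "red_meat"] + fg[, "processed_meat"])) +
    as.integer(fg[, "alcoholic_beverages"] >= 5 &
                 fg[, "alcoholic_beverages"] <= 15)
  expect_equal(amed, manual_amed)
  # identical participants score zero on all above-median components
  same <- matrix(1, 4, length(groups), dimnames = list(NULL, groups))
  expect_true(all(scoreAmed(same, sex = rep(1, 4)) == 0L))
})

test_that("plant and meat percentages are grams-based shares", {
  groups <- foodGroupMeta()$group
  fg <- matrix(0, 1, length(groups), dimnames = list(NULL, groups))
  fg[, "fruits"] <- 100
  pm <- plantMeatPercent(fg)
  expect_equal(pm$plant_pct, 100)
  expect_equal(pm$meat_pct, 0)
  fg[, "fruits"] <- 30
  fg[, "red_meat"] <- 30
  fg[, "dairy"] <- 40 # neither plant nor meat category
  pm <- plantMeatPercent(fg)
  expect_equal(pm$plant_pct, 30)
  expect_equal(pm$meat_pct, 30)
  expect_error(plantMeatPercent(fg * 0), "zero total")
  # empty meat category in the config gives zero meat share
  defs <- loadIndexDefinitions()
  defs$plant_meat$meat <- character()
  expect_equal(plantMeatPercent(fg, defs)$meat_pct, 0)
})

test_that("pooled cohort equations reduce to the baseline identities", {
  zero_cs <- list(test_female = list(
    terms = list(ln_age = 0, ln_tc = 0, ln_hdl = 0, ln_sbp_treated = 0,
                 ln_sbp_untreated = 0, smoker = 0, diabetes = 0),
    mean_lp = 0, baseline_survival = 0.95
  ))
  profile <- data.frame(age_years = 55, sex = 0, race_group = "test",
                        total_chol_mgdl = 200, hdl_mgdl = 50,
                        sbp_mmhg = 120, on_htn_meds = 0, diabetes = 0,
                        smoker = 0)
  expect_equal(ascvdRisk(profile, zero_cs), 1 - 0.95)
  zero_cs$test_female$baseline_survival <- 1
  expect_equal(ascvdRisk(profile, zero_cs), 0)
  expect_error(ascvdRisk(profile, list()), "stratum")
})

test_that("risk is monotone in blood pressure for the shipped strata", {
  profile <- data.frame(age_years = 55, sex = 1, race_group = "white",
                        total_chol_mgdl = 213, hdl_mgdl = 50,
                        sbp_mmhg = 120, on_htn_meds = 0, diabetes = 0,
                        smoker = 0)
  risks <- sapply(c(110, 130, 150, 170), function(sbp) {
    profile$sbp_mmhg <- sbp
    ascvdRisk(profile)
  })
  expect_true(all(diff(risks) > 0))
  expect_true(all(risks > 0 & risks < 1))
})

test_that("all indices stay in range on synthetic cohorts", {
  for (which in c("discovery", "replication")) {
    idx <- smallPrepared(which)$indices
    expect_true(all(idx$PDI >= 18 & idx$PDI <= 90))
    expect_true(all(idx$hPDI >= 18 & idx$hPDI <= 90))
    expect_true(all(idx$uPDI >= 18 & idx$uPDI <= 90))
    expect_true(all(idx$DASH >= 8 & idx$DASH <= 40))
    expect_true(all(idx$aMED >= 0 & idx$aMED <= 9))
    expect_true(all(idx$plant_pct + idx$meat_pct <= 100 + 1e-9))
  }
})
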