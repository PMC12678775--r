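#' Load the dietary index component definitions
#'
#' Component lists for the PDI family, DASH, aMED and the plant/meat
#' percentage categories live in a JSON configuration file mirroring the
#' supplementary component tables of the emulated study design, not in code.
#'
#' @param path JSON file; default is the copy shipped with the package.
#' @return nested list of index definitions.
#' @export
loadIndexDefinitions <- function(path = system.file("extdata",
                                                    "diet_indices.json",
                                                    package = "metadiet")) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}

#' Within-cohort quintile scores
#'
#' Scores each value 1-5 by the empirical 20/40/60/80 percentiles of the
#' cohort vector (quintile 1 scores 1, ..., quintile 5 scores 5); with
#' `reverse = TRUE` the scoring direction is flipped. Values tied with a
#' quintile edge fall in the lower quintile, which matters for components
#' with many zero intakes (e.g. alcohol).
#'
#' @param x cohort-level intake vector (length >= 5).
#' @param reverse flip the scoring direction.
#' @return integer scores in 1..5, same length as `x`.
#' @export
quintileScores <- function(x, reverse = FALSE) {
  if (length(x) < 5) stop("quintile scoring requires at least 5 values")
  edges <- quantile(x, c(0.2, 0.4, 0.6, 0.8), names = FALSE)
  sc <- 1L + (x > edges[1]) + (x > edges[2]) + (x > edges[3]) + (x > edges[4])
  if (reverse) sc <- 6L - sc
  as.integer(sc)
}

#' Plant-based diet index family (PDI, hPDI, uPDI)
#'
#' Sums within-cohort quintile scores over the 18 PDI component groups.
#' PDI scores all plant groups positively and animal groups reversed; hPDI
#' scores healthy-plant groups positively and everything else reversed;
#' uPDI scores less-healthy-plant groups positively and everything else
#' reversed. The score range is 18-90.
#'
#' @param foodgroups participant x group matrix of energy-adjusted intakes.
#' @param variant one of `"PDI"`, `"hPDI"`, `"uPDI"`.
#' @param defs index definitions from [loadIndexDefinitions()].
#' @return integer score per participant.
#' @export
scorePdiFamily <- function(foodgroups, variant = c("PDI", "hPDI", "uPDI"),
                           defs = loadIndexDefinitions()) {
  variant <- match.arg(variant)
  comp <- defs$pdi
  all_groups <- c(comp$healthy_plant, comp$less_healthy_plant, comp$animal)
  missing <- setdiff(all_groups, colnames(foodgroups))
  if (length(missing)) {
    stop("missing index component group(s): ", paste(missing, collapse = ", "))
  }
  positive <- switch(variant,
    PDI = c(comp$healthy_plant, comp$less_healthy_plant),
    hPDI = comp$healthy_plant,
    uPDI = comp$less_healthy_plant
  )
  total <- integer(nrow(foodgroups))
  for (g in all_groups) {
    total <- total + quintileScores(foodgroups[, g],
                                    reverse = !(g %in% positive))
  }
  total
}

componentIntake <- function(component, foodgroups, nutrients) {
  if (!is.null(component$nutrient) && !is.na(component$nutrient)) {
    if (is.null(nutrients) || !component$nutrient %in% colnames(nutrients)) {
      stop("missing index component nutrient: ", component$nutrient)
    }
    return(nutrients[[component$nutrient]])
  }
  groups <- unlist(component$groups)
  missing <- setdiff(groups, colnames(foodgroups))
  if (length(missing)) {
    stop("missing index component group(s): ", paste(missing, collapse = ", "))
  }
  rowSums(foodgroups[, groups, drop = FALSE])
}

asComponentList <- function(x) {
  # jsonlite may simplify the component array to a data.frame
  if (is.data.frame(x)) {
    lapply(seq_len(nrow(x)), function(i) as.list(x[i, , drop = FALSE]))
  } else {
    x
  }
}

#' DASH diet score
#'
#' Eight components: encouraged components (fruits, vegetables,
#' nuts/legumes, wholegrains, low-fat dairy) are quintile-scored 1-5 and
#' discouraged components (sodium, red/processed meat, sweetened beverages)
#' reverse-scored; the sum ranges 8-40.
#'
#' @inheritParams scorePdiFamily
#' @param nutrients nutrient table providing the sodium component.
#' @return integer score per participant.
#' @export
scoreDash <- function(foodgroups, nutrients = NULL,
                      defs = loadIndexDefinitions()) {
  total <- integer(nrow(foodgroups))
  for (comp in asComponentList(defs$dash$encouraged)) {
    total <- total + quintileScores(componentIntake(comp, foodgroups,
                                                    nutrients))
  }
  for (comp in asComponentList(defs$dash$discouraged)) {
    total <- total + quintileScores(componentIntake(comp, foodgroups,
                                                    nutrients),
                                    reverse = TRUE)
  }
  total
}

#' Alternate Mediterranean diet score (aMED)
#'
#' Nine binary components scored against within-cohort medians: 1 point for
#' each beneficial component above the cohort median, 1 point for
#' red/processed meat below the median, and 1 point for alcohol intake
#' inside a moderate window (defaults 5-15 g/day for women, 10-25 g/day for
#' men; a convention from the aMED literature, configurable in the
#' definitions file). Range 0-9.
#'
#' @inheritParams scorePdiFamily
#' @param sex 0/1 vector (0 = female) used for the alcohol window; if
#'   `NULL`, the female window is applied to everyone.
#' @return integer score per participant.
#' @export
scoreAmed <- function(foodgroups, sex = NULL, defs = loadIndexDefinitions()) {
  if (nrow(foodgroups) < 2) stop("aMED requires at least 2 participants")
  total <- integer(nrow(foodgroups))
  for (comp in asComponentList(defs$amed$beneficial)) {
    v <- componentIntake(comp, foodgroups, NULL)
    total <- total + as.integer(v > median(v))
  }
  for (comp in asComponentList(defs$amed$adverse)) {
    v <- componentIntake(comp, foodgroups, NULL)
    total <- total + as.integer(v < median(v))
  }
  alc <- defs$amed$alcohol
  v <- foodgroups[, alc$group]
  wf <- alc$window_female
  wm <- alc$window_male
  if (is.null(sex)) sex <- rep(0L, nrow(foodgroups))
  lo <- ifelse(sex == 1, wm[1], wf[1])
  hi <- ifelse(sex == 1, wm[2], wf[2])
  total + as.integer(v >= lo & v <= hi)
}

#' Percentage of the diet from plant-based foods and meat products
#'
#' Category grams over total grams, times 100, computed from unadjusted
#' group intakes.
#'
#' @param foodgroups_raw participant x group matrix of intakes in grams.
#' @param defs index definitions from [loadIndexDefinitions()].
#' @return data.frame with `plant_pct` and `meat_pct`.
#' @export
plantMeatPercent <- function(foodgroups_raw, defs = loadIndexDefinitions()) {
  tot <- rowSums(foodgroups_raw)
  if (any(tot <= 0)) stop("zero total intake for at least one participant")
  plant <- intersect(defs$plant_meat$plant, colnames(foodgroups_raw))
  meat <- intersect(defs$plant_meat$meat, colnames(foodgroups_raw))
  data.frame(
    plant_pct = 100 * rowSums(foodgroups_raw[, plant, drop = FALSE]) / tot,
    meat_pct = if (length(meat)) {
      100 * rowSums(foodgroups_raw[, meat, drop = FALSE]) / tot
    } else {
      0
    }
  )
}

#' Load the pooled-cohort-equation coefficient set
#'
#' @param path JSON file with sex- and race-specific terms, mean linear
#'   predictor and baseline survival; default is the published ACC/AHA set
#'   shipped with the package.
#' @return nested list keyed by `<race_group>_<sex>` stratum.
#' @export
loadAscvdCoefficients <- function(path = system.file(
                                    "extdata", "ascvd_coefficients.json",
                                    package = "metadiet")) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}

#' 10-year ASCVD risk by the pooled cohort equations
#'
#' Computes `risk = 1 - S0 ^ exp(L - mean_L)` where `L` is the stratum
#' linear predictor built from log-transformed age, total and HDL
#' cholesterol, systolic blood pressure (split by antihypertensive
#' treatment), smoking and diabetes status, with the stratum interaction
#' terms. Participants aged 80 or over are ineligible.
#'
#' @param profile data.frame with columns `age_years`, `sex` (0 female /
#'   1 male), `race_group` (`"white"` or `"african_american"`),
#'   `total_chol_mgdl`, `hdl_mgdl`, `sbp_mmhg`, `on_htn_meds`, `diabetes`,
#'   `smoker`.
#' @param coeffs coefficient set from [loadAscvdCoefficients()].
#' @return risk in `[0, 1]` per row.
#' @export
ascvdRisk <- function(profile, coeffs = loadAscvdCoefficients()) {
  if (any(profile$age_years >= 80)) {
    stop("ASCVD risk is defined for ages below 80; filter first")
  }
  if (any(profile$total_chol_mgdl <= 0) || any(profile$hdl_mgdl <= 0) ||
      any(profile$sbp_mmhg <= 0)) {
    stop("lipid and blood-pressure values must be positive")
  }
  out <- numeric(nrow(profile))
  for (i in seq_len(nrow(profile))) {
    p <- profile[i, ]
    stratum <- paste0(p$race_group, "_", ifelse(p$sex == 1, "male", "female"))
    cs <- coeffs[[stratum]]
    if (is.null(cs)) stop("no coefficient stratum for ", stratum)
    treated <- p$on_htn_meds == 1
    vals <- c(
      ln_age = log(p$age_years),
      ln_age_sq = log(p$age_years)^2,
      ln_tc = log(p$total_chol_mgdl),
      ln_age_x_ln_tc = log(p$age_years) * log(p$total_chol_mgdl),
      ln_hdl = log(p$hdl_mgdl),
      ln_age_x_ln_hdl = log(p$age_years) * log(p$hdl_mgdl),
      ln_sbp_treated = if (treated) log(p$sbp_mmhg) else 0,
      ln_sbp_untreated = if (treated) 0 else log(p$sbp_mmhg),
      ln_age_x_ln_sbp_treated =
        if (treated) log(p$age_years) * log(p$sbp_mmhg) else 0,
      ln_age_x_ln_sbp_untreated =
        if (treated) 0 else log(p$age_years) * log(p$sbp_mmhg),
      smoker = as.numeric(p$smoker),
      ln_age_x_smoker = log(p$age_years) * as.numeric(p$smoker),
      diabetes = as.numeric(p$diabetes)
    )
    terms <- unlist(cs$terms)
    lp <- sum(terms * vals[names(terms)])
    out[i] <- 1 - cs$baseline_survival^exp(lp - cs$mean_lp)
  }
  out
}

#' Compute all seven a priori dietary indices for a prepared cohort
#'
#' @param foodgroups energy-adjusted group intake matrix (quintile-based
#'   indices are computed on this scale).
#' @param foodgroups_raw unadjusted gram intakes (plant/meat percentages).
#' @param nutrients nutrient table (sodium for DASH).
#' @param sex 0/1 vector for the aMED alcohol window.
#' @param defs index definitions.
#' @return data.frame with columns `PDI`, `hPDI`, `uPDI`, `DASH`, `aMED`,
#'   `plant_pct`, `meat_pct`.
#' @export
scoreAllIndices <- function(foodgroups, foodgroups_raw, nutrients = NULL,
                            sex = NULL, defs = loadIndexDefinitions()) {
  pm <- plantMeatPercent(foodgroups_raw, defs)
  data.frame(
    PDI = scorePdiFamily(foodgroups, "PDI", defs),
    hPDI = scorePdiFamily(foodgroups, "hPDI", defs),
    uPDI = scorePdiFamily(foodgroups, "uPDI", defs),
    DASH = scoreDash(foodgroups, nutrients, defs),
    aMED = scoreAmed(foodgroups, sex, defs),
    plant_pct = pm$plant_pct,
    meat_pct = pm$meat_pct,
    row.names = rownames(foodgroups)
  )
}
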