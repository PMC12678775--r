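#' Exclude FFQ records with too many unanswered line items
#'
#' A record is retained if and only if its number of unanswered line items
#' (`NA` cells) does not exceed `max_unanswered`; the rule is strict, so a
#' record with exactly `max_unanswered` unanswered items is kept.
#'
#' @param ffq participant x line-item intake matrix; `NA` marks unanswered.
#' @param max_unanswered maximum tolerated number of unanswered items.
#' @return list with `ffq` (retained rows), `kept` (logical) and
#'   `exclusions` (data.frame of dropped ids with reasons).
#' @export
excludeIncomplete <- function(ffq, max_unanswered = 10) {
  n_missing <- rowSums(is.na(ffq))
  keep <- n_missing <= max_unanswered
  ids <- if (is.null(rownames(ffq))) as.character(seq_len(nrow(ffq)))
         else rownames(ffq)
  exclusions <- data.frame(
    participant_id = ids[!keep],
    n_unanswered = unname(n_missing[!keep]),
    reason = rep("incomplete_ffq", sum(!keep)),
    stringsAsFactors = FALSE
  )
  list(ffq = ffq[keep, , drop = FALSE], kept = keep, exclusions = exclusions)
}

#' Basal metabolic rate by the Harris-Benedict equation
#'
#' Original (1919) coefficients: females
#' `655.1 + 9.563 W + 1.850 H - 4.676 A`, males
#' `66.47 + 13.75 W + 5.003 H - 6.755 A`, with weight W in kg, height H in
#' cm and age A in years. Coefficients are arguments so the revised
#' (Roza-Shetty) form can be substituted.
#'
#' @param sex 0/"female" for female, 1/"male" for male (vectorised).
#' @param weight_kg,height_cm,age_years anthropometrics (positive).
#' @param coef_female,coef_male equation coefficients
#'   (intercept, weight, height, age).
#' @return kcal/day vector.
#' @export
harrisBenedictBmr <- function(sex, weight_kg, height_cm, age_years,
                              coef_female = c(655.1, 9.563, 1.850, -4.676),
                              coef_male = c(66.47, 13.75, 5.003, -6.755)) {
  if (any(weight_kg <= 0) || any(height_cm <= 0)) {
    stop("weight and height must be positive")
  }
  male <- sex %in% c(1, "1", "male", "M")
  X <- cbind(1, weight_kg, height_cm, age_years)
  ifelse(male, as.numeric(X %*% coef_male), as.numeric(X %*% coef_female))
}

#' Exclude implausible reporters by the energy-to-BMR ratio
#'
#' Computes the ratio of reported total energy intake to basal metabolic
#' rate over the supplied records and drops records whose ratio lies more
#' than `sd_mult` standard deviations from the mean. Statistics are computed
#' on the records that survived earlier filters (the caller passes only
#' those).
#'
#' @param energy_kcal reported energy intakes.
#' @param bmr basal metabolic rates, same length.
#' @param sd_mult standard-deviation multiplier (default 2).
#' @param use_log compute the filter on `log(ratio)` instead of the ratio.
#' @return list with `kept` logical vector, `ratio`, `mean` and `sd` used.
#' @export
excludeEnergyOutliers <- function(energy_kcal, bmr, sd_mult = 2,
                                  use_log = FALSE) {
  stopifnot(length(energy_kcal) == length(bmr))
  r <- energy_kcal / bmr
  if (use_log) r <- log(r)
  if (length(r) < 3) {
    warning("fewer than 3 records; no energy-ratio exclusion applied")
    return(list(kept = rep(TRUE, length(r)), ratio = r,
                mean = mean(r), sd = NA_real_))
  }
  m <- mean(r)
  s <- sd(r)
  kept <- if (!is.finite(s) || s == 0) {
    rep(TRUE, length(r))
  } else {
    abs(r - m) <= sd_mult * s
  }
  kept[is.na(kept)] <- TRUE
  list(kept = kept, ratio = r, mean = m, sd = s)
}

#' Aggregate FFQ line items into food and beverage groups
#'
#' Sums the member line items of each group. Unanswered items (`NA`) in
#' retained records are treated as zero intake; every line item must map to
#' at most one group.
#'
#' @param ffq participant x line-item intake matrix.
#' @param mapping data.frame with columns `item` and `group`.
#' @return participant x group intake matrix (g/day), no missing cells.
#' @export
aggregateFoodGroups <- function(ffq, mapping = defaultFoodGroupMapping()) {
  if (anyDuplicated(mapping$item)) {
    dup <- mapping$item[duplicated(mapping$item)][1]
    stop("line item mapped to more than one group: ", dup)
  }
  groups <- unique(mapping$group)
  out <- matrix(0, nrow(ffq), length(groups),
                dimnames = list(rownames(ffq), groups))
  for (g in groups) {
    items <- intersect(mapping$item[mapping$group == g], colnames(ffq))
    out[, g] <- rowSums(ffq[, items, drop = FALSE], na.rm = TRUE)
  }
  out
}

#' Energy adjustment by the residual method
#'
#' Replaces an intake with the residual of its least-squares regression on
#' total energy plus the sample mean intake, so adjusted values stay on an
#' interpretable scale and are uncorrelated with energy.
#'
#' @param intake intake vector.
#' @param energy total energy intakes, same length (>= 3).
#' @return adjusted intake vector.
#' @export
energyAdjustResidual <- function(intake, energy) {
  stopifnot(length(intake) == length(energy), length(intake) >= 3)
  if (sd(energy) == 0) {
    warning("constant energy; returning mean-centred intake plus mean")
    return(intake - mean(intake) + mean(intake))
  }
  fit <- lm(intake ~ energy)
  unname(residuals(fit)) + mean(intake)
}

#' Rank-based inverse normal transformation
#'
#' Maps values through `qnorm((rank - c) / (n - 2c + 1))` with the Blom
#' offset `c = 3/8` by default; ties receive average ranks. Missing values
#' are ignored and returned as `NA`.
#'
#' @param x numeric vector with at least 2 distinct non-missing values.
#' @param offset rank offset constant (Blom: 3/8).
#' @return normal scores, monotone in `x`, mean approximately 0.
#' @export
inverseRankTransform <- function(x, offset = 3 / 8) {
  obs <- !is.na(x)
  v <- x[obs]
  if (length(unique(v)) < 2) {
    stop("inverse rank transform requires at least 2 distinct values")
  }
  n <- length(v)
  sc <- qnorm((rank(v, ties.method = "average") - offset) /
                (n - 2 * offset + 1))
  out <- rep(NA_real_, length(x))
  out[obs] <- sc
  out
}

#' Run the full FFQ preparation pipeline on a cohort
#'
#' Applies, in fixed order: the incompleteness filter, the energy-to-BMR
#' ratio filter (statistics computed on the survivors of the first filter),
#' aggregation into food groups, and energy adjustment of group intakes by
#' the residual method within the cohort.
#'
#' @param bundle a [CohortBundle-class].
#' @param mapping line-item mapping, see [aggregateFoodGroups()].
#' @param max_unanswered,sd_mult filter parameters.
#' @return list with `foodgroups` (energy-adjusted group matrix),
#'   `foodgroups_raw` (grams), `kept_ids`, `exclusions` and `energy_kcal`
#'   for the retained participants.
#' @export
prepareDiet <- function(bundle, mapping = defaultFoodGroupMapping(),
                        max_unanswered = 10, sd_mult = 2) {
  p <- participants(bundle)
  step1 <- excludeIncomplete(ffqIntakes(bundle), max_unanswered)
  keep1 <- step1$kept
  energy <- nutrientTotals(bundle)$energy_kcal[keep1]
  bmr <- harrisBenedictBmr(p$sex[keep1], p$weight_kg[keep1],
                           p$height_cm[keep1], p$age[keep1])
  step2 <- excludeEnergyOutliers(energy, bmr, sd_mult)
  ids <- p$participant_id[keep1][step2$kept]
  ffq <- step1$ffq[step2$kept, , drop = FALSE]
  raw <- aggregateFoodGroups(ffq, mapping)
  energy_kept <- energy[step2$kept]
  adj <- apply(raw, 2, energyAdjustResidual, energy = energy_kept)
  rownames(adj) <- ids
  exclusions <- rbind(
    step1$exclusions,
    data.frame(
      participant_id = p$participant_id[keep1][!step2$kept],
      n_unanswered = NA_integer_, reason = "energy_ratio_outlier",
      stringsAsFactors = FALSE
    )
  )
  list(foodgroups = adj, foodgroups_raw = raw, kept_ids = ids,
       exclusions = exclusions, energy_kcal = energy_kept)
}
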