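#' Enumerate mutually associated exposure-mediator-outcome trios
#'
#' A trio (food group, metabolite, species) qualifies when all three
#' pairwise association edges pass their respective thresholds:
#' food-metabolite at the Meff-Bonferroni threshold, food-species at
#' FDR < 0.1, metabolite-species at the stricter FDR < 0.01. Each
#' qualifying triple is emitted in both causal orderings (metabolite as
#' mediator with species as outcome, and vice versa).
#'
#' @param food_met meta-analysis table (from [metaAnalyse()]) of food-group
#'   to metabolite associations; rows with `passes_threshold` qualify.
#' @param food_species meta table of food-group to species associations;
#'   rows with `q < fdr_food_species` qualify.
#' @param met_species meta table of metabolite to species associations
#'   (exposure = metabolite, outcome = species); rows with
#'   `q < fdr_met_species` qualify.
#' @param fdr_food_species,fdr_met_species FDR thresholds (0.1 and 0.01).
#' @return data.frame with `exposure`, `mediator`, `outcome`,
#'   `mediator_type`.
#' @export
enumerateTrios <- function(food_met, food_species, met_species,
                           fdr_food_species = 0.1, fdr_met_species = 0.01) {
  fm <- food_met[which(food_met$passes_threshold), c("exposure", "outcome")]
  names(fm) <- c("food", "metabolite")
  fs <- food_species[which(food_species$q < fdr_food_species),
                     c("exposure", "outcome")]
  names(fs) <- c("food", "species")
  ms <- met_species[which(met_species$q < fdr_met_species),
                    c("exposure", "outcome")]
  names(ms) <- c("metabolite", "species")
  if (!nrow(fm) || !nrow(fs) || !nrow(ms)) {
    return(data.frame(exposure = character(), mediator = character(),
                      outcome = character(), mediator_type = character(),
                      stringsAsFactors = FALSE))
  }
  trios <- merge(merge(fm, fs, by = "food"), ms,
                 by = c("metabolite", "species"))
  rbind(
    data.frame(exposure = trios$food, mediator = trios$metabolite,
               outcome = trios$species, mediator_type = "metabolite",
               stringsAsFactors = FALSE),
    data.frame(exposure = trios$food, mediator = trios$species,
               outcome = trios$metabolite, mediator_type = "species",
               stringsAsFactors = FALSE)
  )
}

#' Causal mediation analysis for one trio
#'
#' Quasi-Bayesian product-of-coefficients mediation for the linear
#' continuous-continuous case without exposure-mediator interaction. Two
#' family random-intercept models are fitted by REML:
#' `mediator ~ exposure + covariates` and
#' `outcome ~ exposure + mediator + covariates`. Coefficient vectors are
#' drawn `n_sim` times from each model's asymptotic normal sampling
#' distribution; per draw, ACME = a*b, ADE = c', and the total effect is
#' their sum (exact additivity by construction). Two-sided p values are
#' taken from the draw distributions.
#'
#' @param exposure,mediator,outcome numeric vectors (analysis scales:
#'   inverse-rank exposures, inverse-normal metabolites, CLR species).
#' @param covariates standardised covariate matrix or `NULL`.
#' @param family family id per sample (random intercept).
#' @param n_sim number of quasi-Bayesian draws (default 1000).
#' @param seed integer seed.
#' @return list with `acme`, `ade`, `total`, `prop_mediated` (point
#'   estimates), `prop_mediated_clipped` (reported value clipped to
#'   `[-1, 2]`), `p_acme`, `p_ade`, `p_total`, `ci_acme`, `ci_ade`,
#'   `draws`.
#' @export
mediate <- function(exposure, mediator, outcome, covariates = NULL, family,
                    n_sim = 1000, seed = 1L) {
  if (identical(mediator, outcome)) {
    stop("mediator and outcome must differ")
  }
  set.seed(seed)
  ord <- orderByFamily(family)
  cov_m <- if (is.null(covariates)) NULL else as.matrix(covariates)
  X1 <- cbind(intercept = 1, exposure = exposure, cov_m)[ord$order, ,
                                                         drop = FALSE]
  X2 <- cbind(intercept = 1, exposure = exposure, mediator = mediator,
              cov_m)[ord$order, , drop = FALSE]
  fit1 <- cpp_lmm_fit(X1, mediator[ord$order], ord$sizes)
  fit2 <- cpp_lmm_fit(X2, outcome[ord$order], ord$sizes)
  th1 <- MASS::mvrnorm(n_sim, fit1$beta, fit1$cov)
  th2 <- MASS::mvrnorm(n_sim, fit2$beta, fit2$cov)
  a <- th1[, 2] # exposure -> mediator
  b <- th2[, 3] # mediator -> outcome given exposure
  cp <- th2[, 2] # direct effect
  acme <- a * b
  ade <- cp
  total <- acme + ade
  two_sided <- function(draws) {
    p <- 2 * min(mean(draws <= 0), mean(draws >= 0))
    max(min(p, 1), 2 / length(draws))
  }
  prop <- mean(acme) / mean(total)
  list(
    acme = mean(acme), ade = mean(ade), total = mean(total),
    prop_mediated = prop,
    prop_mediated_clipped = min(max(prop, -1), 2),
    p_acme = two_sided(acme), p_ade = two_sided(ade),
    p_total = two_sided(total),
    ci_acme = quantile(acme, c(0.025, 0.975), names = FALSE),
    ci_ade = quantile(ade, c(0.025, 0.975), names = FALSE),
    a = fit1$beta[2], b = fit2$beta[3], c_prime = fit2$beta[2],
    draws = data.frame(acme = acme, ade = ade, total = total)
  )
}

#' Mediation screen over a trio list
#'
#' Runs [mediate()] for every row of a trio table against the supplied data
#' matrices and collects the headline statistics.
#'
#' @param trios data.frame from [enumerateTrios()].
#' @param exposures,mediator_mats named access: `exposures` is the food
#'   group matrix; `mediator_mats` is a list with elements `metabolite` and
#'   `species` giving the matrices in which mediators/outcomes are looked
#'   up by column name.
#' @param covariates,family passed to [mediate()].
#' @param n_sim,seed resampling controls.
#' @return data.frame, one row per trio.
#' @export
mediationScan <- function(trios, exposures, mediator_mats, covariates = NULL,
                          family, n_sim = 1000, seed = 1L) {
  lookup <- function(name) {
    for (m in mediator_mats) if (name %in% colnames(m)) return(m[, name])
    stop("variable not found in any matrix: ", name)
  }
  rows <- lapply(seq_len(nrow(trios)), function(i) {
    res <- mediate(
      exposure = exposures[, trios$exposure[i]],
      mediator = lookup(trios$mediator[i]),
      outcome = lookup(trios$outcome[i]),
      covariates = covariates, family = family,
      n_sim = n_sim, seed = seed + i
    )
    data.frame(
      trios[i, c("exposure", "mediator", "outcome", "mediator_type")],
      acme = res$acme, ade = res$ade, total = res$total,
      prop_mediated = res$prop_mediated,
      prop_mediated_clipped = res$prop_mediated_clipped,
      p_acme = res$p_acme, p_ade = res$p_ade, p_total = res$p_total,
      acme_lo = res$ci_acme[1], acme_hi = res$ci_acme[2],
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
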