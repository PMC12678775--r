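#' Food and beverage group metadata used by the synthetic generator
#'
#' Twenty food and beverage groups with the generator's distributional
#' parameters: log-normal location/scale of daily intake (g), loading on the
#' latent plant-vs-animal dietary axis (positive = plant pole), energy
#' density (kcal/g), plant/meat category membership and the number of FFQ
#' line items belonging to each group (131 items in total).
#'
#' @return data.frame with one row per food group.
#' @export
foodGroupMeta <- function() {
  df <- data.frame(
    group = c(
      "fruits", "vegetables", "wholegrains", "refined_grains", "legumes",
      "nuts_seeds", "potatoes", "sweets_desserts",
      "sugar_sweetened_beverages", "fruit_juices", "tea_coffee",
      "vegetable_oils", "alcoholic_beverages", "red_meat", "processed_meat",
      "poultry", "fish_seafood", "eggs", "dairy", "low_fat_dairy"
    ),
    median_g = c(150, 200, 80, 100, 30, 10, 80, 50, 100, 60, 500, 15, 8,
                 40, 20, 30, 30, 20, 150, 80),
    sigma_log = c(0.7, 0.6, 0.9, 0.7, 1.0, 1.1, 0.8, 0.9, 1.2, 1.1, 0.8,
                  0.8, 1.5, 0.9, 1.0, 0.9, 1.0, 0.9, 0.8, 1.0),
    loading = c(0.45, 0.45, 0.45, -0.25, 0.40, 0.40, -0.20, -0.20, -0.25,
                0.15, 0.25, 0.30, 0.10, -0.45, -0.45, -0.30, -0.20, -0.25,
                -0.25, 0.20),
    kcal_per_g = c(0.5, 0.3, 2.5, 2.6, 1.2, 6.0, 0.9, 4.0, 0.4, 0.45, 0.05,
                   9.0, 7.0, 2.2, 3.0, 1.6, 1.5, 1.5, 0.7, 0.5),
    plant = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE,
              TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
              FALSE),
    meat = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
             FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, FALSE,
             FALSE, FALSE),
    n_items = c(12, 18, 8, 8, 5, 4, 4, 10, 4, 3, 4, 4, 6, 7, 6, 4, 7, 3,
                10, 4),
    stringsAsFactors = FALSE
  )
  stopifnot(sum(df$n_items) == 131)
  df
}

#' Default FFQ line-item to food-group mapping
#'
#' Deterministic mapping of the 131 synthetic FFQ line items onto the 20
#' food and beverage groups of [foodGroupMeta()]. Each item belongs to
#' exactly one group.
#'
#' @return data.frame with columns `item` and `group`.
#' @export
defaultFoodGroupMapping <- function() {
  meta <- foodGroupMeta()
  items <- sprintf("item_%03d", seq_len(sum(meta$n_items)))
  data.frame(
    item = items,
    group = rep(meta$group, meta$n_items),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic twin-cohort generator
#'
#' Defaults mirror the structure of the emulated study: two cohorts with
#' twin fractions matching the discovery cohort's MZ:DZ:unpaired split,
#' 20 food groups, 131 FFQ line items, and a faecal metabolome / species
#' panel of realistic dimension. Planted effect sizes are expressed as
#' standardised slopes on the inverse-normal analysis scales.
#'
#' @param n_discovery,n_replication cohort sizes.
#' @param frac_mz_pairs,frac_dz_pairs fraction of individuals belonging to
#'   monozygotic / dizygotic twin pairs (remainder unpaired).
#' @param n_food_groups number of food groups (must be 20, the configured
#'   group set).
#' @param n_metabolites,n_species panel sizes.
#' @param n_informative_metabolites number of metabolites carrying planted
#'   dietary signal.
#' @param effect_size_beta standardised diet-to-metabolite slope for planted
#'   effects.
#' @param family_icc share of the residual metabolite variance contributed by
#'   the family random effect.
#' @param missing_rate_range per-metabolite below-detection (missingness)
#'   fraction is drawn uniformly from this interval.
#' @param missing_mechanism `"censor"` (intensity-dependent, default) or
#'   `"mcar"`.
#' @param diet_family_cor within-pair correlation of the latent dietary axis.
#' @param species_link_gamma slope of planted metabolite-to-species links on
#'   the log-abundance scale.
#' @param mediation_trios data.frame with columns `exposure` (food group),
#'   `mediator_type` (`"metabolite"` or `"species"`), `a`, `b`, `c_prime`;
#'   `NULL` plants three default trios with a = 0.5, b = 0.4, c' = 0.3.
#' @param n_run_days number of metabolomics run days (round-robin assignment).
#' @param seed integer seed; the generator is deterministic given the seed.
#'
#' @return a validated list of class `"SynthConfig"`.
#' @export
synthConfig <- function(n_discovery = 1810, n_replication = 837,
                        frac_mz_pairs = 0.452, frac_dz_pairs = 0.287,
                        n_food_groups = 20, n_metabolites = 650,
                        n_species = 567, n_informative_metabolites = 54,
                        effect_size_beta = 0.7, family_icc = 0.3,
                        missing_rate_range = c(0, 0.35),
                        missing_mechanism = c("censor", "mcar"),
                        diet_family_cor = 0.3, species_link_gamma = 0.5,
                        mediation_trios = NULL, n_run_days = 8, seed = 1L) {
  missing_mechanism <- match.arg(missing_mechanism)
  cfg <- list(
    n_discovery = as.integer(n_discovery),
    n_replication = as.integer(n_replication),
    frac_mz_pairs = frac_mz_pairs, frac_dz_pairs = frac_dz_pairs,
    n_food_groups = as.integer(n_food_groups),
    n_metabolites = as.integer(n_metabolites),
    n_species = as.integer(n_species),
    n_informative_metabolites = as.integer(n_informative_metabolites),
    effect_size_beta = effect_size_beta, family_icc = family_icc,
    missing_rate_range = missing_rate_range,
    missing_mechanism = missing_mechanism,
    diet_family_cor = diet_family_cor,
    species_link_gamma = species_link_gamma,
    mediation_trios = mediation_trios,
    n_run_days = as.integer(n_run_days), seed = as.integer(seed)
  )
  props <- c(frac_mz_pairs = frac_mz_pairs, frac_dz_pairs = frac_dz_pairs,
             family_icc = family_icc, diet_family_cor = diet_family_cor)
  for (nm in names(props)) {
    if (!is.finite(props[[nm]]) || props[[nm]] < 0 || props[[nm]] > 1) {
      stop("invalid SynthConfig field: ", nm, " must lie in [0, 1]")
    }
  }
  if (frac_mz_pairs + frac_dz_pairs > 1) {
    stop("invalid SynthConfig field: frac_mz_pairs + frac_dz_pairs > 1")
  }
  if (any(missing_rate_range < 0) || any(missing_rate_range > 1) ||
      missing_rate_range[1] > missing_rate_range[2]) {
    stop("invalid SynthConfig field: missing_rate_range")
  }
  if (cfg$n_informative_metabolites > cfg$n_metabolites) {
    stop("invalid SynthConfig field: n_informative_metabolites > n_metabolites")
  }
  if (cfg$n_food_groups != nrow(foodGroupMeta())) {
    stop("invalid SynthConfig field: n_food_groups must equal the ",
         nrow(foodGroupMeta()), " configured groups")
  }
  if (abs(effect_size_beta) >= 1) {
    stop("invalid SynthConfig field: effect_size_beta must lie in (-1, 1)")
  }
  if (!is.null(mediation_trios)) {
    need <- c("exposure", "mediator_type", "a", "b", "c_prime")
    if (!all(need %in% names(mediation_trios))) {
      stop("invalid SynthConfig field: mediation_trios must have columns ",
           paste(need, collapse = ", "))
    }
    if (!all(mediation_trios$exposure %in% foodGroupMeta()$group)) {
      stop("invalid SynthConfig field: mediation_trios references unknown ",
           "food groups")
    }
  }
  class(cfg) <- "SynthConfig"
  cfg
}

defaultMediationTrios <- function() {
  data.frame(
    exposure = c("red_meat", "nuts_seeds", "wholegrains"),
    mediator_type = c("metabolite", "metabolite", "species"),
    a = 0.5, b = 0.4, c_prime = 0.3,
    stringsAsFactors = FALSE
  )
}

# family layout: MZ pairs share the full family effect, DZ pairs half
# (effect correlation 0.5), singletons none
makeFamilies <- function(n, frac_mz, frac_dz, prefix) {
  n_mz <- 2L * floor(frac_mz * n / 2)
  n_dz <- 2L * floor(frac_dz * n / 2)
  n_up <- n - n_mz - n_dz
  zyg <- c(rep("MZ", n_mz), rep("DZ", n_dz), rep("UP", n_up))
  fam <- c(rep(seq_len(n_mz / 2), each = 2),
           n_mz / 2 + rep(seq_len(n_dz / 2), each = 2),
           n_mz / 2 + n_dz / 2 + seq_len(n_up))
  data.frame(
    participant_id = sprintf("%s_%04d", prefix, seq_len(n)),
    family_id = sprintf("%s_fam%04d", prefix, fam),
    zygosity = zyg,
    stringsAsFactors = FALSE
  )
}

# draw per-individual values of a unit-variance effect shared within
# families: MZ share fully, DZ with correlation `dz_share`, singletons i.i.d.
familyEffect <- function(fam, zyg, dz_share = 0.5) {
  n <- length(fam)
  u_fam <- rnorm(length(unique(fam)))
  names(u_fam) <- unique(fam)
  shared <- u_fam[fam]
  own <- rnorm(n)
  w <- ifelse(zyg == "MZ", 1, ifelse(zyg == "DZ", sqrt(dz_share), 0))
  as.numeric(w * shared + sqrt(1 - w^2) * own)
}

generateOneCohort <- function(name, n, cfg, item_weights, informative_map,
                              trios, mean_age, sd_age, frac_female) {
  meta <- foodGroupMeta()
  fams <- makeFamilies(n, cfg$frac_mz_pairs, cfg$frac_dz_pairs, name)

  # covariates; twins share age and (usually) sex
  fam_ids <- unique(fams$family_id)
  fam_age <- pmin(pmax(rnorm(length(fam_ids), mean_age, sd_age), 18), 95)
  fam_sex <- rbinom(length(fam_ids), 1, 1 - frac_female)
  names(fam_age) <- names(fam_sex) <- fam_ids
  age <- round(fam_age[fams$family_id], 1)
  sex <- as.integer(fam_sex[fams$family_id])
  height <- rnorm(n, ifelse(sex == 1, 177, 163), 6)
  bmi <- 25.9 + 0.6 * familyEffect(fams$family_id, fams$zygosity) +
    rnorm(n, 0, 4.5)
  bmi <- pmin(pmax(bmi, 15), 50)
  weight <- bmi * (height / 100)^2
  participants <- data.frame(
    fams,
    age = unname(age), sex = sex, bmi = round(bmi, 2),
    weight_kg = round(weight, 1), height_cm = round(height, 1),
    cohort = name, stringsAsFactors = FALSE
  )

  # latent plant-vs-animal axis with a shared family (household) component
  u <- sqrt(cfg$diet_family_cor) *
    familyEffect(fams$family_id, fams$zygosity, dz_share = 1) +
    sqrt(1 - cfg$diet_family_cor) * rnorm(n)

  # right-skewed group intakes correlated through the latent axis
  G <- nrow(meta)
  z <- matrix(rnorm(n * G), n, G)
  z <- sweep(z, 2, sqrt(1 - meta$loading^2), "*") + outer(u, meta$loading)
  intakes <- exp(sweep(sweep(z, 2, meta$sigma_log, "*"), 2,
                       log(meta$median_g), "+"))
  colnames(intakes) <- meta$group

  energy <- as.numeric(intakes %*% meta$kcal_per_g) + rnorm(n, 0, 80)
  energy <- pmax(energy, 600)
  nutrients <- data.frame(
    energy_kcal = round(energy, 1),
    protein_g = round(0.16 * energy / 4 * exp(rnorm(n, 0, 0.15)), 1),
    fat_g = round(0.35 * energy / 9 * exp(rnorm(n, 0, 0.15)), 1),
    carbohydrate_g = round(0.48 * energy / 4 * exp(rnorm(n, 0, 0.15)), 1),
    sodium_mg = round(1400 + 12 * intakes[, "processed_meat"] +
                        4 * intakes[, "refined_grains"] + rnorm(n, 0, 350), 0)
  )
  nutrients$sodium_mg <- pmax(nutrients$sodium_mg, 200)

  # split group intakes into line items by fixed weights; mark a few items
  # unanswered (small counts mostly, a small fraction exceeding the QC gate)
  mapping <- defaultFoodGroupMapping()
  ffq <- matrix(0, n, nrow(mapping),
                dimnames = list(participants$participant_id, mapping$item))
  for (g in meta$group) {
    idx <- which(mapping$group == g)
    w <- item_weights[idx]
    ffq[, idx] <- intakes[, g] %o% (w / sum(w))
  }
  n_unanswered <- rbinom(n, 4, 0.25) +
    ifelse(runif(n) < 0.02, sample(11:25, n, replace = TRUE), 0L)
  for (i in which(n_unanswered > 0)) {
    ffq[i, sample(ncol(ffq), min(n_unanswered[i], ncol(ffq)))] <- NA
  }

  # exposure scale actually used by the analysis: inverse-normal scores of
  # the energy-adjusted group intakes, computed on the FFQ-QC survivors
  # from answered items, exactly as the diet-preparation stage will
  # reconstruct them (planted effects live on this scale); participants the
  # QC will exclude carry the full-cohort approximation instead
  x_adj <- apply(intakes, 2, function(v) {
    inverseRankTransform(energyAdjustResidual(v, energy))
  })
  keep1 <- rowSums(is.na(ffq)) <= 10
  if (sum(keep1) >= 10) {
    bmr <- harrisBenedictBmr(sex[keep1], weight[keep1], height[keep1],
                             age[keep1])
    keep2 <- excludeEnergyOutliers(energy[keep1], bmr)$kept
    surv <- which(keep1)[keep2]
    if (length(surv) >= 10) {
      agg <- aggregateFoodGroups(ffq[surv, , drop = FALSE])
      x_surv <- apply(agg, 2, function(v) {
        inverseRankTransform(energyAdjustResidual(v, energy[surv]))
      })
      x_adj[surv, ] <- x_surv
    }
  }

  # metabolites: planted linear diet effects + family random intercept + noise
  M <- cfg$n_metabolites
  beta <- cfg$effect_size_beta
  icc <- cfg$family_icc
  met_names <- sprintf("met_%03d", seq_len(M))
  lat <- matrix(0, n, M, dimnames = list(participants$participant_id,
                                         met_names))
  for (m in seq_len(M)) {
    b_m <- 0
    x_m <- 0
    if (m <= nrow(informative_map)) {
      b_m <- beta
      x_m <- x_adj[, informative_map$food_group[m]]
    }
    res_var <- 1 - b_m^2
    fam_part <- familyEffect(fams$family_id, fams$zygosity) *
      sqrt(icc * res_var)
    lat[, m] <- b_m * x_m + fam_part + rnorm(n, 0, sqrt((1 - icc) * res_var))
  }

  # mediation trios: mediator and outcome columns are planted explicitly
  S <- cfg$n_species
  sp_names <- sprintf("sp_%03d", seq_len(S))
  trio_registry <- NULL
  sp_extra <- list() # species log-abundance shifts planted by trios
  if (nrow(trios)) {
    trio_registry <- trios
    trio_registry$mediator <- NA_character_
    trio_registry$outcome <- NA_character_
    trio_registry$true_prop_mediated <-
      with(trios, a * b / (a * b + c_prime))
    free_met <- rev(seq_len(M)) # take mediator/outcome columns from the top
    free_sp <- seq_len(S)
    for (k in seq_len(nrow(trios))) {
      x_k <- x_adj[, trios$exposure[k]]
      a <- trios$a[k]; b <- trios$b[k]; cp <- trios$c_prime[k]
      med_lat <- a * x_k +
        sqrt(max(1 - a^2, 0.05)) *
          (sqrt(icc) * familyEffect(fams$family_id, fams$zygosity) +
             sqrt(1 - icc) * rnorm(n))
      out_res <- max(1 - (b^2 + cp^2 + 2 * a * b * cp), 0.05)
      out_lat <- b * med_lat + cp * x_k +
        sqrt(out_res) *
          (sqrt(icc) * familyEffect(fams$family_id, fams$zygosity) +
             sqrt(1 - icc) * rnorm(n))
      if (trios$mediator_type[k] == "metabolite") {
        m_col <- free_met[k]
        lat[, m_col] <- med_lat
        s_col <- free_sp[S - k + 1]
        sp_extra[[sp_names[s_col]]] <- out_lat
        trio_registry$mediator[k] <- met_names[m_col]
        trio_registry$outcome[k] <- sp_names[s_col]
      } else {
        s_col <- free_sp[S - k + 1]
        sp_extra[[sp_names[s_col]]] <- med_lat
        m_col <- free_met[k]
        lat[, m_col] <- out_lat
        trio_registry$mediator[k] <- sp_names[s_col]
        trio_registry$outcome[k] <- met_names[m_col]
      }
    }
  }

  # intensities with run-day drift and below-detection censoring
  run_day <- rep(seq_len(cfg$n_run_days), length.out = n)
  drift <- matrix(exp(rnorm(cfg$n_run_days * M, 0, 0.25)), cfg$n_run_days, M)
  raw <- exp(0.8 * lat) * drift[run_day, ]
  rates <- runif(M, cfg$missing_rate_range[1], cfg$missing_rate_range[2])
  for (m in seq_len(M)) {
    if (rates[m] <= 0) next
    if (cfg$missing_mechanism == "censor") {
      # detection limits are an instrument property of each run day
      for (day in seq_len(cfg$n_run_days)) {
        rows_d <- which(run_day == day)
        if (!length(rows_d)) next
        thr <- quantile(raw[rows_d, m], rates[m], names = FALSE)
        raw[rows_d[raw[rows_d, m] < thr], m] <- NA
      }
    } else {
      raw[runif(n) < rates[m], m] <- NA
    }
  }

  # species: log-normal abundances with planted metabolite / diet links,
  # heterogeneous prevalence, then rounded counts at a random depth
  base <- matrix(rnorm(n * S, 0, 1.5), n, S,
                 dimnames = list(participants$participant_id, sp_names))
  base <- sweep(base, 2, rnorm(S, 0, 2), "+")
  n_links <- min(nrow(informative_map), S - length(sp_extra))
  link_registry <- NULL
  if (n_links > 0) {
    link_sp <- sp_names[seq_len(n_links)]
    link_met <- met_names[seq_len(n_links)]
    for (j in seq_len(n_links)) {
      base[, link_sp[j]] <- base[, link_sp[j]] +
        cfg$species_link_gamma * lat[, link_met[j]]
    }
    link_registry <- data.frame(
      metabolite = link_met, species = link_sp,
      gamma = cfg$species_link_gamma, type = "metabolite",
      stringsAsFactors = FALSE
    )
  }
  for (nm in names(sp_extra)) {
    base[, nm] <- 1.5 * sp_extra[[nm]] + rnorm(n, 0, 0.5)
  }
  prevalence_target <- runif(S, 0.02, 1)
  # species carrying planted links or mediation outcomes stay well observed
  if (n_links > 0) {
    prevalence_target[seq_len(n_links)] <-
      pmax(prevalence_target[seq_len(n_links)], 0.8)
  }
  if (length(sp_extra)) {
    prevalence_target[match(names(sp_extra), sp_names)] <- 1
  }
  base_orig <- base
  for (s in seq_len(S)) {
    thr <- quantile(base[, s], 1 - prevalence_target[s], names = FALSE)
    base[base[, s] < thr, s] <- -Inf
  }
  # every sample keeps at least its most abundant species
  empty <- which(!is.finite(apply(base, 1, max)))
  for (i in empty) {
    j <- which.max(base_orig[i, ])
    base[i, j] <- base_orig[i, j]
  }
  abund <- exp(base)
  abund <- abund / rowSums(abund)
  depth <- sample(20000:100000, n, replace = TRUE)
  counts <- round(abund * depth)

  truth <- new("TruthRegistry",
    dietMetaboliteEffects = data.frame(
      food_group = informative_map$food_group,
      metabolite = met_names[seq_len(nrow(informative_map))],
      beta = rep(beta, nrow(informative_map)), stringsAsFactors = FALSE
    ),
    metaboliteSpeciesEffects =
      if (is.null(link_registry)) {
        data.frame(metabolite = character(), species = character(),
                   gamma = numeric(), type = character())
      } else {
        link_registry
      },
    mediationParams =
      if (is.null(trio_registry)) {
        data.frame(exposure = character(), mediator = character(),
                   outcome = character(), a = numeric(), b = numeric(),
                   c_prime = numeric(), true_prop_mediated = numeric())
      } else {
        trio_registry[, c("exposure", "mediator", "outcome", "a", "b",
                          "c_prime", "true_prop_mediated")]
      },
    informativeFeatures = met_names[seq_len(nrow(informative_map))]
  )

  rownames(raw) <- participants$participant_id
  new("CohortBundle",
    name = name, participants = participants, ffq = ffq,
    nutrients = nutrients, metabolites = raw,
    runDay = as.integer(run_day), species = counts, truth = truth
  )
}

#' Generate a pair of synthetic twin cohorts with planted ground truth
#'
#' Simulates a "discovery" and a "replication" cohort sharing the same
#' planted effect directions: right-skewed food-group intakes correlated
#' through one latent plant-vs-animal axis, faecal metabolite intensities
#' with planted linear diet effects (on the inverse-normal analysis scale)
#' plus a family random intercept, run-day drift and below-detection
#' missingness, and compositional species abundances with planted
#' metabolite/diet links and mediation trios. Deterministic given
#' `config$seed`.
#'
#' @param config a [synthConfig()] object.
#' @return named list with `discovery` and `replication`
#'   [CohortBundle-class] objects.
#' @export
generateCohorts <- function(config = synthConfig()) {
  if (!inherits(config, "SynthConfig")) {
    stop("config must be created by synthConfig()")
  }
  set.seed(config$seed)
  meta <- foodGroupMeta()

  # informative metabolites cycle through the index component groups,
  # strongest pattern loadings first
  idx_groups <- meta$group[order(-abs(meta$loading))]
  idx_groups <- setdiff(idx_groups, c("alcoholic_beverages", "low_fat_dairy"))
  n_inf <- config$n_informative_metabolites
  informative_map <- data.frame(
    food_group = rep(idx_groups, length.out = n_inf),
    stringsAsFactors = FALSE
  )
  trios <- config$mediation_trios
  if (is.null(trios)) trios <- defaultMediationTrios()

  item_weights <- rgamma(131, shape = 2, rate = 1) + 0.1

  list(
    discovery = generateOneCohort(
      "discovery", config$n_discovery, config, item_weights,
      informative_map, trios, mean_age = 61.0, sd_age = 13.7,
      frac_female = 0.86
    ),
    replication = generateOneCohort(
      "replication", config$n_replication, config, item_weights,
      informative_map, trios, mean_age = 46.3, sd_age = 11.6,
      frac_female = 0.74
    )
  )
}

#' Simulate ASCVD risk-factor inputs for a participant table
#'
#' Draws plausible lipid, blood-pressure and binary risk-factor values for
#' each participant, for use with [ascvdRisk()]. Ages are taken from the
#' participant table; the downstream eligibility rule restricts risk
#' calculation to ages below 80.
#'
#' @param participants participant data.frame with `participant_id`, `age`
#'   and `sex` columns.
#' @param seed integer seed.
#' @return data.frame of risk-factor profiles, one row per participant.
#' @export
generateAscvdInputs <- function(participants, seed = 1L) {
  set.seed(seed)
  n <- nrow(participants)
  if (n == 0) {
    return(data.frame(
      participant_id = character(), age_years = numeric(), sex = integer(),
      race_group = character(), total_chol_mgdl = numeric(),
      hdl_mgdl = numeric(), sbp_mmhg = numeric(), on_htn_meds = integer(),
      diabetes = integer(), smoker = integer()
    ))
  }
  data.frame(
    participant_id = participants$participant_id,
    age_years = participants$age,
    sex = participants$sex,
    race_group = sample(c("white", "african_american"), n, replace = TRUE,
                        prob = c(0.9, 0.1)),
    total_chol_mgdl = pmin(pmax(rnorm(n, 200, 35), 100), 400),
    hdl_mgdl = pmin(pmax(rnorm(n, 55, 15), 20), 120),
    sbp_mmhg = pmin(pmax(rnorm(n, 125, 15), 85), 200),
    on_htn_meds = rbinom(n, 1, pmin(pmax(0.02 + 0.004 * participants$age,
                                         0), 0.8)),
    diabetes = rbinom(n, 1, pmin(pmax(0.01 + 0.002 * participants$age,
                                      0), 0.5)),
    smoker = rbinom(n, 1, 0.12),
    stringsAsFactors = FALSE
  )
}
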