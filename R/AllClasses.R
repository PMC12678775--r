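#' Registry of planted ground-truth effects in a synthetic cohort
#'
#' Records every effect planted by [generateCohorts()] so that downstream
#' analyses can be scored against a known truth: diet-to-metabolite slopes,
#' metabolite/diet-to-species links, mediation trios and the identifiers of
#' the diet-informative metabolites.
#'
#' @slot dietMetaboliteEffects data.frame with columns `food_group`,
#'   `metabolite`, `beta` (slope on the inverse-normal scale).
#' @slot metaboliteSpeciesEffects data.frame with columns `metabolite`
#'   (or `food_group`), `species`, `gamma` (slope on the log-abundance scale)
#'   and `type` (`"metabolite"` or `"diet"`).
#' @slot mediationParams data.frame with columns `exposure`, `mediator`,
#'   `outcome`, `a`, `b`, `c_prime`, `true_prop_mediated`.
#' @slot informativeFeatures character vector of metabolite identifiers that
#'   carry planted dietary signal.
#'
#' @export
setClass("TruthRegistry",
  representation(
    dietMetaboliteEffects = "data.frame",
    metaboliteSpeciesEffects = "data.frame",
    mediationParams = "data.frame",
    informativeFeatures = "character"
  )
)

setValidity("TruthRegistry", function(object) {
  mp <- object@mediationParams
  if (nrow(mp)) {
    tot <- mp$a * mp$b + mp$c_prime
    ok <- abs(tot) < 1e-12 |
      abs(mp$true_prop_mediated - (mp$a * mp$b) / tot) < 1e-8
    if (!all(ok)) {
      return("true_prop_mediated must equal a*b / (a*b + c_prime)")
    }
  }
  TRUE
})

#' Synthetic (or assembled) cohort container
#'
#' Holds one cohort's participant table, FFQ line-item intakes, nutrient
#' totals, raw metabolite intensities with run-day labels, species counts and
#' the planted-truth registry. Twin pairs share a `family_id`; run-day labels
#' partition the metabolomics samples.
#'
#' @slot name cohort label, e.g. `"discovery"`.
#' @slot participants data.frame with `participant_id`, `age`, `sex` (0 =
#'   female, 1 = male), `bmi`, `weight_kg`, `height_cm`, `family_id`,
#'   `zygosity` (`"MZ"`, `"DZ"`, `"UP"`).
#' @slot ffq participant x line-item matrix of daily intakes (g); `NA` marks
#'   an unanswered line item.
#' @slot nutrients data.frame with `energy_kcal`, `protein_g`, `fat_g`,
#'   `carbohydrate_g`, `sodium_mg`.
#' @slot metabolites participant x metabolite matrix of raw intensities with
#'   `NA` for values below the detection limit.
#' @slot runDay integer run-day label per participant sample.
#' @slot species participant x species matrix of nonnegative counts.
#' @slot truth a [TruthRegistry-class] object.
#'
#' @export
setClass("CohortBundle",
  representation(
    name = "character",
    participants = "data.frame",
    ffq = "matrix",
    nutrients = "data.frame",
    metabolites = "matrix",
    runDay = "integer",
    species = "matrix",
    truth = "TruthRegistry"
  )
)

setValidity("CohortBundle", function(object) {
  n <- nrow(object@participants)
  msg <- character()
  if (nrow(object@ffq) != n) msg <- c(msg, "ffq rows must match participants")
  if (nrow(object@metabolites) != n) {
    msg <- c(msg, "metabolite rows must match participants")
  }
  if (length(object@runDay) != n) {
    msg <- c(msg, "runDay must have one label per participant")
  }
  if (nrow(object@species) != n) {
    msg <- c(msg, "species rows must match participants")
  }
  if (any(object@species < 0)) msg <- c(msg, "species counts must be >= 0")
  tab <- table(object@participants$family_id)
  zyg <- object@participants$zygosity
  if (any(zyg %in% c("MZ", "DZ"))) {
    paired <- object@participants$family_id[zyg %in% c("MZ", "DZ")]
    if (any(tab[as.character(unique(paired))] != 2)) {
      msg <- c(msg, "twin pairs must share a family_id of size 2")
    }
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn CohortBundle participant table accessor
#' @param object,x a `CohortBundle`
#' @export
setGeneric("participants", function(object) standardGeneric("participants"))

#' @export
setMethod("participants", "CohortBundle", function(object) object@participants)

#' @describeIn CohortBundle FFQ line-item intake matrix (g/day)
#' @export
setGeneric("ffqIntakes", function(object) standardGeneric("ffqIntakes"))

#' @export
setMethod("ffqIntakes", "CohortBundle", function(object) object@ffq)

#' @describeIn CohortBundle nutrient totals table
#' @export
setGeneric("nutrientTotals", function(object) standardGeneric("nutrientTotals"))

#' @export
setMethod("nutrientTotals", "CohortBundle", function(object) object@nutrients)

#' @describeIn CohortBundle raw metabolite intensity matrix
#' @export
setGeneric("metaboliteIntensities",
           function(object) standardGeneric("metaboliteIntensities"))

#' @export
setMethod("metaboliteIntensities", "CohortBundle",
          function(object) object@metabolites)

#' @describeIn CohortBundle run-day labels
#' @export
setGeneric("runDays", function(object) standardGeneric("runDays"))

#' @export
setMethod("runDays", "CohortBundle", function(object) object@runDay)

#' @describeIn CohortBundle species count matrix
#' @export
setGeneric("speciesCounts", function(object) standardGeneric("speciesCounts"))

#' @export
setMethod("speciesCounts", "CohortBundle", function(object) object@species)

#' @describeIn CohortBundle planted-truth registry
#' @export
setGeneric("truthRegistry", function(object) standardGeneric("truthRegistry"))

#' @export
setMethod("truthRegistry", "CohortBundle", function(object) object@truth)

#' @export
setMethod("show", "CohortBundle", function(object) {
  p <- object@participants
  cat("CohortBundle \"", object@name, "\"\n", sep = "")
  cat("  participants: ", nrow(p), " (MZ ", sum(p$zygosity == "MZ"),
      ", DZ ", sum(p$zygosity == "DZ"),
      ", unpaired ", sum(p$zygosity == "UP"), ")\n", sep = "")
  cat("  ffq line items: ", ncol(object@ffq),
      "; metabolites: ", ncol(object@metabolites),
      "; species: ", ncol(object@species), "\n", sep = "")
  cat("  run days: ", length(unique(object@runDay)),
      "; planted diet-metabolite effects: ",
      nrow(object@truth@dietMetaboliteEffects), "\n", sep = "")
  invisible(object)
})

#' @export
setMethod("show", "TruthRegistry", function(object) {
  cat("TruthRegistry:",
      nrow(object@dietMetaboliteEffects), "diet-metabolite effects,",
      nrow(object@metaboliteSpeciesEffects), "species links,",
      nrow(object@mediationParams), "mediation trios\n")
  invisible(object)
})
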