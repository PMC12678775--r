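#' Write a cohort bundle to plain-text files
#'
#' Writes `participants.tsv`, `ffq.tsv`, `nutrients.tsv`,
#' `metabolites.tsv` (with a `run_day` column, `NA` for missing),
#' `species.tsv` and `truth.json` into a directory.
#'
#' @param bundle a [CohortBundle-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
writeCohortBundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, file) {
    write.table(x, file.path(dir, file), sep = "\t", quote = FALSE,
                row.names = FALSE, na = "NA")
  }
  wt(participants(bundle), "participants.tsv")
  wt(data.frame(participant_id = rownames(ffqIntakes(bundle)),
                ffqIntakes(bundle), check.names = FALSE), "ffq.tsv")
  wt(data.frame(participant_id = participants(bundle)$participant_id,
                nutrientTotals(bundle)), "nutrients.tsv")
  wt(data.frame(participant_id = rownames(metaboliteIntensities(bundle)),
                run_day = runDays(bundle),
                metaboliteIntensities(bundle), check.names = FALSE),
     "metabolites.tsv")
  wt(data.frame(participant_id = rownames(speciesCounts(bundle)),
                speciesCounts(bundle), check.names = FALSE), "species.tsv")
  tr <- truthRegistry(bundle)
  jsonlite::write_json(
    list(
      diet_metabolite_effects = tr@dietMetaboliteEffects,
      metabolite_species_effects = tr@metaboliteSpeciesEffects,
      mediation_params = tr@mediationParams,
      informative_features = tr@informativeFeatures
    ),
    file.path(dir, "truth.json"), dataframe = "rows", auto_unbox = TRUE,
    digits = NA
  )
  invisible(dir)
}

#' Read a cohort bundle written by [writeCohortBundle()]
#'
#' @param dir directory containing the bundle files.
#' @param name cohort label for the reconstructed bundle.
#' @return a [CohortBundle-class].
#' @export
readCohortBundle <- function(dir, name = basename(dir)) {
  rd <- function(file) {
    read.delim(file.path(dir, file), check.names = FALSE,
               stringsAsFactors = FALSE)
  }
  part <- rd("participants.tsv")
  ffq <- rd("ffq.tsv")
  met <- rd("metabolites.tsv")
  sp <- rd("species.tsv")
  nut <- rd("nutrients.tsv")
  tr <- jsonlite::fromJSON(file.path(dir, "truth.json"),
                           simplifyVector = TRUE)
  as_df <- function(x, cols) {
    if (is.null(x) || !length(x)) {
      as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
    } else {
      as.data.frame(x)
    }
  }
  mat <- function(df, drop_cols) {
    m <- as.matrix(df[, setdiff(colnames(df), drop_cols), drop = FALSE])
    rownames(m) <- df$participant_id
    m
  }
  truth <- new("TruthRegistry",
    dietMetaboliteEffects = as_df(tr$diet_metabolite_effects,
                                  c("food_group", "metabolite", "beta")),
    metaboliteSpeciesEffects = as_df(tr$metabolite_species_effects,
                                     c("metabolite", "species", "gamma",
                                       "type")),
    mediationParams = as_df(tr$mediation_params,
                            c("exposure", "mediator", "outcome", "a", "b",
                              "c_prime", "true_prop_mediated")),
    informativeFeatures = as.character(tr$informative_features)
  )
  new("CohortBundle",
    name = name, participants = part,
    ffq = mat(ffq, "participant_id"),
    nutrients = nut[, setdiff(colnames(nut), "participant_id")],
    metabolites = mat(met, c("participant_id", "run_day")),
    runDay = as.integer(met$run_day),
    species = mat(sp, "participant_id"),
    truth = truth
  )
}

#' Pipeline configuration
#'
#' @param synth a [synthConfig()] for the simulation stage.
#' @param out_dir output directory for stage TSVs and the run manifest.
#' @param stages character vector of stages to run, a subset of
#'   `c("simulate", "dietprep", "score", "omicsprep", "predict", "assoc",
#'   "multivar", "mediate")` in that order.
#' @param predict_targets index columns to model in the predict stage.
#' @param alpha family-wise level for the Meff-Bonferroni threshold.
#' @param fdr_food_species,fdr_met_species trio FDR thresholds.
#' @param n_perm PERMANOVA permutations.
#' @param n_top_permanova number of top meta-associated metabolites taken
#'   to PERMANOVA.
#' @param grid optional hyperparameter grid override for the predict stage.
#' @param boruta_iter,num_trees,repeats,n_boot,n_sim workload knobs.
#' @param seed master seed; stage seeds are derived from it.
#' @return list of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(synth = synthConfig(), out_dir = tempfile("metadiet_"),
                           stages = c("simulate", "dietprep", "score",
                                      "omicsprep", "predict", "assoc",
                                      "multivar", "mediate"),
                           predict_targets = "DASH", alpha = 0.05,
                           fdr_food_species = 0.1, fdr_met_species = 0.01,
                           n_perm = 999, n_top_permanova = 5, grid = NULL,
                           boruta_iter = 100, num_trees = 300, repeats = 2,
                           n_boot = 1000, n_sim = 1000, seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Run the full analysis pipeline end to end
#'
#' Executes the enabled stages in their canonical order
#' (simulate, dietprep, score, omicsprep, predict, assoc, multivar,
#' mediate), writes each stage's tabular outputs under `config$out_dir`
#' and a `manifest.json` recording seeds, package version and input file
#' hashes. Later stages read the in-memory results of earlier ones; a
#' missing dependency raises an error naming the producing stage.
#'
#' @param config a [pipelineConfig()].
#' @return invisibly, a list with all stage results and the manifest.
#' @export
runPipeline <- function(config = pipelineConfig()) {
  stages <- config$stages
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  need <- function(what, producer) {
    if (is.null(res[[what]])) {
      stop("stage dependency missing: run the '", producer, "' stage first")
    }
    res[[what]]
  }
  wt <- function(x, file) {
    write.table(x, file.path(out, file), sep = "\t", quote = FALSE,
                row.names = FALSE, na = "NA")
  }

  if ("simulate" %in% stages) {
    cohorts <- generateCohorts(config$synth)
    for (nm in names(cohorts)) {
      writeCohortBundle(cohorts[[nm]], file.path(out, nm))
    }
    res$cohorts <- cohorts
  }

  if ("dietprep" %in% stages) {
    cohorts <- need("cohorts", "simulate")
    res$diet <- lapply(cohorts, prepareDiet)
    for (nm in names(res$diet)) {
      wt(data.frame(participant_id = res$diet[[nm]]$kept_ids,
                    res$diet[[nm]]$foodgroups, check.names = FALSE),
         paste0("foodgroups_", nm, ".tsv"))
    }
  }

  if ("score" %in% stages) {
    cohorts <- need("cohorts", "simulate")
    diet <- need("diet", "dietprep")
    res$indices <- lapply(names(cohorts), function(nm) {
      d <- diet[[nm]]
      p <- participants(cohorts[[nm]])
      rows <- match(d$kept_ids, p$participant_id)
      scoreAllIndices(d$foodgroups, d$foodgroups_raw,
                      nutrientTotals(cohorts[[nm]])[rows, , drop = FALSE],
                      sex = p$sex[rows])
    })
    names(res$indices) <- names(cohorts)
    for (nm in names(res$indices)) {
      wt(data.frame(participant_id = diet[[nm]]$kept_ids,
                    res$indices[[nm]]), paste0("indices_", nm, ".tsv"))
    }
  }

  if ("omicsprep" %in% stages) {
    cohorts <- need("cohorts", "simulate")
    diet <- need("diet", "dietprep")
    res$omics <- lapply(names(cohorts), function(nm) {
      prepareOmics(cohorts[[nm]], ids = diet[[nm]]$kept_ids)
    })
    names(res$omics) <- names(cohorts)
    for (nm in names(res$omics)) {
      o <- res$omics[[nm]]
      wt(data.frame(participant_id = rownames(o$metabolites),
                    shannon = o$shannon, outlier = o$outlier_flags),
         paste0("diversity_", nm, ".tsv"))
    }
  }

  analysisInputs <- function(nm) {
    cohorts <- need("cohorts", "simulate")
    diet <- need("diet", "dietprep")
    omics <- need("omics", "omicsprep")
    p <- participants(cohorts[[nm]])
    rows <- match(diet[[nm]]$kept_ids, p$participant_id)
    list(
      fg_int = apply(diet[[nm]]$foodgroups, 2, inverseRankTransform),
      met = omics[[nm]]$metabolites,
      clr = omics[[nm]]$species_clr,
      covars = standardizeCovariates(
        data.frame(age = p$age, sex = p$sex, bmi = p$bmi)[rows, ]
      ),
      family = p$family_id[rows],
      ids = diet[[nm]]$kept_ids
    )
  }

  if ("predict" %in% stages) {
    need("indices", "score")
    ai_d <- analysisInputs("discovery")
    ai_r <- analysisInputs("replication")
    p_d <- participants(res$cohorts$discovery)
    rows_d <- match(ai_d$ids, p_d$participant_id)
    covars_raw_d <- as.matrix(
      data.frame(age = p_d$age, sex = p_d$sex, bmi = p_d$bmi)[rows_d, ]
    )
    p_r <- participants(res$cohorts$replication)
    rows_r <- match(ai_r$ids, p_r$participant_id)
    covars_raw_r <- as.matrix(
      data.frame(age = p_r$age, sex = p_r$sex, bmi = p_r$bmi)[rows_r, ]
    )
    res$predict <- lapply(config$predict_targets, function(target) {
      dietPredict(
        metabolites = ai_d$met, covariates = covars_raw_d,
        scores = res$indices$discovery[[target]], families = ai_d$family,
        metabolites_val = ai_r$met[, colnames(ai_d$met), drop = FALSE],
        covariates_val = covars_raw_r,
        scores_val = res$indices$replication[[target]],
        task = "classify_quartiles", boruta_iter = config$boruta_iter,
        grid = config$grid, repeats = config$repeats,
        num_trees = config$num_trees, n_boot = config$n_boot,
        seed = config$seed
      )
    })
    names(res$predict) <- config$predict_targets
    eval_rows <- do.call(rbind, lapply(names(res$predict), function(t) {
      pr <- res$predict[[t]]
      data.frame(target = t, auc_test = pr$eval_test$estimate,
                 auc_validation = pr$eval_val$estimate,
                 auc_null = pr$null_eval_test$estimate,
                 p_delong_null = pr$delong_null$p,
                 n_selected = length(pr$selected),
                 n_panel = length(pr$rfe$subset))
    }))
    wt(eval_rows, "eval.tsv")
    res$panel <- buildPanel(lapply(res$predict, function(p) p$rfe))
    jsonlite::write_json(res$panel, file.path(out, "panel.json"))
  }

  if ("assoc" %in% stages) {
    ai <- lapply(c("discovery", "replication"), analysisInputs)
    names(ai) <- c("discovery", "replication")
    scans <- lapply(names(ai), function(nm) {
      a <- ai[[nm]]
      common <- intersect(colnames(ai$discovery$met),
                          colnames(ai$replication$met))
      associationScan(a$met[, common, drop = FALSE], a$fg_int, a$covars,
                      a$family, cohort = nm)
    })
    names(scans) <- names(ai)
    a_d <- ai$discovery
    common <- intersect(colnames(ai$discovery$met),
                        colnames(ai$replication$met))
    thr <- bonferroniThreshold(config$alpha, c(
      meff(cor(a_d$met[, common, drop = FALSE])),
      meff(cor(a_d$fg_int))
    ))
    res$assoc <- list(
      discovery = scans$discovery, replication = scans$replication,
      threshold = thr,
      meta = metaAnalyse(scans$discovery, scans$replication, thr)
    )
    wt(scans$discovery, "assoc_discovery.tsv")
    wt(scans$replication, "assoc_replication.tsv")
    wt(res$assoc$meta, "meta.tsv")

    # food group -> species and metabolite -> species scans for the trios
    sp_scans <- lapply(names(ai), function(nm) {
      a <- ai[[nm]]
      common_sp <- intersect(colnames(ai$discovery$clr),
                             colnames(ai$replication$clr))
      list(
        food = associationScan(a$clr[, common_sp, drop = FALSE], a$fg_int,
                               a$covars, a$family, cohort = nm),
        met = associationScan(a$clr[, common_sp, drop = FALSE],
                              a$met[, common, drop = FALSE],
                              a$covars, a$family, cohort = nm)
      )
    })
    names(sp_scans) <- names(ai)
    res$assoc$meta_food_species <- metaAnalyse(sp_scans$discovery$food,
                                               sp_scans$replication$food)
    res$assoc$meta_met_species <- metaAnalyse(sp_scans$discovery$met,
                                              sp_scans$replication$met)
  }

  if ("multivar" %in% stages) {
    meta <- need("assoc", "assoc")$meta
    ai <- lapply(c("discovery", "replication"), analysisInputs)
    names(ai) <- c("discovery", "replication")
    hits <- meta[meta$passes_threshold, ]
    hits <- hits[order(hits$p), ]
    top_mets <- head(unique(hits$outcome), config$n_top_permanova)
    if (!length(top_mets)) {
      top_mets <- head(unique(meta$outcome[order(meta$p)]),
                       config$n_top_permanova)
    }
    perm_rows <- lapply(top_mets, function(m) {
      per_cohort <- lapply(names(ai), function(nm) {
        a <- ai[[nm]]
        keep <- dedupTwins(a$family, seed = config$seed)
        bray <- brayCurtis(
          res$omics[[nm]]$species_rel[keep, , drop = FALSE]
        )
        pv <- permanova(bray, as.data.frame(a$covars[keep, , drop = FALSE]),
                        a$met[keep, m], n_perm = config$n_perm,
                        seed = config$seed)
        c(R2 = pv$term$R2, p = pv$term$p_perm, n = length(keep))
      })
      d <- per_cohort[[1]]
      r <- per_cohort[[2]]
      data.frame(metabolite = m, r2_discovery = d["R2"], p_discovery = d["p"],
                 r2_replication = r["R2"], p_replication = r["p"],
                 weighted_r2 = weightedR2(c(d["R2"], r["R2"]),
                                          c(d["n"], r["n"])),
                 row.names = NULL)
    })
    res$permanova <- do.call(rbind, perm_rows)
    wt(res$permanova, "permanova.tsv")
  }

  if ("mediate" %in% stages) {
    assoc <- need("assoc", "assoc")
    ai <- analysisInputs("discovery")
    trios <- enumerateTrios(assoc$meta, assoc$meta_food_species,
                            assoc$meta_met_species,
                            config$fdr_food_species, config$fdr_met_species)
    res$trios <- trios
    if (nrow(trios)) {
      # both twins retained; family structure enters as a random intercept
      res$mediation <- mediationScan(
        trios,
        exposures = ai$fg_int,
        mediator_mats = list(metabolite = ai$met, species = ai$clr),
        covariates = ai$covars,
        family = ai$family, n_sim = config$n_sim, seed = config$seed
      )
      wt(res$mediation, "mediation.tsv")
    }
  }

  files <- list.files(out, recursive = TRUE, full.names = TRUE)
  files <- files[!grepl("manifest.json", files)]
  manifest <- list(
    package_version = as.character(utils::packageVersion("metadiet")),
    seed = config$seed, stages = stages,
    timestamp = format(Sys.time(), tz = "UTC"),
    files = data.frame(
      file = sub(paste0("^", out, "/?"), "", files),
      md5 = unname(tools::md5sum(files))
    )
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  res$manifest <- manifest
  invisible(res)
}
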