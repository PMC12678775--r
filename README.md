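# metadiet

Habitual diet leaves a molecular fingerprint in stool: food-derived
compounds and their microbial transformation products. `metadiet` is an R
package for analysing that fingerprint in a two-cohort twin design. It
links food frequency questionnaire (FFQ) data, the faecal metabolome and
gut-microbiome composition through one tested pipeline: dietary-index
scoring, machine-learning prediction of diet quality and cardiovascular
risk from metabolites, mixed-model association scans with replication
meta-analysis, community-level (PERMANOVA) and set-level (enrichment,
clustering) analyses, and a causal mediation screen for
diet–microbe–metabolite trios.

It is written for computational biologists and nutritional epidemiologists
who want the full analysis chain as reusable, validated functions. Because
cohort data of this kind are access-controlled, the package also ships a
synthetic twin-cohort generator with planted ground truth
(`generateCohorts()`), so every stage can be validated by recovery of
known effects.

## The statistical core

* **Diet**: 131 FFQ line items → 20 food groups; quality control
  (more than 10 unanswered items, energy/BMR ratio beyond ±2 SD via
  Harris–Benedict); energy adjustment by the residual method; seven a
  priori indices — PDI/hPDI/uPDI (quintile sums, range 18–90), DASH
  (8 components, 8–40), aMED (median-based, 0–9), plant% and meat% — and
  10-year ASCVD risk, `risk = 1 − S0^exp(L − mean L)`, from the pooled
  cohort equations.
* **Omics**: run-day block normalisation (compound medians adjusted to 1),
  minimum-value imputation with exclusion at ≥ 20% missingness, inverse
  normal transformation; species prevalence filter (> 10% of samples),
  centred log-ratio transform, Shannon index, Bray–Curtis dissimilarities,
  PCoA/DBSCAN outlier flags.
* **Prediction**: twin-aware 80/20 splits with class balancing, native
  Boruta shadow-feature selection, grid-tuned `ranger` random forests,
  AUC/Spearman evaluation with bootstrap CIs, paired DeLong tests,
  cross-cohort bootstrap AUC comparison, and mean-masking recursive
  feature elimination (features frozen at training means, never refit)
  that yields minimal marker panels.
* **Association**: `outcome ~ exposure + age + sex + BMI + (1 | family)`
  by profiled REML (compiled block solver, ~0.1 ms per fit; lme4-verified),
  effective-number-of-tests Bonferroni correction
  `Meff = 1 + (M−1)(1 − Var(λ)/M)`, direction-filtered inverse-variance
  fixed-effects meta-analysis, BH-FDR, and Wilcoxon comparison of
  association strength between matrices.
* **Multivariate / mediation**: sequential-SS PERMANOVA with covariates
  and sample-size-weighted R² pooling; hypergeometric overrepresentation;
  Ward clustering of signed association profiles under the ACC distance;
  quasi-Bayesian mediation (ACME, ADE, total effect, proportion mediated)
  with exact per-draw additivity.

## Worked example

```r
library(metadiet)

cfg <- synthConfig(n_discovery = 250, n_replication = 150,
                   n_metabolites = 60, n_species = 50,
                   n_informative_metabolites = 10,
                   missing_rate_range = c(0, 0.15), seed = 2)
res <- runPipeline(pipelineConfig(
  synth = cfg, out_dir = "run1",
  grid = data.frame(mtry = 8, min_node = 5, splitrule = "gini"),
  boruta_iter = 60, num_trees = 200, repeats = 1,
  n_perm = 199, n_boot = 200, n_sim = 500, seed = 9
))

res$cohorts$discovery
#> CohortBundle "discovery"
#>   participants: 250 (MZ 112, DZ 70, unpaired 68)
#>   ffq line items: 131; metabolites: 60; species: 50
#>   run days: 8; planted diet-metabolite effects: 10

res$assoc$threshold
#> [1] 4.251344e-05

sum(res$assoc$meta$passes_threshold)
#> [1] 16

# planted mediation trios recovered by the screen
tr <- truthRegistry(res$cohorts$discovery)@mediationParams
planted <- paste(res$mediation$mediator, res$mediation$outcome) %in%
  paste(tr$mediator, tr$outcome)
res$mediation[planted, c("exposure", "mediator", "outcome",
                         "prop_mediated", "p_acme")]
#>       exposure mediator outcome prop_mediated p_acme
#> 14  nuts_seeds  met_059  sp_049     0.5164211  0.004
#> 15    red_meat  met_060  sp_050     0.3504098  0.004
#> 28 wholegrains   sp_048 met_058     0.2913732  0.004
```

The association threshold is the discovery-cohort Meff-Bonferroni level
(0.05 divided by the product of the effective test counts of the
metabolite and food-group blocks). The mediation rows are the planted
trios: the generator plants a true proportion mediated of 0.4
(a = 0.5, b = 0.4, c′ = 0.3), and the screen recovers estimates near it
with significant ACME. Stage outputs (`meta.tsv`, `eval.tsv`,
`permanova.tsv`, `mediation.tsv`, a seeded `manifest.json`, …) are written
under `out_dir`.

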