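---
title: "Methods: diet, the faecal metabolome and the gut microbiome in metadiet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diet, the faecal metabolome and the gut microbiome in metadiet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

Habitual diet is usually measured with food frequency questionnaires
(FFQs), which are noisy and self-reported, while the stool metabolome is an
objective molecular readout of what was actually eaten and of how the gut
microbiome transformed it. `metadiet` implements, as a reusable and tested
pipeline, the chain of analyses that connects these three layers in a
two-cohort (discovery/replication) twin design:

1. **Diet preparation** — FFQ quality control, aggregation of 131 line
   items into 20 food and beverage groups, energy adjustment.
2. **Dietary index scoring** — seven a priori indices (PDI, hPDI, uPDI,
   DASH, aMED, plant% and meat%) plus 10-year ASCVD risk from the pooled
   cohort equations.
3. **Omics preparation** — run-day normalisation, minimum-value imputation
   and inverse normal transformation of metabolite intensities;
   compositional transforms, diversity and dissimilarity metrics for
   species abundances.
4. **Prediction** — twin-aware random-forest models of dietary adherence
   from metabolites, with Boruta feature selection, grid-tuned
   hyperparameters, DeLong and bootstrap model comparisons, and a
   mean-masking recursive feature elimination that distils minimal marker
   panels.
5. **Association** — linear mixed models with a family random intercept,
   an effective-number-of-tests (Meff) Bonferroni correction,
   direction-filtered fixed-effects meta-analysis and BH-FDR.
6. **Community and set-level analyses** — PERMANOVA on Bray–Curtis
   dissimilarities with covariates, sample-size-weighted pooling of R²,
   hypergeometric overrepresentation analysis, and Ward clustering of
   signed association profiles under the ACC distance.
7. **Mediation** — a quasi-Bayesian screen of diet → microbe → metabolite
   and diet → metabolite → microbe trios reporting ACME, ADE, the total
   effect and the proportion mediated.

Real cohort data of this kind are access-controlled, so the package ships a
synthetic twin-cohort generator with a machine-readable registry of planted
ground truth. Every downstream claim the package makes about itself is a
claim about recovering that planted truth.

# The synthetic cohorts

`generateCohorts()` emulates the statistical structure the analyses assume,
not any particular cohort's biology:

* **Twin structure.** Individuals belong to MZ pairs, DZ pairs or are
  unpaired (default fractions 0.452/0.287, the discovery-style split).
  MZ co-twins share the full family effect; DZ co-twins share it with
  correlation 0.5; the fitted models use a single family random intercept,
  the standard simplification.
* **Diet.** Each of 20 food groups has a log-normal daily intake (g) whose
  log-scale location and spread are realistic for a European adult cohort
  (e.g. median tea/coffee ≈ 500 g, nuts ≈ 10 g, alcohol heavily skewed).
  Groups are correlated through a single latent plant-vs-animal axis with
  loadings of ±0.45 for pattern-defining groups (fruits, vegetables,
  wholegrains, red and processed meat, …) and ±0.15–0.3 for secondary
  groups, giving within-pattern food-group correlations around 0.1–0.2.
  Total energy is the energy-density-weighted sum of intakes plus noise, so
  the residual method has genuine confounding to remove.
* **Metabolites.** A planted marker metabolite for food group *g* is
  `beta * z_g + family + noise` on a latent normal scale, where `z_g` is
  the inverse-normal score of the *energy-adjusted* group intake — exactly
  the exposure scale the association stage reconstructs — and the family
  intercept contributes `family_icc` (default 0.3) of the residual
  variance. Intensities are `exp(0.8 * latent)` with per-(day, metabolite)
  multiplicative drift over 8 pseudo run days.
* **Missingness.** Values below a per-metabolite detection quantile are
  missing (left-censoring), with the censoring fraction drawn uniformly
  from `missing_rate_range` (default 0–0.35, straddling the 20% exclusion
  boundary so both the imputation and the exclusion paths are exercised).
  Intensity-dependent censoring is the dominant mechanism in untargeted
  MS and is the regime in which minimum-value imputation is coherent; a
  missing-completely-at-random mode is available via
  `missing_mechanism = "mcar"` for sensitivity work.
* **Species.** Log-normal latent abundances with heterogeneous prevalence
  (so the >10% prevalence filter has work to do), planted
  metabolite→species links, closure to relative abundances and rounding to
  counts at a random sequencing depth.
* **Mediation trios.** For each configured trio, the mediator is
  `a * exposure + e_m` and the outcome `b * mediator + c' * exposure +
  e_y` (independent family effects in each equation), so the true
  proportion mediated is `a*b / (a*b + c')`. The defaults
  (a = 0.5, b = 0.4, c' = 0.3) plant a proportion of 0.4.

## Why the default planted effect is strong

`effect_size_beta` defaults to 0.7. This is deliberately the
strong-biomarker regime: the validation studies run at desk scale
(hundreds of participants, a 20-marker panel among 200 metabolites), and
for a 20-marker panel to reconstruct a quintile-sum dietary index at all,
each marker must operate near the per-component information ceiling — the
index spreads over 18 components, so a marker with group-level fidelity
`beta` carries roughly `beta / sqrt(18)` of index-level signal. Weaker,
publication-scale effects are exercised explicitly where a study states
them: the null-calibration studies set `effect_size_beta = 0` and the
effect-recovery study plants `beta = 0.25` with family ICC 0.3, the
magnitude regime typical of strong single diet-metabolite associations.

# Statistical choices worth knowing about

* **Energy adjustment** is the residual method: the regression residual of
  intake on total energy plus the mean intake, applied per cohort after
  aggregation. Applying it twice is a no-op (residuals are already
  orthogonal to energy), which the tests pin.
* **Quintile scoring** uses empirical 20/40/60/80 percentiles with ties
  assigned to the lower quintile — consequential for zero-inflated
  components such as alcohol. Exclusion order in diet QC is fixed:
  incompleteness first (more than 10 unanswered items), then the
  energy/BMR ratio filter (±2 SD), whose statistics are computed on the
  survivors only. The Harris–Benedict equation uses the original 1919
  coefficients, held in arguments so the Roza–Shetty revision can be
  swapped in.
* **Inverse (rank) normal transformation** uses the Blom offset 3/8 and
  average ranks for ties; exposures are inverse-rank transformed and
  outcomes inverse-normal, so association slopes are standardised and
  comparable across pairs.
* **The metabolite processing order is fixed**: run-day block
  normalisation (compound medians adjusted to 1 within day), then
  minimum-value imputation with the missingness filter — a metabolite
  missing in exactly 20% of samples is *excluded* (the strict imputation
  band `< 20%`) — then the inverse normal transformation.
* **Mixed models.** The association engine fits
  `outcome ~ exposure + age + sex + BMI + (1 | family)` by REML. Because
  family blocks are singletons or pairs, the covariance inverse is closed
  form, and grouping families by size makes each profiled-REML objective
  evaluation O(p²); the scan core is compiled (RcppArmadillo) and runs a
  fit in ~0.1 ms, which is what makes replicate-level calibration studies
  feasible. lme4 is the reference implementation: the test suite pins
  agreement of slopes and standard errors, and exact equality with OLS
  when all families are singletons. Slope inference uses a t reference
  with residual degrees of freedom (`n - p`, close to the Satterthwaite
  value for individual-level covariates in pair/singleton designs;
  `df = Inf` restores a plain Wald z). The distinction only matters in
  the far tail, but the far tail is exactly where the Meff-Bonferroni
  threshold lives.
* **Meff** uses the Nyholt eigenvalue-variance form
  `1 + (M-1)(1 - Var(lambda)/M)` with the sample variance. The Bonferroni
  threshold is `alpha` divided by the product of block-wise Meff values
  (metabolite block × food-group block), derived in the discovery cohort
  and applied to the meta-analysis p values. Only pairs with the same
  effect direction in both cohorts are meta-analysed (inverse-variance
  fixed effects); discordant pairs are reported but not pooled.
* **Boruta** is implemented natively: per iteration every active feature
  gains a permuted shadow copy, a forest is fitted, and a feature scores a
  hit when it beats the best shadow; hit counts are tested two-sided
  against Binomial(iters, 1/2) with a Bonferroni-adjusted alpha of 0.01,
  and decisively rejected features leave the active set (which is what
  keeps 500-iteration runs fast).
* **Mean-masking RFE** never refits the model: features are cumulatively
  frozen at their training means, least-important-first by out-of-bag
  permutation importance, and the minimal subset is the smallest feature
  set whose metric stays within the tolerance (default 0.05) of the
  unmasked metric on *both* the held-out test set and the validation
  cohort; at least one feature is always retained.
* **Bootstrap AUC comparison.** Each evaluation set is resampled 1000
  times (single-class resamples redrawn, keeping the count fixed); the
  two-sided p value compares the observed AUC difference against the
  null-centred bootstrap distribution, `p = mean(|d* - d| >= |d|)`. The
  centring matters: the uncentred proportion can never fall below ~0.5
  and would make the test vacuous. Identical inputs give p = 1 exactly.
* **PERMANOVA** is `vegan::adonis2` with sequential sums of squares in the
  fixed order age, sex, BMI, then the term of interest, after randomly
  dropping one twin per family; per-cohort R² values are pooled as a
  sample-size-weighted average.
* **ACC clustering.** The signed association profile of each item (+1 /
  −1 / 0 per category) is compared pairwise as
  `(same-sign − opposite-sign) / |union of non-zero categories|`, mapped
  to a distance `(1 − ACC)/2`; all-zero profiles are dropped. Ward.D2
  linkage, with the cluster count chosen by maximal mean silhouette
  (smallest k on ties).
* **Mediation** is the quasi-Bayesian product-of-coefficients scheme:
  coefficients of the two family random-intercept models are drawn from
  their asymptotic normal distributions, ACME = a·b and ADE = c′ per draw,
  so ACME + ADE equals the total effect exactly in every draw. The
  reported proportion mediated is additionally clipped to [−1, 2] for
  stability near zero total effects; the raw value is kept.

# Validation studies and their problem sizes

The acceptance suite (`tests/testthat/test-acceptance.R`) and the
reproduction script (`scripts/acceptance.R`) rerun the pipeline on freshly
generated cohorts. The study conditions, chosen once:

* *Oracle equivalence*: Shannon, Bray–Curtis, CLR, Meff, fixed-effects
  pooling, BH-FDR, the hypergeometric tail (background ≤ 30, full
  enumeration) and the ACC distance each match an independent brute-force
  implementation on 100 random instances to 1e-9.
* *Null calibration*: 50 replicate cohort pairs at n = 400/cohort with 200
  metabolites, 20 food groups and `effect_size_beta = 0`; the family-wise
  rate of any Meff-Bonferroni-passing meta-association must stay ≤ 0.10,
  and the mean test AUC of every dietary index must lie in [0.40, 0.60].
  PERMANOVA null p values (200 runs at 999 permutations against a noise
  term) must pass a uniformity KS test.
* *Effect recovery*: planted `beta = 0.25`, family ICC 0.3, combined
  n = 1200 (800 + 400), 100 replicates; the mean pooled meta slope must
  land within 0.25 ± 0.02 with 95% CI coverage in [0.92, 0.98].
* *Prediction recovery*: 20 planted markers among 200 metabolites at
  n = 800 with low missingness (`missing_rate_range = c(0, 0.1)`, so the
  planted panel is actually present after filtering); top-vs-bottom
  quartile AUC for the healthful plant-based diet index (hPDI — the index
  whose component scoring directions coincide with the generator's single
  healthfulness axis, so every planted marker is genuinely informative
  for it), Boruta recall/specificity and the mean-masking RFE subset are
  scored against the registry.
* *Bootstrap comparison*: 100 repeats of same-model evaluation sets
  (n = 500 each) and of forced 0.95-vs-0.55 AUCs.
* *Mediation recovery*: 20 replicate cohorts at n = 474 with the default
  planted trios (true proportion mediated 0.4) and 20 null-path
  (`b = 0`) replicates.
* *Leakage guard*: 20 seeds of the full selection → tuning → RFE stack on
  labels permuted after the twin-aware split (n = 3000 so the test-set
  binomial noise cannot masquerade as leakage); every test AUC must stay
  within [0.40, 0.60].

# What passing these studies does and does not show

The generator produces Gaussian latent structure, monotone intensity maps,
exactly log-normal intakes and a single dietary axis. Real cohorts have
batch structure beyond multiplicative day drift, non-monotone
diet-metabolite relationships, shared-environment confounding, and many
correlated dietary axes. Passing tests therefore demonstrates that the
*procedures* are implemented correctly and are calibrated and unbiased
under the structures they assume — not that any particular biological
finding would replicate. The mediation screen in particular inherits the
usual sequential-ignorability caveat: a significant ACME on observational
data is compatible with mediation, never proof of it.

Known limitations: the PCoA outlier flag drops negative eigenvalues
(no Lingoes/Cailliez correction); heterogeneity statistics (I², Q) are not
computed alongside the fixed-effects pool; splits beyond gini/extratrees/
hellinger and variance/extratrees/maxstat are not exposed; and the
prediction stack models metabolites plus age/sex/BMI covariates only.
Two finite-sample properties of the emulated procedures are worth knowing.
First, at a few hundred samples per cohort the direction-filtered
fixed-effects pool has mild extreme-tail inflation (group-shared variance
heterogeneity plus estimated-variance-ratio kurtosis), so its family-wise
error at the Meff-Bonferroni threshold can exceed twice the nominal level;
the effect disappears by roughly a thousand samples per cohort. Second,
mean-masking RFE panels are governed by information saturation of
quintile-sum indices: the minimal subset within an AUC tolerance of 0.05
is typically far smaller than the full set of genuinely informative
markers, because index-level signal saturates well before all markers are
used — minimal panels bound the marker set from below, never enumerate
it.

# Reproducing the numbers

```r
library(metadiet)
cfg <- synthConfig(n_discovery = 400, n_replication = 200,
                   n_metabolites = 60, n_species = 50,
                   n_informative_metabolites = 10, seed = 1)
res <- runPipeline(pipelineConfig(synth = cfg, out_dir = "run1",
                                  n_perm = 999, seed = 1))
head(res$assoc$meta[order(res$assoc$meta$p), ])
```

`Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json`
recomputes the headline validation quantities from scratch; the README
describes each reported field.
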