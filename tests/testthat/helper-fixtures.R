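# Shared fixtures: built once per test run, in code (no stored data).

.fixture_env <- new.env(parent = emptyenv())

# no planted mediation trios (used for null-calibration fixtures)
noTrios <- function() {
  data.frame(exposure = character(), mediator_type = character(),
             a = numeric(), b = numeric(), c_prime = numeric())
}

# small two-cohort fixture with planted signal, shared across tests
smallCohorts <- function() {
  if (is.null(.fixture_env$small)) {
    cfg <- synthConfig(
      n_discovery = 220, n_replication = 140, n_metabolites = 40,
      n_species = 40, n_informative_metabolites = 8,
      missing_rate_range = c(0, 0.15), seed = 101
    )
    .fixture_env$small <- generateCohorts(cfg)
  }
  .fixture_env$small
}

# prepared analysis blocks for one bundle
prepareAll <- function(bundle) {
  d <- prepareDiet(bundle)
  p <- participants(bundle)
  rows <- match(d$kept_ids, p$participant_id)
  p <- p[rows, ]
  om <- prepareOmics(bundle, ids = d$kept_ids)
  list(
    diet = d, p = p, om = om,
    fg_int = apply(d$foodgroups, 2, inverseRankTransform),
    covars = standardizeCovariates(
      data.frame(age = p$age, sex = p$sex, bmi = p$bmi)
    ),
    indices = scoreAllIndices(d$foodgroups, d$foodgroups_raw,
                              nutrientTotals(bundle)[rows, , drop = FALSE],
                              sex = p$sex)
  )
}

smallPrepared <- function(which = "discovery") {
  key <- paste0("prep_", which)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- prepareAll(smallCohorts()[[which]])
  }
  .fixture_env[[key]]
}

# twin-structured regression data with a known slope, for LMM tests
twinRegression <- function(n_pairs = 150, n_single = 50, beta = 0.3,
                           icc = 0.3, seed = 1) {
  set.seed(seed)
  n <- 2 * n_pairs + n_single
  family <- c(rep(seq_len(n_pairs), each = 2), n_pairs + seq_len(n_single))
  fam_eff <- rnorm(n_pairs + n_single)[family]
  w <- c(rep(1, 2 * n_pairs), rep(1, n_single))
  x <- rnorm(n)
  covars <- cbind(age = rnorm(n), sex = rbinom(n, 1, 0.5), bmi = rnorm(n))
  y <- beta * x + sqrt(icc) * w * fam_eff + sqrt(1 - icc) * rnorm(n)
  list(y = y, x = x, covars = covars, family = family)
}
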