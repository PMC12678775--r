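orderByFamily <- function(family) {
  ord <- order(match(family, unique(family)))
  sizes <- as.integer(table(factor(family, levels = unique(family))))
  list(order = ord, sizes = sizes)
}

#' Standardise covariates to mean 0 and standard deviation 1
#'
#' Sex stays a 0/1 indicator centred and scaled like the other covariates,
#' matching the convention of scaling all covariates before modelling.
#'
#' @param covariates data.frame or matrix of numeric covariates.
#' @return numeric matrix of scaled covariates.
#' @export
standardizeCovariates <- function(covariates) {
  m <- as.matrix(covariates)
  scale(m)[, , drop = FALSE]
}

#' Linear mixed model association with a family random intercept
#'
#' Fits `outcome ~ exposure + covariates + (1 | family)` by restricted
#' maximum likelihood and reports the Wald test on the exposure slope
#' against a t reference with residual degrees of freedom (`n - p`, close
#' to the Satterthwaite value for individual-level covariates in
#' pair/singleton designs; `df = Inf` gives the normal reference). The
#' `"fast"` engine is the package's profiled-REML block solver; `"lmer"`
#' uses lme4 and falls back to ordinary least squares with a logged flag
#' if the fit fails.
#'
#' @param outcome numeric outcome (inverse-normal scale by convention).
#' @param exposure numeric exposure (inverse-rank transformed).
#' @param covariates matrix/data.frame of covariates (standardised), or
#'   `NULL`.
#' @param family family identifier per sample.
#' @param engine `"fast"` or `"lmer"`.
#' @param df degrees of freedom for the slope test; `NULL` (default) uses
#'   the residual `n - p`, `Inf` the normal reference.
#' @return one-row data.frame with `beta`, `se`, `z`, `p`, `n`,
#'   `lambda` (family-to-residual variance ratio) and `engine`.
#' @export
fitLmm <- function(outcome, exposure, covariates = NULL, family,
                   engine = c("fast", "lmer"), df = NULL) {
  engine <- match.arg(engine)
  keep <- complete.cases(outcome, exposure,
                         if (is.null(covariates)) rep(0, length(outcome))
                         else covariates)
  outcome <- outcome[keep]
  exposure <- exposure[keep]
  family <- family[keep]
  covariates <- if (is.null(covariates)) NULL else
    as.matrix(covariates)[keep, , drop = FALSE]
  n <- length(outcome)
  if (engine == "lmer") {
    dat <- data.frame(y = outcome, x = exposure, fam = family)
    form <- "y ~ x + (1 | fam)"
    if (!is.null(covariates)) {
      dat <- cbind(dat, as.data.frame(covariates))
      form <- paste("y ~ x +", paste(colnames(covariates), collapse = " + "),
                    "+ (1 | fam)")
    }
    fit <- tryCatch(
      lme4::lmer(stats::as.formula(form), data = dat, REML = TRUE),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      ols <- lm(outcome ~ exposure + covariates)
      sm <- summary(ols)$coefficients["exposure", ]
      return(data.frame(beta = sm[1], se = sm[2], z = sm[3],
                        p = 2 * pnorm(-abs(sm[3])), n = n, lambda = 0,
                        engine = "ols_fallback"))
    }
    sm <- summary(fit)$coefficients
    beta <- sm["x", "Estimate"]
    se <- sm["x", "Std. Error"]
    vc <- as.data.frame(lme4::VarCorr(fit))
    lambda <- vc$vcov[vc$grp == "fam"] / vc$vcov[vc$grp == "Residual"]
  } else {
    ord <- orderByFamily(family)
    X <- cbind(intercept = 1,
               if (!is.null(covariates)) covariates,
               exposure = exposure)[ord$order, , drop = FALSE]
    fit <- cpp_lmm_fit(X, outcome[ord$order], ord$sizes)
    p_idx <- ncol(X)
    beta <- fit$beta[p_idx]
    se <- sqrt(fit$cov[p_idx, p_idx])
    lambda <- fit$lambda
  }
  z <- beta / se
  p_cols <- 2 + (if (is.null(covariates)) 0 else ncol(covariates))
  if (is.null(df)) df <- n - p_cols
  data.frame(beta = beta, se = se, z = z, p = 2 * pt(-abs(z), df = df),
             n = n, lambda = lambda, engine = engine, row.names = NULL)
}

#' Mixed-model association scan over all exposure-outcome pairs
#'
#' For every exposure column and outcome column, fits the family
#' random-intercept model `outcome ~ exposure + covariates + (1 | family)`
#' by profiled REML (compiled block solver) and reports the Wald z test on
#' the exposure slope. All matrices must be complete (no missing cells).
#'
#' @param outcomes sample x outcome matrix (inverse-normal scale).
#' @param exposures sample x exposure matrix (inverse-rank transformed).
#' @param covariates covariate matrix (standardised) or `NULL`.
#' @param family family id per sample.
#' @param cohort optional cohort label stored in the result.
#' @param df degrees of freedom for the slope tests; `NULL` (default) uses
#'   the residual `n - p`, `Inf` the normal reference.
#' @return data.frame with one row per (exposure, outcome) pair: `exposure`,
#'   `outcome`, `beta`, `se`, `z`, `p`, `n`, `cohort`.
#' @export
associationScan <- function(outcomes, exposures, covariates = NULL, family,
                            cohort = NA_character_, df = NULL) {
  outcomes <- as.matrix(outcomes)
  exposures <- as.matrix(exposures)
  stopifnot(nrow(outcomes) == nrow(exposures))
  ord <- orderByFamily(family)
  C <- cbind(intercept = 1,
             if (!is.null(covariates)) as.matrix(covariates))
  res <- cpp_lmm_scan(C[ord$order, , drop = FALSE],
                      exposures[ord$order, , drop = FALSE],
                      outcomes[ord$order, , drop = FALSE],
                      ord$sizes)
  z <- res$beta / res$se
  if (is.null(df)) df <- nrow(outcomes) - ncol(C) - 1
  data.frame(
    exposure = rep(colnames(exposures), times = ncol(outcomes)),
    outcome = rep(colnames(outcomes), each = ncol(exposures)),
    beta = as.vector(res$beta), se = as.vector(res$se),
    z = as.vector(z), p = as.vector(2 * pt(-abs(z), df = df)),
    n = nrow(outcomes), cohort = cohort,
    stringsAsFactors = FALSE
  )
}

#' Effective number of independent tests from eigenvalue variance
#'
#' Nyholt's formula: `Meff = 1 + (M - 1) (1 - Var(lambda) / M)` with
#' `Var(lambda)` the sample variance (denominator `M - 1`) of the
#' eigenvalues of the correlation matrix. Equals `M` for the identity and 1
#' for perfect correlation.
#'
#' @param corr_matrix symmetric correlation matrix with unit diagonal.
#' @return effective number of tests in `[1, M]`.
#' @export
meff <- function(corr_matrix) {
  if (!isSymmetric(unname(corr_matrix), tol = 1e-8)) {
    stop("correlation matrix must be symmetric")
  }
  M <- ncol(corr_matrix)
  if (M == 1) return(1)
  ev <- eigen(corr_matrix, symmetric = TRUE, only.values = TRUE)$values
  1 + (M - 1) * (1 - var(ev) / M)
}

#' Meff-based Bonferroni threshold
#'
#' `alpha / prod(meff_components)`, e.g. the product of the effective test
#' numbers of the outcome block and the exposure block.
#'
#' @param alpha family-wise error target (default 0.05).
#' @param meff_components effective test counts (each >= 1).
#' @return significance threshold.
#' @export
bonferroniThreshold <- function(alpha = 0.05, meff_components) {
  if (!length(meff_components)) stop("no Meff components supplied")
  if (any(meff_components < 1)) stop("Meff components must be >= 1")
  alpha / prod(meff_components)
}

#' Inverse-variance fixed-effects meta-analysis of one association
#'
#' Weights `w = 1 / se^2`; pooled `beta = sum(w b) / sum(w)`, pooled
#' `se = 1 / sqrt(sum(w))`. The default p value uses the normal reference;
#' supplying per-cohort degrees of freedom applies a small-sample t
#' reference with Satterthwaite-combined df, which matters only in the far
#' tail at modest cohort sizes.
#'
#' @param beta per-cohort slopes.
#' @param se per-cohort standard errors (positive).
#' @param df optional per-cohort residual degrees of freedom.
#' @return list with `beta`, `se`, `z`, `p` (and `df` when supplied).
#' @export
fixedEffectsMeta <- function(beta, se, df = NULL) {
  stopifnot(length(beta) == length(se), all(se > 0))
  w <- 1 / se^2
  b <- sum(w * beta) / sum(w)
  s <- 1 / sqrt(sum(w))
  z <- b / s
  if (is.null(df)) {
    list(beta = b, se = s, z = z, p = 2 * pnorm(-abs(z)))
  } else {
    stopifnot(length(df) == length(beta), all(df > 0))
    nu <- sum(w)^2 / sum(w^2 / df)
    list(beta = b, se = s, z = z, p = 2 * pt(-abs(z), df = nu), df = nu)
  }
}

#' Direction-filtered fixed-effects meta-analysis of two association tables
#'
#' Joins discovery and replication scans on (exposure, outcome); pairs with
#' the same effect-size direction in both cohorts are pooled by
#' inverse-variance fixed-effects meta-analysis, others are marked not
#' meta-analysed. `passes_threshold` compares the meta p value with the
#' discovery-derived Meff-Bonferroni threshold.
#'
#' @param discovery,replication data.frames from [associationScan()].
#' @param threshold significance threshold from [bonferroniThreshold()].
#' @param small_sample use the Satterthwaite-combined t reference for the
#'   pooled p values (per-cohort residual df taken from the scan tables);
#'   `FALSE` gives the plain normal reference.
#' @return data.frame with pooled `beta`, `se`, `p`, `q` (BH-FDR over the
#'   meta-analysed rows), `direction_consistent` and `passes_threshold`.
#' @export
metaAnalyse <- function(discovery, replication, threshold = 0.05,
                        small_sample = TRUE) {
  key <- c("exposure", "outcome")
  merged <- merge(discovery, replication, by = key,
                  suffixes = c("_disc", "_repl"))
  consistent <- sign(merged$beta_disc) == sign(merged$beta_repl)
  out <- data.frame(
    merged[key],
    beta = NA_real_, se = NA_real_, p = NA_real_,
    beta_disc = merged$beta_disc, p_disc = merged$p_disc,
    beta_repl = merged$beta_repl, p_repl = merged$p_repl,
    direction_consistent = consistent,
    stringsAsFactors = FALSE
  )
  dfs <- if (small_sample && all(c("n_disc", "n_repl") %in% names(merged))) {
    cbind(pmax(merged$n_disc - 5, 1), pmax(merged$n_repl - 5, 1))
  } else {
    NULL
  }
  for (i in which(consistent)) {
    m <- fixedEffectsMeta(c(merged$beta_disc[i], merged$beta_repl[i]),
                          c(merged$se_disc[i], merged$se_repl[i]),
                          df = if (is.null(dfs)) NULL else dfs[i, ])
    out$beta[i] <- m$beta
    out$se[i] <- m$se
    out$p[i] <- m$p
  }
  out$q <- NA_real_
  out$q[consistent] <- bhFdr(out$p[consistent])
  out$passes_threshold <- !is.na(out$p) & out$p < threshold
  out
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Standard step-up adjustment with monotonicity enforcement;
#' `q >= p` elementwise.
#'
#' @param pvals p values in `(0, 1]`.
#' @return adjusted q values.
#' @export
bhFdr <- function(pvals) {
  p.adjust(pvals, method = "BH")
}

#' Compare association strength between two sets of tests
#'
#' Two-sided Wilcoxon rank-sum test on the `-log10 p` values of two
#' association collections (e.g. faecal vs serum metabolite scans).
#'
#' @param p_a,p_b p-value collections.
#' @return list with `p`, `statistic`, and `stronger` (`"A"`, `"B"` or
#'   `"tied"`, by median `-log10 p`).
#' @export
compareMatrixStrength <- function(p_a, p_b) {
  if (!length(p_a) || !length(p_b)) stop("empty p-value collection")
  la <- -log10(p_a)
  lb <- -log10(p_b)
  wt <- wilcox.test(la, lb, alternative = "two.sided", exact = FALSE)
  list(
    p = wt$p.value, statistic = unname(wt$statistic),
    stronger = if (median(la) > median(lb)) "A"
               else if (median(la) < median(lb)) "B" else "tied"
  )
}
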