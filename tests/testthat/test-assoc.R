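test_that("fast REML engine agrees with lme4 and recovers planted slopes", {
  dat <- twinRegression(n_pairs = 120, n_single = 40, beta = 0.3, icc = 0.3,
                        seed = 10)
  fast <- fitLmm(dat$y, dat$x, dat$covars, dat$family, engine = "fast")
  skip_if_not_installed("lme4")
  ref <- fitLmm(dat$y, dat$x, dat$covars, dat$family, engine = "lmer")
  expect_equal(fast$beta, ref$beta, tolerance = 1e-5)
  expect_equal(fast$se, ref$se, tolerance = 1e-4)
  expect_equal(fast$lambda, ref$lambda, tolerance = 1e-2)
})

test_that("with singleton families the mixed model equals the OLS oracle", {
  set.seed(11)
  n <- 120
  x <- rnorm(n)
  covars <- cbind(age = rnorm(n), bmi = rnorm(n))
  y <- 0.4 * x + rnorm(n)
  fit <- fitLmm(y, x, covars, family = seq_len(n), engine = "fast")
  ols <- summary(lm(y ~ covars + x))$coefficients["x", ]
  expect_equal(fit$beta, unname(ols[1]), tolerance = 1e-6)
  expect_equal(fit$se, unname(ols[2]), tolerance = 1e-6)
})

test_that("the scan reproduces single fits across all pairs", {
  dat <- twinRegression(seed = 12)
  E <- cbind(e1 = dat$x, e2 = rnorm(length(dat$y)))
  Y <- cbind(m1 = dat$y, m2 = rnorm(length(dat$y)))
  scan <- associationScan(Y, E, dat$covars, dat$family)
  expect_equal(nrow(scan), 4)
  for (i in seq_len(nrow(scan))) {
    single <- fitLmm(Y[, scan$outcome[i]], E[, scan$exposure[i]],
                     dat$covars, dat$family, engine = "fast")
    expect_equal(scan$beta[i], single$beta, tolerance = 1e-8)
    expect_equal(scan$se[i], single$se, tolerance = 1e-8)
  }
})

test_that("null exposures give calibrated p values", {
  set.seed(13)
  reps <- 200
  dat <- twinRegression(n_pairs = 60, n_single = 20, beta = 0, seed = 14)
  E <- matrix(rnorm(length(dat$y) * reps), ncol = reps)
  colnames(E) <- paste0("e", seq_len(reps))
  scan <- associationScan(cbind(y = dat$y), E, dat$covars, dat$family)
  ks <- suppressWarnings(stats::ks.test(scan$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("Meff follows the eigenvalue-variance formula", {
  expect_equal(meff(diag(10)), 10)
  allones <- matrix(1, 10, 10)
  expect_equal(meff(allones), 1, tolerance = 1e-8)
  r <- matrix(c(1, 0.5, 0.5, 1), 2)
  expect_equal(meff(r), 2 - 0.5^2) # closed form for 2 x 2
  expect_error(meff(matrix(c(1, 0.2, 0.5, 1), 2)), "symmetric")
  # oracle: direct formula on random correlation matrices
  set.seed(15)
  for (i in 1:20) {
    X <- matrix(rnorm(400), 40)
    R <- cor(X)
    ev <- eigen(R, only.values = TRUE)$values
    M <- ncol(R)
    expect_equal(meff(R), 1 + (M - 1) * (1 - var(ev) / M), tolerance = 1e-9)
    expect_gte(meff(R), 1)
    expect_lte(meff(R), M)
  }
})

test_that("Bonferroni threshold multiplies Meff components", {
  expect_equal(bonferroniThreshold(0.05, 10), 0.005)
  expect_equal(bonferroniThreshold(0.05, c(10, 5)), 0.001)
  expect_equal(bonferroniThreshold(0.05, c(1, 1)), 0.05)
  expect_error(bonferroniThreshold(0.05, numeric()), "no Meff")
  expect_error(bonferroniThreshold(0.05, 0.5), ">= 1")
})

test_that("fixed-effects meta-analysis matches the hand arithmetic", {
  m <- fixedEffectsMeta(c(0.2, 0.4), c(0.1, 0.2))
  expect_equal(m$beta, 0.24, tolerance = 1e-12)
  expect_equal(m$se, sqrt(1 / (100 + 25)), tolerance = 1e-12)
  single <- fixedEffectsMeta(0.3, 0.05)
  expect_equal(single$beta, 0.3)
  expect_equal(single$se, 0.05)
  equal_se <- fixedEffectsMeta(c(0.1, 0.5), c(0.2, 0.2))
  expect_equal(equal_se$beta, 0.3)
  # pooled CI shrinks as cohorts accumulate
  se3 <- fixedEffectsMeta(c(0.2, 0.4, 0.3), c(0.1, 0.2, 0.15))$se
  expect_lt(se3, m$se)
})

test_that("fixed-effects pooling agrees with metafor", {
  skip_if_not_installed("metafor")
  set.seed(16)
  for (i in 1:25) {
    b <- rnorm(2)
    s <- runif(2, 0.05, 0.3)
    ours <- fixedEffectsMeta(b, s)
    ref <- metafor::rma(yi = b, sei = s, method = "FE")
    expect_equal(ours$beta, as.numeric(ref$beta), tolerance = 1e-9)
    expect_equal(ours$se, as.numeric(ref$se), tolerance = 1e-9)
    expect_equal(ours$p, as.numeric(ref$pval), tolerance = 1e-9)
  }
})

test_that("meta table applies the direction filter and thresholds", {
  disc <- data.frame(exposure = c("f1", "f1"), outcome = c("m1", "m2"),
                     beta = c(0.3, 0.2), se = c(0.05, 0.05),
                     z = NA, p = NA, n = 100, cohort = "discovery")
  repl <- data.frame(exposure = c("f1", "f1"), outcome = c("m1", "m2"),
                     beta = c(0.25, -0.2), se = c(0.08, 0.08),
                     z = NA, p = NA, n = 60, cohort = "replication")
  meta <- metaAnalyse(disc, repl, threshold = 1e-3)
  m1 <- meta[meta$outcome == "m1", ]
  m2 <- meta[meta$outcome == "m2", ]
  expect_true(m1$direction_consistent)
  expect_false(m2$direction_consistent)
  expect_true(is.na(m2$beta)) # opposite signs: not meta-analysed
  expect_true(m1$passes_threshold)
  byhand <- fixedEffectsMeta(c(0.3, 0.25), c(0.05, 0.08))
  expect_equal(m1$beta, byhand$beta)
})

test_that("BH adjustment reproduces the step-up enumeration", {
  expect_equal(bhFdr(0.02), 0.02)
  expect_equal(bhFdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhFdr(rep(1, 5)), rep(1, 5))
  set.seed(17)
  p <- runif(50)
  q <- bhFdr(p)
  expect_true(all(q >= p))
  # brute-force step-up oracle
  ord <- order(p)
  m <- length(p)
  stepup <- rev(cummin(rev(p[ord] * m / seq_len(m))))
  expect_equal(q[ord], pmin(stepup, 1), tolerance = 1e-12)
})

test_that("association-strength comparison is symmetric and powered", {
  set.seed(18)
  strong <- rep(1e-6, 50)
  weak <- rep(0.5, 50)
  res <- compareMatrixStrength(strong, weak)
  expect_lt(res$p, 1e-3)
  expect_equal(res$stronger, "A")
  swapped <- compareMatrixStrength(weak, strong)
  expect_equal(res$p, swapped$p)
  expect_equal(swapped$stronger, "B")
  same <- compareMatrixStrength(runif(30), runif(30))
  expect_gt(same$p, 0.001)
  expect_error(compareMatrixStrength(numeric(), weak), "empty")
})

test_that("planted effects are recovered without bias", {
  set.seed(19)
  est <- replicate(40, {
    dat <- twinRegression(n_pairs = 100, n_single = 0, beta = 0.25,
                          icc = 0.3, seed = sample.int(1e6, 1))
    fitLmm(dat$y, dat$x, dat$covars, dat$family)$beta
  })
  expect_lt(abs(mean(est) - 0.25), 0.02)
})
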