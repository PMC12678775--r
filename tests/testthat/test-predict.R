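test_that("quartile labelling keeps the extremes and drops the middle", {
  lab <- quartileLabels(1:8)
  expect_equal(which(lab == 0L), 1:2)
  expect_equal(which(lab == 1L), 7:8)
  expect_equal(sum(is.na(lab)), 4)
  lab100 <- quartileLabels(rnorm(100))
  expect_equal(sum(lab100 == 0, na.rm = TRUE), 25)
  expect_equal(sum(lab100 == 1, na.rm = TRUE), 25)
  # deterministic tie handling by stable order
  tied <- c(1, 1, 1, 1, 2, 2, 2, 2)
  expect_identical(quartileLabels(tied), quartileLabels(tied))
  expect_equal(which(quartileLabels(tied) == 0L), 1:2)
  expect_error(quartileLabels(rep(1, 10)), "constant")
  expect_error(quartileLabels(1:7), "at least 8")
})

test_that("twin-aware split keeps families together and classes balanced", {
  set.seed(20)
  n <- 120
  fam <- c(rep(1:40, each = 2), 40 + seq_len(n - 80))
  labels <- rep(c(0L, 1L), length.out = n)
  sp <- twinAwareSplit(labels, fam, train_frac = 0.8, seed = 3)
  expect_length(intersect(fam[sp$train], fam[sp$test]), 0)
  expect_equal(unname(table(labels[sp$train])[1]),
               unname(table(labels[sp$train])[2]))
  expect_equal(unname(table(labels[sp$test])[1]),
               unname(table(labels[sp$test])[2]))
  sp2 <- twinAwareSplit(labels, fam, train_frac = 0.8, seed = 3)
  expect_identical(sp, sp2)
  # all singletons with balanced classes: a clean 80/20 split
  singles <- twinAwareSplit(rep(c(0L, 1L), 50), seq_len(100), seed = 4)
  expect_equal(length(singles$train), 80)
  expect_equal(length(singles$test), 20)
  # a dominant family lands entirely on one side
  big_fam <- c(rep(1, 30), 100 + seq_len(70))
  spb <- twinAwareSplit(rep(c(0L, 1L), 50), big_fam, seed = 5)
  expect_true(all(which(big_fam == 1) %in% spb$train) ||
                all(which(big_fam == 1) %in% spb$test))
})

test_that("AUC rank statistic counts concordant pairs", {
  expect_equal(aucRank(c(0.9, 0.8, 0.3, 0.1), c(1, 0, 1, 0)), 0.75)
  expect_equal(aucRank(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(aucRank(rep(0.5, 10), rep(c(0, 1), 5)), 0.5) # all ties
  expect_error(aucRank(c(0.2, 0.4), c(1, 1)), "single-class")
  skip_if_not_installed("pROC")
  set.seed(21)
  probs <- runif(60)
  labels <- rbinom(60, 1, probs)
  ref <- suppressMessages(pROC::auc(labels, probs))
  expect_equal(aucRank(probs, labels), as.numeric(ref), tolerance = 1e-12)
})

test_that("DeLong test matches pROC and is symmetric", {
  set.seed(22)
  n <- 80
  labels <- rep(c(0, 1), n / 2)
  pa <- plogis(labels + rnorm(n))
  pb <- plogis(0.3 * labels + rnorm(n))
  res <- delongTest(pa, pb, labels)
  swapped <- delongTest(pb, pa, labels)
  expect_equal(res$p, swapped$p)
  expect_equal(res$z, -swapped$z)
  same <- delongTest(pa, pa, labels)
  expect_equal(same$p, 1)
  skip_if_not_installed("pROC")
  ref <- suppressMessages(pROC::roc.test(
    pROC::roc(labels, pa, quiet = TRUE), pROC::roc(labels, pb, quiet = TRUE),
    method = "delong"
  ))
  expect_equal(res$p, ref$p.value, tolerance = 1e-6)
})

test_that("bootstrap AUC comparison behaves at the null and under separation", {
  set.seed(23)
  labels <- rep(c(0, 1), 100)
  probs <- plogis(2 * labels - 1 + rnorm(200))
  same <- bootstrapAucCompare(probs, labels, probs, labels, n_boot = 200,
                              seed = 1)
  expect_equal(same$diff, 0)
  expect_equal(same$p, 1)
  rerun <- bootstrapAucCompare(probs, labels, probs, labels, n_boot = 200,
                               seed = 1)
  expect_identical(same$p, rerun$p)
  # strongly separated vs near-chance classifiers
  la <- rep(c(0, 1), 250)
  pa <- la * 2.33 + rnorm(500) # AUC ~ 0.95
  lb <- rep(c(0, 1), 250)
  pb <- lb * 0.18 + rnorm(500) # AUC ~ 0.55
  res <- bootstrapAucCompare(pa, la, pb, lb, n_boot = 500, seed = 2)
  expect_lt(res$p, 0.05)
  expect_warning(bootstrapAucCompare(pa, la, pb, lb, n_boot = 50, seed = 3),
                 "fewer than 100")
})

test_that("Boruta confirms a copied target and rejects pure noise", {
  set.seed(24)
  n <- 150
  x <- matrix(rnorm(n * 15), n, dimnames = list(NULL, paste0("f", 1:15)))
  y_num <- x[, "f3"]
  res <- borutaSelect(x, y_num, max_iter = 60, num_trees = 60, seed = 1)
  expect_true("f3" %in% res$confirmed)
  y_null <- rnorm(n)
  res_null <- borutaSelect(x, y_null, max_iter = 60, num_trees = 60, seed = 2)
  expect_length(res_null$confirmed, 0)
  expect_error(borutaSelect(x[, 1, drop = FALSE], y_num), "at least 2")
})

test_that("grid tuning selects sensible cells deterministically", {
  set.seed(25)
  n <- 120
  x <- matrix(rnorm(n * 6), n, dimnames = list(NULL, paste0("f", 1:6)))
  y <- factor(as.integer(x[, 1] + 0.5 * x[, 2] + rnorm(n, 0, 0.5) > 0))
  one_cell <- data.frame(mtry = 2, min_node = 5, splitrule = "gini")
  fit <- tuneAndFit(x, y, grid = one_cell, repeats = 1, num_trees = 100,
                    seed = 1)
  expect_equal(fit$best$mtry, 2)
  # duplicated cells: the first in grid order wins
  dup <- rbind(one_cell, one_cell)
  fit2 <- tuneAndFit(x, y, grid = dup, repeats = 1, num_trees = 100, seed = 1)
  expect_equal(rownames(fit2$best), "1")
  # planted signal beats chance comfortably in CV
  expect_gt(max(fit$cv$metric), 0.5 + 3 * sqrt(0.25 / n))
  expect_error(tuneAndFit(x, y, grid = one_cell[0, ]), "empty")
  # default grid covers the prescribed mtry fractions and rules
  g <- defaultGrid(100, "classification")
  expect_true(all(c(10, 20, 30, 40, 50) %in% g$mtry))
  expect_setequal(unique(g$splitrule), c("gini", "extratrees", "hellinger"))
  gr <- defaultGrid(100, "regression")
  expect_setequal(unique(gr$splitrule), c("variance", "extratrees", "maxstat"))
})

test_that("evaluation returns perfect and chance-level AUCs appropriately", {
  set.seed(26)
  n <- 200
  x <- matrix(rnorm(n * 5), n, dimnames = list(NULL, paste0("f", 1:5)))
  y <- factor(as.integer(x[, 1] > 0))
  fit <- tuneAndFit(x, y, grid = data.frame(mtry = 2, min_node = 5,
                                            splitrule = "gini"),
                    repeats = 1, num_trees = 150, seed = 1)
  ev <- evaluateModel(fit$model, x, y, n_boot = 100, seed = 1)
  expect_gt(ev$estimate, 0.95) # in-sample on a deterministic rule
  expect_true(ev$ci[1] <= ev$estimate && ev$estimate <= ev$ci[2])
  # chance-level labels
  y2 <- factor(rep(c(0, 1), n / 2))
  ev2 <- evaluateModel(fit$model, x, y2, n_boot = 100, seed = 1)
  expect_true(ev2$estimate > 0.3 && ev2$estimate < 0.7)
  expect_error(evaluateModel(fit$model, x, factor(rep(1, n), levels = c(0, 1))),
               "single-class")
})

test_that("mean-masking RFE keeps signal features and the step-0 identity", {
  set.seed(27)
  n <- 400
  p <- 12
  x <- matrix(rnorm(n * p), n, dimnames = list(NULL, paste0("f", 1:p)))
  signal <- x[, 1] + x[, 2] + x[, 3]
  y <- factor(as.integer(signal + rnorm(n, 0, 0.5) > 0))
  tr <- seq_len(300)
  te <- setdiff(seq_len(n), tr)
  fit <- tuneAndFit(x[tr, ], y[tr],
                    grid = data.frame(mtry = 3, min_node = 5,
                                      splitrule = "gini"),
                    repeats = 1, num_trees = 200, seed = 1)
  imp <- permutationImportance(fit$model)
  rfe <- meanMaskRfe(fit$model, colMeans(x[tr, ]), imp,
                     x[te, ], y[te], x[te, ], y[te], tolerance = 0.02)
  expect_equal(rfe$trajectory$metric_test[1], rfe$original_test)
  ev <- evaluateModel(fit$model, x[te, ], y[te], n_boot = 10, seed = 1)
  expect_equal(rfe$original_test, ev$estimate)
  expect_true(all(c("f1", "f2", "f3") %in% rfe$subset))
  expect_gte(min(rfe$trajectory$n_retained), 1)
  expect_error(meanMaskRfe(fit$model, colMeans(x[tr, ]), imp,
                           x[te, ], y[te], x[te, ], y[te], tolerance = -1),
               "nonnegative")
})

test_that("panel building unions subsets and strips covariates", {
  expect_setequal(buildPanel(list(c("a", "b"), c("b", "c"))), c("a", "b", "c"))
  expect_setequal(buildPanel(list(c("a", "age", "bmi"))), "a")
  expect_equal(buildPanel(list(list(subset = c("x", "sex")))), "x")
  expect_length(buildPanel(list()), 0)
})

test_that("unused features carry near-zero permutation importance", {
  set.seed(28)
  n <- 300
  x <- matrix(rnorm(n * 6), n, dimnames = list(NULL, paste0("f", 1:6)))
  y <- factor(as.integer(x[, 1] > 0))
  fit <- tuneAndFit(x, y, grid = data.frame(mtry = 2, min_node = 5,
                                            splitrule = "gini"),
                    repeats = 1, num_trees = 200, seed = 1)
  imp <- permutationImportance(fit$model, x, y, repeats = 5, seed = 1)
  expect_equal(names(imp)[1], "f1")
  expect_gt(imp["f1"], 10 * max(abs(imp[c("f4", "f5", "f6")])))
})
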