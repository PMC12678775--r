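test_that("incompleteness filter is strict above the gate", {
  ffq <- matrix(1, 3, 20, dimnames = list(c("a", "b", "c"), NULL))
  ffq[1, 1:10] <- NA # exactly 10 unanswered: retained
  ffq[2, 1:11] <- NA # 11 unanswered: excluded
  res <- excludeIncomplete(ffq, max_unanswered = 10)
  expect_equal(rownames(res$ffq), c("a", "c"))
  expect_equal(res$exclusions$participant_id, "b")
  expect_equal(res$exclusions$n_unanswered, 11)
  empty <- excludeIncomplete(ffq[0, , drop = FALSE])
  expect_equal(nrow(empty$ffq), 0)
})

test_that("Harris-Benedict equation matches its published form", {
  expect_equal(harrisBenedictBmr("female", 70, 165, 30), 1489.48,
               tolerance = 1e-6)
  expect_equal(harrisBenedictBmr("male", 80, 180, 40),
               66.47 + 1100 + 900.54 - 270.2, tolerance = 1e-6)
  # linear in age: one extra year lowers female BMR by exactly 4.676
  expect_equal(harrisBenedictBmr(0, 70, 165, 31) -
                 harrisBenedictBmr(0, 70, 165, 30), -4.676)
  expect_error(harrisBenedictBmr(0, -1, 165, 30), "positive")
})

test_that("energy-ratio filter drops only genuine outliers", {
  # identical ratios: sd = 0, nothing excluded
  res <- excludeEnergyOutliers(rep(2000, 10), rep(1000, 10))
  expect_true(all(res$kept))
  # one extreme ratio among many near-identical ones
  energy <- c(rep(2000, 20), 9000)
  bmr <- rep(1000, 21)
  res <- excludeEnergyOutliers(energy, bmr)
  expect_equal(which(!res$kept), 21L)
  # infinite multiplier excludes nothing
  res <- excludeEnergyOutliers(rnorm(50, 2000, 300), rep(1000, 50),
                               sd_mult = Inf)
  expect_true(all(res$kept))
  expect_warning(excludeEnergyOutliers(2000, 1000), "fewer than 3")
})

test_that("food-group aggregation sums members and rejects double mapping", {
  ffq <- matrix(c(10, 5, 2, NA), 1, 4,
                dimnames = list("p1", paste0("item_", 1:4)))
  mapping <- data.frame(item = paste0("item_", 1:4),
                        group = c("g1", "g1", "g2", "g2"))
  out <- aggregateFoodGroups(ffq, mapping)
  expect_equal(out["p1", "g1"], 15) # 10 + 5
  expect_equal(out["p1", "g2"], 2) # unanswered treated as zero
  bad <- rbind(mapping, data.frame(item = "item_1", group = "g2"))
  expect_error(aggregateFoodGroups(ffq, bad), "more than one group")
})

test_that("residual energy adjustment has its closed-form properties", {
  expect_equal(energyAdjustResidual(c(1, 2, 3), c(1, 2, 3)), c(2, 2, 2))
  # intake proportional to energy collapses to the mean
  e <- c(1000, 1500, 2000, 2500)
  expect_equal(energyAdjustResidual(0.5 * e, e), rep(mean(0.5 * e), 4))
  # adjusted intake is orthogonal to energy, and adjustment is idempotent
  set.seed(1)
  intake <- rlnorm(200)
  energy <- rlnorm(200, 7)
  adj <- energyAdjustResidual(intake, energy)
  expect_lt(abs(cor(adj, energy)), 1e-10)
  expect_equal(energyAdjustResidual(adj, energy), adj, tolerance = 1e-12)
  expect_warning(energyAdjustResidual(intake[1:5], rep(2000, 5)), "constant")
})

test_that("inverse rank transform produces Blom normal scores", {
  got <- inverseRankTransform(c(5, 1, 3))
  expect_equal(got, qnorm((c(3, 1, 2) - 3 / 8) / 3.25), tolerance = 1e-12)
  expect_equal(got[2], -got[1], tolerance = 1e-12)
  expect_equal(got[3], 0, tolerance = 1e-12)
  # rank invariance: shuffling permutes the same multiset of scores
  set.seed(2)
  x <- rnorm(50)
  perm <- sample(50)
  expect_equal(inverseRankTransform(x)[perm], inverseRankTransform(x[perm]))
  # symmetric two-point case
  expect_equal(sum(inverseRankTransform(c(2, 8))), 0, tolerance = 1e-12)
  expect_error(inverseRankTransform(rep(1, 10)), "distinct")
  # near-normality of the scores at n >= 200
  z <- inverseRankTransform(rlnorm(300))
  skew <- mean(z^3) / sd(z)^3
  expect_lt(abs(skew), 0.2)
  expect_lt(abs(mean(z)), 1e-10)
})

test_that("prepared diet pipeline fixes the exclusion order and scale", {
  b <- smallCohorts()$discovery
  d <- prepareDiet(b)
  expect_true(all(colnames(d$foodgroups) == foodGroupMeta()$group))
  expect_false(any(is.na(d$foodgroups)))
  # adjusted intakes are uncorrelated with energy within the cohort
  cors <- abs(cor(d$foodgroups, d$energy_kcal))
  expect_true(all(cors < 1e-8))
  # incompleteness exclusions happen before the energy-ratio filter
  reasons <- d$exclusions$reason
  if (length(reasons) > 1) {
    expect_true(!is.unsorted(match(reasons, c("incomplete_ffq",
                                              "energy_ratio_outlier"))))
  }
})
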