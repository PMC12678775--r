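test_that("PERMANOVA detects constructed separation and respects labels", {
  set.seed(30)
  n <- 60
  group <- rep(c(0, 1), each = n / 2)
  # near-disjoint dominant species between the two groups
  base <- matrix(rlnorm(n * 20, 0, 0.2), n, 20)
  base[group == 0, 1:10] <- base[group == 0, 1:10] * 100
  base[group == 1, 11:20] <- base[group == 1, 11:20] * 100
  rel <- relativeAbundance(base)
  d <- brayCurtis(rel)
  covars <- data.frame(age = rnorm(n), sex = rbinom(n, 1, 0.5),
                       bmi = rnorm(n))
  res <- permanova(d, covars, group, n_perm = 999, seed = 1)
  expect_equal(res$term$p_perm, 1 / 1000) # minimum attainable
  expect_gt(res$term$R2, 0.5)
  # R2 of all fitted terms plus the residual sums to one
  fitted_rows <- setdiff(rownames(res$table), "Total")
  expect_equal(sum(res$table[fitted_rows, "R2"], na.rm = TRUE), 1,
               tolerance = 1e-9)
  # joint relabelling leaves R2 unchanged
  perm <- sample(n)
  res2 <- permanova(d[perm, perm], covars[perm, ], group[perm],
                    n_perm = 99, seed = 1)
  expect_equal(res2$term$R2, res$term$R2, tolerance = 1e-9)
  expect_error(permanova(d, covars, covars$age), "singular")
})

test_that("twin de-duplication keeps exactly one member per family", {
  fam <- c("a", "a", "b", "c", "c", "d")
  keep <- dedupTwins(fam, seed = 1)
  expect_equal(length(keep), 4)
  expect_false(any(duplicated(fam[keep])))
  expect_identical(keep, dedupTwins(fam, seed = 1))
})

test_that("weighted R2 pooling is a sample-size average", {
  expect_equal(weightedR2(c(0.02, 0.01), c(474, 219)),
               (0.02 * 474 + 0.01 * 219) / 693)
  expect_equal(weightedR2(c(0.3, 0.1), c(50, 50)), 0.2)
  expect_equal(weightedR2(0.25, 100), 0.25)
  expect_error(weightedR2(c(0.1), c(0)), "positive")
})

test_that("hypergeometric ORA matches exact tail enumeration", {
  background <- paste0("m", 1:100)
  pw <- list(pathA = background[1:10])
  hits <- c(background[1:5], background[50:64])
  res <- oraHypergeom(hits, pw, background)
  expect_equal(res$p, phyper(4, 10, 90, 20, lower.tail = FALSE),
               tolerance = 1e-12)
  # pathway equal to the background always overlaps: p = 1
  res_all <- oraHypergeom(hits, list(all = background), background)
  expect_equal(res_all$p, 1)
  # zero overlap: p = P[X >= 0] = 1
  res0 <- oraHypergeom(background[90:99], list(p = background[1:10]),
                       background)
  expect_equal(res0$p, 1)
  expect_error(oraHypergeom("zzz", pw, background), "subset")
  expect_error(oraHypergeom(hits, pw, character()), "empty")
  # brute-force oracle on small universes
  set.seed(31)
  for (i in 1:25) {
    N <- sample(10:30, 1)
    bg <- paste0("x", seq_len(N))
    set <- sample(bg, sample(2:(N - 2), 1))
    hit <- sample(bg, sample(2:(N - 2), 1))
    k <- length(intersect(hit, set))
    # enumerate all overlap counts at least as large
    brute <- sum(sapply(k:min(length(set), length(hit)), function(j) {
      choose(length(set), j) * choose(N - length(set), length(hit) - j)
    })) / choose(N, length(hit))
    got <- oraHypergeom(hit, list(s = set), bg)$p
    expect_equal(got, brute, tolerance = 1e-12)
  }
})

test_that("ACC distance counts signed commonality over the union", {
  s <- rbind(
    A = c(1, 0, -1, 0),
    B = c(1, 1, 0, 0),
    C = c(-1, 0, 1, 0),
    D = c(1, 0, -1, 0)
  )
  d <- accDistance(s)
  expect_equal(d["A", "B"], (1 - 1 / 3) / 2)
  expect_equal(d["A", "D"], 0)       # identical profiles
  expect_equal(d["A", "C"], 1)       # sign-flipped profiles
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  expect_error(accDistance(rbind(c(2, 0))), "entries")
  expect_warning(accDistance(rbind(A = c(1, 0), Z = c(0, 0))), "all-zero")
})

test_that("Ward clustering picks the silhouette-optimal k", {
  set.seed(32)
  pts <- rbind(matrix(rnorm(30, 0, 0.3), ncol = 2),
               matrix(rnorm(30, 6, 0.3), ncol = 2))
  d <- as.matrix(dist(pts))
  res <- wardClusterOptimal(d, k_range = 2:6)
  expect_equal(res$k, 2)
  expect_equal(length(unique(res$labels)), 2)
  # duplicated input gives identical labels
  res2 <- wardClusterOptimal(d, k_range = 2:6)
  expect_identical(res$labels, res2$labels)
  # all-equal distances: degenerate silhouette, smallest k wins
  eq <- matrix(1, 6, 6) - diag(6)
  res_eq <- wardClusterOptimal(eq, k_range = 2:4)
  expect_equal(res_eq$k, 2)
  expect_error(wardClusterOptimal(eq[1:2, 1:2]), "at least 3")
})
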