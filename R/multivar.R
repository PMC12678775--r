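#' Randomly keep one twin per family
#'
#' @param families family id per sample.
#' @param seed integer seed.
#' @return integer indices of the retained samples (one per family).
#' @export
dedupTwins <- function(families, seed = 1L) {
  set.seed(seed)
  shuffled <- sample(seq_along(families))
  keep <- shuffled[!duplicated(families[shuffled])]
  sort(keep)
}

#' PERMANOVA for one term conditional on covariates
#'
#' Sequential (order-dependent) sums of squares on the Gower-centred
#' distance matrix via `vegan::adonis2`, with the model built in the fixed
#' order age, sex, BMI, then the term of interest; the permutation p value
#' and R-squared refer to that final term. Samples should contain one twin
#' per family (see [dedupTwins()]).
#'
#' @param d dissimilarity matrix (e.g. [brayCurtis()]).
#' @param covariates data.frame with columns `age`, `sex`, `bmi` (or any
#'   covariate set; order preserved).
#' @param term numeric vector, the variable of interest.
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed for the permutation stream.
#' @return list with `term` statistics (`R2`, `pseudo_F`, `p_perm`,
#'   `n_perm`) and the full `table`.
#' @export
permanova <- function(d, covariates, term, n_perm = 10000, seed = 1L) {
  if (n_perm < 99) warning("fewer than 99 permutations")
  dat <- data.frame(covariates, .term = term)
  if (qr(as.matrix(dat))$rank < ncol(dat)) {
    stop("singular covariate/term matrix")
  }
  form <- stats::as.formula(
    paste("as.dist(d) ~", paste(colnames(covariates), collapse = " + "),
          "+ .term")
  )
  set.seed(seed)
  tab <- vegan::adonis2(form, data = dat, permutations = n_perm,
                        by = "terms")
  row <- match(".term", rownames(tab))
  list(
    term = data.frame(
      R2 = tab$R2[row], pseudo_F = tab$F[row], p_perm = tab$`Pr(>F)`[row],
      n_perm = n_perm
    ),
    table = as.data.frame(tab)
  )
}

#' Sample-size-weighted pooling of per-cohort R-squared values
#'
#' `sum(n_i R2_i) / sum(n_i)`.
#'
#' @param r2 per-cohort R-squared values.
#' @param n per-cohort sample sizes.
#' @return pooled R-squared.
#' @export
weightedR2 <- function(r2, n) {
  stopifnot(length(r2) == length(n))
  if (sum(n) <= 0) stop("total sample size must be positive")
  sum(n * r2) / sum(n)
}

#' Overrepresentation analysis by the hypergeometric tail
#'
#' For each pathway, the upper-tail probability of observing at least the
#' realised overlap between the hit set and the pathway within the
#' background universe (Fisher's exact test statistic for enrichment),
#' Bonferroni-corrected over the tested pathways.
#'
#' @param hits character vector of significant items (subset of background).
#' @param pathways named list of item sets.
#' @param background character vector, the measured universe.
#' @param alpha Bonferroni family-wise level for the `significant` flag.
#' @return data.frame with `pathway`, `overlap`, `size`, `p`,
#'   `p_bonferroni`, `significant`.
#' @export
oraHypergeom <- function(hits, pathways, background, alpha = 0.05) {
  if (!length(background)) stop("empty background")
  if (!all(hits %in% background)) stop("hits must be a subset of background")
  N <- length(background)
  n_hit <- length(intersect(hits, background))
  res <- lapply(names(pathways), function(pw) {
    set <- intersect(pathways[[pw]], background)
    K <- length(set)
    k <- length(intersect(hits, set))
    p <- phyper(k - 1, K, N - K, n_hit, lower.tail = FALSE)
    data.frame(pathway = pw, overlap = k, size = K, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_bonferroni <- pmin(out$p * nrow(out), 1)
  out$significant <- out$p_bonferroni < alpha
  out
}

#' Adjusted coefficient of commonality distance between signed profiles
#'
#' For two items with association profiles in `{-1, 0, +1}` over a set of
#' categories, ACC = (same-sign count - opposite-sign count) / size of the
#' union of nonzero categories, in `[-1, 1]`; the distance is
#' `(1 - ACC) / 2`. Items with all-zero profiles carry no information and
#' are dropped with a warning.
#'
#' @param signed item x category matrix with entries in `{-1, 0, +1}`.
#' @return item x item distance matrix in `[0, 1]`.
#' @export
accDistance <- function(signed) {
  signed <- as.matrix(signed)
  if (!all(signed %in% c(-1, 0, 1))) {
    stop("signed matrix entries must be -1, 0 or +1")
  }
  nonzero <- rowSums(signed != 0) > 0
  if (any(!nonzero)) {
    warning("dropping item(s) with all-zero profiles: ",
            paste(rownames(signed)[!nonzero], collapse = ", "))
    signed <- signed[nonzero, , drop = FALSE]
  }
  n <- nrow(signed)
  d <- matrix(0, n, n, dimnames = list(rownames(signed), rownames(signed)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      a <- signed[i, ]
      b <- signed[j, ]
      u <- a != 0 | b != 0
      same <- sum(a[u] == b[u] & a[u] != 0)
      opp <- sum(a[u] == -b[u] & a[u] != 0 & b[u] != 0)
      acc <- (same - opp) / sum(u)
      d[i, j] <- d[j, i] <- (1 - acc) / 2
    }
  }
  d
}

#' Ward clustering with silhouette-optimal cluster count
#'
#' Agglomerative clustering with Ward's linkage on a distance matrix; the
#' number of clusters maximising the mean silhouette width over `k_range`
#' is chosen (smallest k on ties, including the degenerate all-equal
#' case).
#'
#' @param d distance matrix.
#' @param k_range candidate cluster counts (subset of `2..n-1`).
#' @return list with `k`, `labels`, `silhouette` (mean width per k) and
#'   `hclust` (the dendrogram object).
#' @export
wardClusterOptimal <- function(d, k_range = 2:8) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3) stop("clustering requires at least 3 items")
  k_range <- k_range[k_range >= 2 & k_range <= n - 1]
  if (!length(k_range)) stop("empty k_range after bounds check")
  hc <- hclust(as.dist(d), method = "ward.D2")
  sil <- vapply(k_range, function(k) {
    lab <- cutree(hc, k)
    mean(cluster::silhouette(lab, dmatrix = d)[, "sil_width"])
  }, 0)
  k <- k_range[which.max(sil)] # first (smallest k) on ties
  list(k = k, labels = cutree(hc, k),
       silhouette = setNames(sil, k_range), hclust = hc)
}
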