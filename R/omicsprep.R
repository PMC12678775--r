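#' Run-day (block) normalisation of metabolite intensities
#'
#' Within each run day, each metabolite is divided by its run-day median
#' over non-missing values, so every compound's median is adjusted to 1
#' within every block; day-to-day multiplicative drift cancels. Run days
#' where a metabolite is entirely missing are left missing.
#'
#' @param mat sample x metabolite intensity matrix (`NA` = missing).
#' @param run_day run-day label per sample.
#' @return normalised matrix of the same shape.
#' @export
blockNormalize <- function(mat, run_day) {
  stopifnot(length(run_day) == nrow(mat))
  out <- mat
  for (d in unique(run_day)) {
    rows <- run_day == d
    med <- apply(mat[rows, , drop = FALSE], 2, median, na.rm = TRUE)
    med[!is.finite(med) | med == 0] <- 1
    out[rows, ] <- sweep(mat[rows, , drop = FALSE], 2, med, "/")
  }
  out
}

#' Minimum-value imputation with a missingness filter
#'
#' Metabolites with a missing fraction below `max_missing_frac` have their
#' missing cells imputed to the metabolite's observed minimum; metabolites
#' at or above the threshold are excluded (the boundary case is excluded,
#' the strict imputation band).
#'
#' @param mat sample x metabolite matrix with `NA` for missing.
#' @param max_missing_frac missingness threshold (default 0.20).
#' @return list with `mat` (imputed survivors) and `dropped` (character).
#' @export
imputeAndFilter <- function(mat, max_missing_frac = 0.20) {
  frac <- colMeans(is.na(mat))
  keep <- frac < max_missing_frac
  out <- mat[, keep, drop = FALSE]
  for (j in seq_len(ncol(out))) {
    miss <- is.na(out[, j])
    if (any(miss)) out[miss, j] <- min(out[, j], na.rm = TRUE)
  }
  list(mat = out, dropped = colnames(mat)[!keep],
       missing_frac = frac)
}

#' Inverse normal transformation of a metabolite matrix
#'
#' Applies the rank-based inverse normal transformation
#' ([inverseRankTransform()]) to every metabolite column; constant columns
#' are dropped with a warning.
#'
#' @param mat imputed sample x metabolite matrix.
#' @return transformed matrix.
#' @export
inverseNormalMetabolites <- function(mat) {
  const <- apply(mat, 2, function(v) length(unique(v[!is.na(v)])) < 2)
  if (any(const)) {
    warning("dropping constant metabolite(s): ",
            paste(colnames(mat)[const], collapse = ", "))
    mat <- mat[, !const, drop = FALSE]
  }
  out <- apply(mat, 2, inverseRankTransform)
  dimnames(out) <- dimnames(mat)
  out
}

#' Prevalence filter for species
#'
#' Retains species present (abundance > 0) in strictly more than
#' `min_prev` of samples.
#'
#' @param mat sample x species abundance matrix (counts or proportions).
#' @param min_prev prevalence threshold (default 0.10).
#' @return filtered matrix.
#' @export
prevalenceFilter <- function(mat, min_prev = 0.10) {
  prev <- colMeans(mat > 0)
  mat[, prev > min_prev, drop = FALSE]
}

#' Close species counts to relative abundances
#'
#' @param counts sample x species nonnegative matrix with positive row sums.
#' @return matrix with rows summing to 1.
#' @export
relativeAbundance <- function(counts) {
  if (any(counts < 0)) stop("abundances must be nonnegative")
  rs <- rowSums(counts)
  if (any(rs <= 0)) stop("samples with zero total abundance")
  counts / rs
}

#' Centred log-ratio transform
#'
#' Per sample, `log(x_i / g(x))` with `g` the geometric mean, after
#' replacing zeros by a pseudocount (default: half the smallest nonzero
#' relative abundance in the matrix). Output rows sum to zero.
#'
#' @param rel sample x species relative-abundance matrix.
#' @param pseudocount zero replacement; `NULL` for the default rule.
#' @return real-valued matrix of the same shape.
#' @export
clrTransform <- function(rel, pseudocount = NULL) {
  if (any(rel < 0)) stop("abundances must be nonnegative")
  if (is.null(pseudocount)) {
    nz <- rel[rel > 0]
    if (!length(nz)) stop("all-zero composition matrix")
    pseudocount <- min(nz) / 2
  }
  x <- rel
  x[x == 0] <- pseudocount
  lg <- log(x)
  sweep(lg, 1, rowMeans(lg), "-")
}

#' Shannon diversity index
#'
#' Community entropy `-sum p_i ln p_i` in nats after renormalising the
#' abundance vector; maximal (`ln` richness) at the uniform composition.
#'
#' @param x abundance vector, or a sample x species matrix (per-row index).
#' @return numeric value (or vector for a matrix input).
#' @export
shannonIndex <- function(x) {
  if (is.matrix(x)) {
    if (any(rowSums(x) <= 0)) stop("all-zero sample")
    return(vegan::diversity(x, index = "shannon"))
  }
  if (sum(x) <= 0) stop("all-zero sample")
  as.numeric(vegan::diversity(rbind(x), index = "shannon"))
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d(u, v) = sum |u_i - v_i| / sum (u_i + v_i)`; symmetric, zero diagonal,
#' in `[0, 1]` for nonnegative data.
#'
#' @param mat sample x species abundance matrix with positive row sums.
#' @return dense sample x sample dissimilarity matrix.
#' @export
brayCurtis <- function(mat) {
  if (any(mat < 0)) stop("abundances must be nonnegative")
  if (any(rowSums(mat) <= 0)) stop("all-zero sample(s); Bray-Curtis undefined")
  as.matrix(vegan::vegdist(mat, method = "bray"))
}

# minimal DBSCAN on a 2-column coordinate matrix
dbscan2d <- function(xy, eps, min_pts) {
  n <- nrow(xy)
  d <- as.matrix(dist(xy))
  labels <- rep(0L, n) # 0 = unvisited/noise
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L) next
    nb <- which(d[i, ] <= eps)
    if (length(nb) < min_pts) {
      labels[i] <- -1L
      next
    }
    cl <- cl + 1L
    labels[i] <- cl
    queue <- setdiff(nb, i)
    while (length(queue)) {
      j <- queue[1]
      queue <- queue[-1]
      if (labels[j] == -1L) labels[j] <- cl
      if (labels[j] != 0L) next
      labels[j] <- cl
      nb_j <- which(d[j, ] <= eps)
      if (length(nb_j) >= min_pts) queue <- c(queue, setdiff(nb_j, j))
    }
  }
  labels
}

#' Flag ecologically abnormal samples in ordination space
#'
#' Embeds the dissimilarity matrix by principal coordinate analysis
#' (eigendecomposition of the double-centred `-d^2/2` matrix, negative
#' eigenvalues dropped) and runs density-based clustering on the first two
#' axes; samples outside the largest density cluster are flagged.
#'
#' @param d sample x sample dissimilarity matrix.
#' @param min_pts DBSCAN core-point neighbourhood size (default 5).
#' @param eps DBSCAN radius; `NULL` picks the k-distance elbow (largest
#'   second difference of the sorted `min_pts`-nearest-neighbour distances).
#' @return logical vector, `TRUE` for flagged samples.
#' @export
pcoaOutlierFlag <- function(d, min_pts = 5, eps = NULL) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 4) return(rep(FALSE, n))
  xy <- cmdscale(as.dist(d), k = 2)
  if (is.null(eps)) {
    dd <- as.matrix(dist(xy))
    kdist <- sort(apply(dd, 1, function(r) sort(r)[min(min_pts + 1, n)]))
    elbow <- if (n >= 5) {
      kdist[which.max(diff(kdist, differences = 2)) + 1]
    } else {
      median(kdist)
    }
    # floor at a multiple of the typical neighbourhood radius so that a
    # homogeneous cloud is never carved into spurious outliers
    eps <- max(elbow, 3 * median(kdist), 1e-12)
  }
  labels <- dbscan2d(xy, eps = eps, min_pts = min_pts)
  if (all(labels <= 0)) return(rep(TRUE, n))
  main <- as.integer(names(which.max(table(labels[labels > 0]))))
  labels != main
}

#' Process a cohort's omics blocks into analysis-ready matrices
#'
#' Canonical preprocessing order: run-day normalisation, then minimum-value
#' imputation with the missingness filter, then the inverse normal
#' transformation (metabolites); closure, prevalence filter and CLR
#' transform plus Shannon diversity and Bray-Curtis dissimilarities
#' (species).
#'
#' @param bundle a [CohortBundle-class].
#' @param ids participant ids to retain (e.g. FFQ survivors); default all.
#' @param max_missing_frac,min_prev filter thresholds.
#' @param species also process the microbiome block (set `FALSE` for
#'   metabolome-only analyses to skip the dissimilarity and ordination
#'   work).
#' @return list with `metabolites` (inverse-normal matrix), `dropped`
#'   metabolites and, when `species = TRUE`, `species_rel`, `species_clr`,
#'   `shannon`, `bray` and `outlier_flags`.
#' @export
prepareOmics <- function(bundle, ids = NULL, max_missing_frac = 0.20,
                         min_prev = 0.10, species = TRUE) {
  p <- participants(bundle)
  if (is.null(ids)) ids <- p$participant_id
  rows <- match(ids, p$participant_id)
  met <- metaboliteIntensities(bundle)[rows, , drop = FALSE]
  norm <- blockNormalize(met, runDays(bundle)[rows])
  imp <- imputeAndFilter(norm, max_missing_frac)
  met_int <- inverseNormalMetabolites(imp$mat)
  out <- list(metabolites = met_int, dropped = imp$dropped)
  if (species) {
    rel_all <- relativeAbundance(speciesCounts(bundle)[rows, , drop = FALSE])
    rel <- prevalenceFilter(rel_all, min_prev)
    bray <- brayCurtis(rel)
    out$species_rel <- rel
    out$species_clr <- clrTransform(rel)
    out$shannon <- shannonIndex(rel_all)
    out$bray <- bray
    out$outlier_flags <- pcoaOutlierFlag(bray)
  }
  out
}
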