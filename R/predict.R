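#' Top/bottom quartile labels for a score vector
#'
#' The bottom quarter of samples (by stable sort order, so boundary ties
#' are resolved deterministically) is labelled 0, the top quarter 1, and
#' the middle half is `NA` (excluded from classification).
#'
#' @param scores numeric vector (length >= 8, not constant).
#' @return integer vector of 0/1/NA labels.
#' @export
quartileLabels <- function(scores) {
  n <- length(scores)
  if (n < 8) stop("quartile labelling requires at least 8 scores")
  if (length(unique(scores)) < 2) stop("constant scores")
  k <- floor(n / 4)
  ord <- order(scores) # stable: ties keep original order
  labels <- rep(NA_integer_, n)
  labels[ord[seq_len(k)]] <- 0L
  labels[ord[seq(n - k + 1, n)]] <- 1L
  labels
}

#' Twin-aware train/test split with class balancing
#'
#' Randomises at the family level so that twin pairs never straddle the
#' train/test boundary. For classification, the majority class is randomly
#' down-sampled before splitting and each side is further down-sampled so
#' that train and test both have exactly equal class counts.
#'
#' @param labels 0/1 labels (classification) or numeric outcomes
#'   (regression, `balance = FALSE`); `NA` entries are dropped.
#' @param families family id per sample.
#' @param train_frac fraction of samples in the training set.
#' @param seed integer seed.
#' @param balance enforce equal class counts (classification).
#' @return list with integer index vectors `train`, `test` and `dropped`.
#' @export
twinAwareSplit <- function(labels, families, train_frac = 0.8, seed = 1L,
                           balance = TRUE) {
  set.seed(seed)
  idx <- which(!is.na(labels))
  if (balance) {
    tab <- table(labels[idx])
    if (length(tab) != 2) stop("balanced split requires two classes")
    n_min <- min(tab)
    if (n_min < 2) stop("class too small to balance")
    keep <- unlist(lapply(names(tab), function(cl) {
      cl_idx <- idx[labels[idx] == cl]
      if (length(cl_idx) > n_min) sort(sample(cl_idx, n_min)) else cl_idx
    }))
    idx <- sort(keep)
  }
  fam <- as.character(families[idx])
  fam_levels <- sample(unique(fam)) # random family order
  if (balance) {
    # greedy class-aware family assignment: a family joins the training
    # side while per-class training targets are unmet
    classes <- sort(unique(labels[idx]))
    target <- floor(train_frac * table(factor(labels[idx], levels = classes)))
    train_count <- setNames(rep(0L, length(classes)), names(target))
    in_train <- logical(length(fam_levels))
    for (k in seq_along(fam_levels)) {
      members <- idx[fam == fam_levels[k]]
      add <- table(factor(labels[members], levels = classes))
      if (all(train_count + add <= target)) {
        in_train[k] <- TRUE
        train_count <- train_count + add
      }
    }
    train <- idx[fam %in% fam_levels[in_train]]
    test <- setdiff(idx, train)
    trim <- function(side) {
      l <- labels[side]
      n_keep <- min(table(factor(l, levels = classes)))
      unlist(lapply(classes, function(cl) {
        cl_idx <- side[l == cl]
        if (length(cl_idx) > n_keep) sort(sample(cl_idx, n_keep)) else cl_idx
      }))
    }
    train <- sort(trim(train))
    test <- sort(trim(test))
  } else {
    counts <- table(factor(fam, levels = fam_levels))
    cum <- cumsum(as.integer(counts))
    n_target <- train_frac * length(idx)
    n_train_fam <- which.min(abs(cum - n_target))
    train_fams <- fam_levels[seq_len(n_train_fam)]
    train <- idx[fam %in% train_fams]
    test <- setdiff(idx, train)
  }
  list(train = train, test = test,
       dropped = setdiff(seq_along(labels), c(train, test)))
}

rangerTask <- function(y) if (is.factor(y)) "classification" else "regression"

fitForest <- function(x, y, mtry = NULL, min_node = NULL, splitrule = NULL,
                      num_trees = 500, seed = 1L, importance = "none",
                      probability = NULL) {
  if (is.null(probability)) probability <- is.factor(y)
  args <- list(
    x = as.data.frame(x), y = y, num.trees = num_trees, seed = seed,
    num.threads = 1, importance = importance,
    probability = if (is.factor(y)) probability else FALSE,
    respect.unordered.factors = TRUE
  )
  if (!is.null(mtry)) args$mtry <- mtry
  if (!is.null(min_node)) args$min.node.size <- min_node
  if (!is.null(splitrule)) args$splitrule <- splitrule
  do.call(ranger::ranger, args)
}

predictForest <- function(model, x) {
  pr <- predict(model, data = as.data.frame(x), num.threads = 1)$predictions
  if (is.matrix(pr)) pr[, "1"] else pr
}

#' Boruta shadow-feature selection
#'
#' Iterative all-relevant feature selection: at each iteration every active
#' feature is duplicated as a permuted "shadow", a random forest is fitted
#' on the joint matrix, and a feature scores a hit when its importance
#' exceeds the maximum shadow importance. Hit counts are tested against a
#' Binomial(iterations, 0.5) null (two-sided, Bonferroni-adjusted over the
#' features still undecided at each check): features significantly above
#' chance are confirmed, features significantly below are rejected and
#' removed from subsequent iterations. Deterministic given the seed. Run on
#' the training partition only.
#'
#' @param x sample x feature matrix or data.frame.
#' @param y response: factor (classification) or numeric (regression).
#' @param max_iter maximum number of iterations (default 500; stops early
#'   once every feature is decided).
#' @param alpha decision level before the Bonferroni adjustment.
#' @param num_trees trees per iteration forest.
#' @param fix_tentative resolve features still undecided after `max_iter`
#'   by the rough fix: confirm a tentative feature whose median importance
#'   across its iterations exceeds the median of the maximum shadow
#'   importance (the reference algorithm's tentative resolution step).
#' @param seed integer seed.
#' @return list with `confirmed`, `rejected`, `tentative` feature names and
#'   the per-feature `hits`/`iterations` bookkeeping.
#' @export
borutaSelect <- function(x, y, max_iter = 500, alpha = 0.01, num_trees = 300,
                         fix_tentative = FALSE, seed = 1L) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("Boruta requires at least 2 features")
  set.seed(seed)
  features <- colnames(x)
  if (is.null(features)) features <- colnames(x) <- paste0("f", seq_len(ncol(x)))
  active <- features
  hits <- setNames(rep(0L, length(features)), features)
  iters <- setNames(rep(0L, length(features)), features)
  decided <- setNames(rep(NA_character_, length(features)), features)
  imp_hist <- lapply(setNames(features, features), function(f) numeric())
  shadow_hist <- numeric()
  check_every <- 10L
  for (it in seq_len(max_iter)) {
    if (!length(active)) break
    xa <- x[, active, drop = FALSE]
    shadow <- apply(xa, 2, sample)
    colnames(shadow) <- paste0(".shadow_", seq_len(ncol(shadow)))
    rf <- fitForest(cbind(xa, shadow), y, num_trees = num_trees,
                    seed = seed + it, importance = "impurity",
                    probability = FALSE)
    imp <- rf$variable.importance
    max_shadow <- max(imp[colnames(shadow)])
    shadow_hist <- c(shadow_hist, max_shadow)
    for (f in active) imp_hist[[f]] <- c(imp_hist[[f]], imp[[f]])
    hit <- imp[active] > max_shadow
    hits[active] <- hits[active] + as.integer(hit)
    iters[active] <- iters[active] + 1L
    if (it %% check_every == 0L || it == max_iter) {
      adj_alpha <- alpha / length(active) # adjust over undecided features
      for (f in active) {
        p_hi <- pbinom(hits[f] - 1L, iters[f], 0.5, lower.tail = FALSE)
        p_lo <- pbinom(hits[f], iters[f], 0.5)
        if (p_hi < adj_alpha) decided[f] <- "confirmed"
        if (p_lo < adj_alpha) decided[f] <- "rejected"
      }
      active <- features[is.na(decided)]
    }
  }
  decided[is.na(decided)] <- "tentative"
  if (fix_tentative && any(decided == "tentative")) {
    med_shadow <- median(shadow_hist)
    for (f in features[decided == "tentative"]) {
      if (median(imp_hist[[f]]) > med_shadow) decided[f] <- "confirmed"
    }
  }
  list(
    confirmed = features[decided == "confirmed"],
    rejected = features[decided == "rejected"],
    tentative = features[decided == "tentative"],
    hits = hits, iterations = iters
  )
}

#' Default random-forest hyperparameter grid
#'
#' mtry = square root of the feature count plus 10-50% of the feature
#' count, node sizes 5/10/15, and the split rules gini / extratrees /
#' hellinger (classification) or variance / extratrees / maxstat
#' (regression).
#'
#' @param p number of input features.
#' @param task `"classification"` or `"regression"`.
#' @return data.frame grid with columns `mtry`, `min_node`, `splitrule`.
#' @export
defaultGrid <- function(p, task = c("classification", "regression")) {
  task <- match.arg(task)
  mtry <- unique(pmax(1, c(floor(sqrt(p)),
                           floor(p * c(0.1, 0.2, 0.3, 0.4, 0.5)))))
  rules <- if (task == "classification") {
    c("gini", "extratrees", "hellinger")
  } else {
    c("variance", "extratrees", "maxstat")
  }
  expand.grid(mtry = mtry, min_node = c(5, 10, 15), splitrule = rules,
              stringsAsFactors = FALSE)
}

stratifiedFolds <- function(y, k) {
  folds <- integer(length(y))
  if (is.factor(y)) {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      folds[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
    }
  } else {
    ord <- order(y)
    chunk <- sample(rep(seq_len(k), length.out = length(y)))
    folds[ord] <- chunk
  }
  folds
}

#' Grid-search hyperparameter tuning by repeated cross-validation
#'
#' Repeated stratified k-fold cross-validation over a hyperparameter grid;
#' the winning cell (best mean accuracy for classification, lowest mean
#' RMSE for regression; ties broken by grid order) is refitted on the full
#' training data with permutation variable importance enabled.
#'
#' @param x training feature matrix.
#' @param y training response (factor or numeric).
#' @param grid hyperparameter grid (default [defaultGrid()]).
#' @param folds,repeats cross-validation design (defaults 5 x 10).
#' @param num_trees trees per forest.
#' @param seed integer seed.
#' @return list with `model` (final ranger fit), `best` (chosen grid row),
#'   and `cv` (per-cell mean metric).
#' @export
tuneAndFit <- function(x, y, grid = NULL, folds = 5, repeats = 10,
                       num_trees = 500, seed = 1L) {
  x <- as.matrix(x)
  task <- rangerTask(y)
  if (is.null(grid)) grid <- defaultGrid(ncol(x), task)
  if (!nrow(grid)) stop("empty hyperparameter grid")
  set.seed(seed)
  metric <- matrix(NA_real_, nrow(grid), folds * repeats)
  for (r in seq_len(repeats)) {
    fold_id <- stratifiedFolds(y, folds)
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      if (is.factor(y) && length(unique(y[!tr])) < 2) next
      for (g in seq_len(nrow(grid))) {
        rf <- fitForest(x[tr, , drop = FALSE], y[tr],
                        mtry = min(grid$mtry[g], ncol(x)),
                        min_node = grid$min_node[g],
                        splitrule = grid$splitrule[g],
                        num_trees = num_trees, seed = seed + 1000 * r + f,
                        probability = FALSE)
        pred <- predict(rf, data = as.data.frame(x[!tr, , drop = FALSE]),
                        num.threads = 1)$predictions
        metric[g, (r - 1) * folds + f] <- if (task == "classification") {
          mean(pred == y[!tr]) # accuracy
        } else {
          sqrt(mean((pred - y[!tr])^2)) # RMSE
        }
      }
    }
  }
  mean_metric <- rowMeans(metric, na.rm = TRUE)
  best_idx <- if (task == "classification") {
    which.max(mean_metric) # first max in grid order on ties
  } else {
    which.min(mean_metric)
  }
  model <- fitForest(x, y, mtry = min(grid$mtry[best_idx], ncol(x)),
                     min_node = grid$min_node[best_idx],
                     splitrule = grid$splitrule[best_idx],
                     num_trees = num_trees, seed = seed,
                     importance = "permutation")
  list(model = model, best = grid[best_idx, , drop = FALSE],
       cv = data.frame(grid, metric = mean_metric))
}

#' Area under the ROC curve by the rank statistic
#'
#' Mann-Whitney formulation: the probability that a random positive scores
#' above a random negative, counting ties as one half.
#'
#' @param probs predicted scores/probabilities.
#' @param labels 0/1 labels.
#' @return AUC in `[0, 1]`.
#' @export
aucRank <- function(probs, labels) {
  labels <- as.integer(as.character(labels))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("AUC undefined for a single-class set")
  r <- rank(probs)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

rocPoints <- function(probs, labels) {
  labels <- as.integer(as.character(labels))
  thr <- c(Inf, sort(unique(probs), decreasing = TRUE))
  tpr <- vapply(thr, function(t) mean(probs[labels == 1] >= t), 0)
  fpr <- vapply(thr, function(t) mean(probs[labels == 0] >= t), 0)
  data.frame(threshold = thr, tpr = tpr, fpr = fpr)
}

#' Evaluate a fitted model on held-out data
#'
#' Classification: AUC from predicted class probabilities with a bootstrap
#' percentile confidence interval (samples resampled jointly in
#' (prediction, truth) pairs) and the ROC curve. Regression: Spearman rank
#' correlation with a bootstrap percentile interval.
#'
#' @param model fitted ranger model (probability forest for classifiers).
#' @param x,y evaluation features and response.
#' @param n_boot bootstrap resamples for the confidence interval.
#' @param seed integer seed.
#' @return list with `metric` (`"auc"` or `"spearman"`), `estimate`, `ci`,
#'   `boot` (resampled estimates), `predictions`, and `roc` (classification).
#' @export
evaluateModel <- function(model, x, y, n_boot = 1000, seed = 1L) {
  set.seed(seed)
  pred <- predictForest(model, x)
  if (model$treetype == "Probability estimation") {
    labels <- as.integer(as.character(y))
    if (length(unique(labels)) < 2) stop("single-class evaluation set")
    est <- aucRank(pred, labels)
    boot <- vapply(seq_len(n_boot), function(b) {
      repeat {
        i <- sample(length(labels), replace = TRUE)
        if (length(unique(labels[i])) == 2) {
          return(aucRank(pred[i], labels[i]))
        }
      }
    }, 0)
    list(metric = "auc", estimate = est,
         ci = quantile(boot, c(0.025, 0.975), names = FALSE),
         boot = boot, predictions = pred, roc = rocPoints(pred, labels))
  } else {
    est <- cor(pred, y, method = "spearman")
    boot <- vapply(seq_len(n_boot), function(b) {
      i <- sample(length(y), replace = TRUE)
      suppressWarnings(cor(pred[i], y[i], method = "spearman"))
    }, 0)
    list(metric = "spearman", estimate = est,
         ci = quantile(boot, c(0.025, 0.975), names = FALSE, na.rm = TRUE),
         boot = boot, predictions = pred)
  }
}

#' Paired DeLong test for the difference of two correlated AUCs
#'
#' Placement-value formulation of DeLong, DeLong and Clarke-Pearson for two
#' classifiers evaluated on the same labelled samples; two-sided normal p.
#'
#' @param probs_a,probs_b predicted scores of the two classifiers.
#' @param labels shared 0/1 labels.
#' @return list with `auc_a`, `auc_b`, `z`, `p`.
#' @export
delongTest <- function(probs_a, probs_b, labels) {
  labels <- as.integer(as.character(labels))
  pos <- which(labels == 1)
  neg <- which(labels == 0)
  m <- length(pos)
  n <- length(neg)
  if (m == 0 || n == 0) stop("both classes required")
  placements <- function(probs) {
    v10 <- vapply(pos, function(i) {
      mean((probs[i] > probs[neg]) + 0.5 * (probs[i] == probs[neg]))
    }, 0)
    v01 <- vapply(neg, function(j) {
      mean((probs[pos] > probs[j]) + 0.5 * (probs[pos] == probs[j]))
    }, 0)
    list(v10 = v10, v01 = v01, auc = mean(v10))
  }
  pa <- placements(probs_a)
  pb <- placements(probs_b)
  s10 <- var(pa$v10 - pb$v10)
  s01 <- var(pa$v01 - pb$v01)
  v <- s10 / m + s01 / n
  d <- pa$auc - pb$auc
  if (!is.finite(v) || v <= 0) {
    if (abs(d) > 0) warning("degenerate DeLong variance with unequal AUCs")
    return(list(auc_a = pa$auc, auc_b = pb$auc, z = 0, p = 1))
  }
  z <- d / sqrt(v)
  list(auc_a = pa$auc, auc_b = pb$auc, z = z, p = 2 * pnorm(-abs(z)))
}

#' Bootstrap comparison of AUCs from two independent evaluation sets
#'
#' Each set is resampled with replacement `B` times (single-class resamples
#' are redrawn, up to 100 attempts, keeping `B` fixed) and the AUC
#' difference computed per iteration. The two-sided p value is the
#' proportion of iterations in which the null-centred difference
#' `|d_b - d_hat|` equals or exceeds the observed difference `|d_hat|`.
#'
#' @param probs_a,labels_a predictions and 0/1 labels of set A.
#' @param probs_b,labels_b predictions and labels of set B.
#' @param n_boot bootstrap iterations (default 1000; < 100 warns).
#' @param seed integer seed.
#' @return list with `auc_a`, `auc_b`, `diff`, `p`, `boot_diffs`.
#' @export
bootstrapAucCompare <- function(probs_a, labels_a, probs_b, labels_b,
                                n_boot = 1000, seed = 1L) {
  if (n_boot < 100) warning("fewer than 100 bootstrap iterations")
  set.seed(seed)
  labels_a <- as.integer(as.character(labels_a))
  labels_b <- as.integer(as.character(labels_b))
  auc_a <- aucRank(probs_a, labels_a)
  auc_b <- aucRank(probs_b, labels_b)
  d_hat <- auc_a - auc_b
  resample_auc <- function(probs, labels) {
    for (try in 1:100) {
      i <- sample(length(labels), replace = TRUE)
      if (length(unique(labels[i])) == 2) return(aucRank(probs[i], labels[i]))
    }
    stop("could not draw a two-class bootstrap resample")
  }
  diffs <- vapply(seq_len(n_boot), function(b) {
    resample_auc(probs_a, labels_a) - resample_auc(probs_b, labels_b)
  }, 0)
  p <- mean(abs(diffs - d_hat) >= abs(d_hat))
  list(auc_a = auc_a, auc_b = auc_b, diff = d_hat, p = p, boot_diffs = diffs)
}

#' Permutation variable importance
#'
#' With only a fitted model, returns ranger's out-of-bag permutation
#' importance (the model must have been fitted with
#' `importance = "permutation"`, as [tuneAndFit()] does). With evaluation
#' data, computes the mean drop in AUC (classification) or Spearman rho
#' (regression) over `repeats` permutations of each feature column.
#'
#' @param model fitted ranger model.
#' @param x,y optional evaluation data.
#' @param repeats permutation repeats per feature (default 10).
#' @param seed integer seed.
#' @return named importance vector, descending order.
#' @export
permutationImportance <- function(model, x = NULL, y = NULL, repeats = 10,
                                  seed = 1L) {
  if (is.null(x)) {
    imp <- ranger::importance(model)
    return(sort(imp, decreasing = TRUE))
  }
  set.seed(seed)
  x <- as.matrix(x)
  classif <- model$treetype == "Probability estimation"
  baseline <- if (classif) {
    aucRank(predictForest(model, x), y)
  } else {
    cor(predictForest(model, x), y, method = "spearman")
  }
  imp <- vapply(colnames(x), function(f) {
    drops <- vapply(seq_len(repeats), function(r) {
      xp <- x
      xp[, f] <- sample(xp[, f])
      m <- if (classif) aucRank(predictForest(model, xp), y)
           else cor(predictForest(model, xp), y, method = "spearman")
      baseline - m
    }, 0)
    mean(drops)
  }, 0)
  sort(imp, decreasing = TRUE)
}

#' Mean-masking recursive feature elimination
#'
#' Starting from the least important feature, features are cumulatively
#' neutralised by fixing their column at the training-set mean (the model
#' is never refitted) and the metric (AUC or Spearman rho) is recorded on
#' the held-out test set and the validation cohort at every step. The
#' minimal retained subset is the smallest feature set whose metric stays
#' within `tolerance` of the unmasked metric on both evaluation sets; at
#' least one feature is always retained.
#'
#' @param model fitted ranger model.
#' @param train_means named vector of training-set feature means.
#' @param importance named importance vector (descending), e.g. from
#'   [permutationImportance()].
#' @param x_test,y_test held-out test set.
#' @param x_val,y_val validation cohort.
#' @param tolerance allowed metric drop (default 0.05).
#' @return list with `trajectory` (data.frame: step, masked feature,
#'   n_retained, metric_test, metric_val), `subset` (retained features),
#'   `original_test`, `original_val`, `tolerance`.
#' @export
meanMaskRfe <- function(model, train_means, importance, x_test, y_test,
                        x_val, y_val, tolerance = 0.05) {
  if (tolerance < 0) stop("tolerance must be nonnegative")
  classif <- model$treetype == "Probability estimation"
  metric <- function(x, y) {
    if (classif) aucRank(predictForest(model, x), y)
    else cor(predictForest(model, x), y, method = "spearman")
  }
  x_test <- as.matrix(x_test)
  x_val <- as.matrix(x_val)
  feats <- names(sort(importance, decreasing = TRUE))
  stopifnot(all(feats %in% colnames(x_test)), all(feats %in% names(train_means)))
  orig_test <- metric(x_test, y_test)
  orig_val <- metric(x_val, y_val)
  mask_order <- rev(feats) # least important first
  steps <- length(mask_order)
  traj <- data.frame(
    step = 0:(steps - 1),
    masked = c(NA_character_, mask_order[seq_len(steps - 1)]),
    n_retained = steps:1,
    metric_test = NA_real_, metric_val = NA_real_,
    stringsAsFactors = FALSE
  )
  xt <- x_test
  xv <- x_val
  traj$metric_test[1] <- orig_test
  traj$metric_val[1] <- orig_val
  for (s in seq_len(steps - 1)) {
    f <- mask_order[s]
    xt[, f] <- train_means[f]
    xv[, f] <- train_means[f]
    traj$metric_test[s + 1] <- metric(xt, y_test)
    traj$metric_val[s + 1] <- metric(xv, y_val)
  }
  ok <- traj$metric_test >= orig_test - tolerance &
    traj$metric_val >= orig_val - tolerance
  best_step <- max(traj$step[ok]) # most masking that still satisfies both
  subset <- feats[seq_len(steps - best_step)]
  list(trajectory = traj, subset = subset,
       original_test = orig_test, original_val = orig_val,
       tolerance = tolerance)
}

#' Union panel of minimal feature subsets
#'
#' Unique union of the minimal subsets across a collection of RFE results,
#' excluding covariates (age, sex, BMI) from the panel.
#'
#' @param rfe_results list of [meanMaskRfe()] results (or plain character
#'   vectors of features).
#' @param covariates covariate names excluded from the panel.
#' @return character vector of panel features.
#' @export
buildPanel <- function(rfe_results, covariates = c("age", "sex", "bmi")) {
  if (!length(rfe_results)) return(character())
  subsets <- lapply(rfe_results, function(r) {
    if (is.character(r)) r else r$subset
  })
  setdiff(unique(unlist(subsets)), covariates)
}

#' Full prediction workflow for one dietary target
#'
#' Twin-aware balanced split on the discovery cohort, Boruta feature
#' selection on the training partition, grid-tuned random forest,
#' evaluation on the held-out test set and the validation cohort, and
#' mean-masking RFE. Covariates are always appended to the selected
#' metabolites (the "metabolite model"); a covariate-only null model is
#' fitted alongside.
#'
#' @param metabolites discovery sample x metabolite matrix.
#' @param covariates discovery covariate matrix (columns like age/sex/bmi).
#' @param scores discovery target scores (classification uses top/bottom
#'   quartiles).
#' @param families discovery family ids.
#' @param metabolites_val,covariates_val,scores_val validation cohort data.
#' @param task `"classify_quartiles"` or `"regress"`.
#' @param use_boruta run Boruta selection (default TRUE).
#' @param boruta_iter,grid,folds,repeats,num_trees,n_boot,tolerance knobs
#'   passed through to the component steps.
#' @param seed integer seed.
#' @return list with `split`, `selected`, `fit`, `null_fit`, `eval_test`,
#'   `eval_val`, `null_eval_test`, `importance`, `rfe`, `delong_null`.
#' @export
dietPredict <- function(metabolites, covariates, scores, families,
                        metabolites_val, covariates_val, scores_val,
                        task = c("classify_quartiles", "regress"),
                        use_boruta = TRUE, boruta_iter = 500, grid = NULL,
                        folds = 5, repeats = 10, num_trees = 500,
                        n_boot = 1000, tolerance = 0.05, seed = 1L) {
  task <- match.arg(task)
  classif <- task == "classify_quartiles"
  if (classif) {
    labels <- quartileLabels(scores)
    labels_val <- quartileLabels(scores_val)
    split <- twinAwareSplit(labels, families, seed = seed, balance = TRUE)
    y_train <- factor(labels[split$train], levels = c(0, 1))
    y_test <- factor(labels[split$test], levels = c(0, 1))
    val_keep <- which(!is.na(labels_val))
    y_val <- factor(labels_val[val_keep], levels = c(0, 1))
  } else {
    split <- twinAwareSplit(scores, families, seed = seed, balance = FALSE)
    y_train <- scores[split$train]
    y_test <- scores[split$test]
    val_keep <- seq_along(scores_val)
    y_val <- scores_val
  }
  x_all <- cbind(metabolites, covariates)
  x_val_all <- cbind(metabolites_val, covariates_val)
  selected <- colnames(metabolites)
  if (use_boruta) {
    bs <- borutaSelect(x_all[split$train, , drop = FALSE], y_train,
                       max_iter = boruta_iter, seed = seed)
    selected <- setdiff(bs$confirmed, colnames(covariates))
  } else {
    bs <- NULL
  }
  feat <- c(selected, colnames(covariates))
  x_train <- x_all[split$train, feat, drop = FALSE]
  fit <- tuneAndFit(x_train, y_train, grid = grid, folds = folds,
                    repeats = repeats, num_trees = num_trees, seed = seed)
  null_fit <- tuneAndFit(covariates[split$train, , drop = FALSE], y_train,
                         grid = grid, folds = folds, repeats = repeats,
                         num_trees = num_trees, seed = seed)
  eval_test <- evaluateModel(fit$model, x_all[split$test, feat, drop = FALSE],
                             y_test, n_boot = n_boot, seed = seed)
  eval_val <- evaluateModel(fit$model,
                            x_val_all[val_keep, feat, drop = FALSE],
                            y_val, n_boot = n_boot, seed = seed)
  null_eval_test <- evaluateModel(null_fit$model,
                                  covariates[split$test, , drop = FALSE],
                                  y_test, n_boot = n_boot, seed = seed)
  delong_null <- if (classif) {
    delongTest(eval_test$predictions, null_eval_test$predictions, y_test)
  } else {
    NULL
  }
  imp <- permutationImportance(fit$model)
  rfe <- meanMaskRfe(
    fit$model, train_means = colMeans(x_train), importance = imp,
    x_test = x_all[split$test, feat, drop = FALSE], y_test = y_test,
    x_val = x_val_all[val_keep, feat, drop = FALSE], y_val = y_val,
    tolerance = tolerance
  )
  list(split = split, boruta = bs, selected = selected, fit = fit,
       null_fit = null_fit, eval_test = eval_test, eval_val = eval_val,
       null_eval_test = null_eval_test, importance = imp, rfe = rfe,
       delong_null = delong_null)
}
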