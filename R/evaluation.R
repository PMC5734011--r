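# Performance assessment: confusion metrics, ROC/AUC, stratified
# k-fold cross-validation, grid search, and group-wise feature tests.
#
# Positives are cassette exons (class 1), negatives constitutive
# exons (class 0): Sn = TP/(TP+FN), Sp = TN/(TN+FP),
# TA = (TP+TN)/(TP+TN+FN+FP).

#' Confusion-matrix metrics
#'
#' @param truth,pred Equal-length binary label vectors (0/1 or
#'   cassette/constitutive; cassette = positive).
#' @return List of class `eval_metrics`: counts `TP`, `FN`, `FP`, `TN`
#'   and rates `Sn`, `Sp`, `TA` (a rate whose denominator is zero is
#'   `NA`).
#' @export
confusion_metrics <- function(truth, pred) {
  truth <- as_binary_labels(truth)
  pred <- as_binary_labels(pred)
  if (length(truth) != length(pred)) stop("label vectors differ in length")
  tp <- sum(truth == 1L & pred == 1L)
  fn <- sum(truth == 1L & pred == 0L)
  fp <- sum(truth == 0L & pred == 1L)
  tn <- sum(truth == 0L & pred == 0L)
  structure(
    list(TP = tp, FN = fn, FP = fp, TN = tn,
         Sn = if (tp + fn > 0L) tp / (tp + fn) else NA_real_,
         Sp = if (tn + fp > 0L) tn / (tn + fp) else NA_real_,
         TA = (tp + tn) / length(truth)),
    class = "eval_metrics"
  )
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat(sprintf("TP=%d FN=%d FP=%d TN=%d | Sn=%.4f Sp=%.4f TA=%.4f\n",
              x$TP, x$FN, x$FP, x$TN, x$Sn, x$Sp, x$TA))
  invisible(x)
}

#' ROC curve and AUC
#'
#' AUC is computed by the rank statistic: the probability that a random
#' positive outscores a random negative, ties counted one half. ROC
#' points are evaluated at every distinct score threshold.
#'
#' @param scores Numeric classifier scores (higher = more positive).
#' @param truth Binary labels with at least one positive and one
#'   negative.
#' @return List with `auc` and `roc`, a data.frame of `threshold`,
#'   `fpr`, `tpr` (including the (0,0) and (1,1) endpoints).
#' @export
roc_auc <- function(scores, truth) {
  truth <- as_binary_labels(truth)
  stopifnot(length(scores) == length(truth))
  n_pos <- sum(truth == 1L)
  n_neg <- sum(truth == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("ROC needs at least one positive and one negative")
  }
  r <- rank(scores)
  auc <- (sum(r[truth == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & truth == 1L) / n_pos, 0)
  fpr <- vapply(thr, function(t) sum(scores >= t & truth == 0L) / n_neg, 0)
  roc <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
  if (roc$fpr[nrow(roc)] < 1 || roc$tpr[nrow(roc)] < 1) {
    roc <- rbind(roc, data.frame(threshold = -Inf, fpr = 1, tpr = 1))
  }
  list(auc = auc, roc = roc)
}

#' Plan a (stratified) k-fold split
#'
#' Folds partition `1..n`, sizes differ by at most one, and with
#' stratification each fold's class proportions differ from the global
#' ones by at most one sample. Deterministic given `seed`.
#'
#' @param n Number of rows.
#' @param k Number of folds, `2 <= k <= n`.
#' @param labels Labels for stratification (any coding), or `NULL`.
#' @param seed RNG seed.
#' @param stratified Stratify by `labels`.
#' @return List of class `fold_plan`: `k`, `folds` (list of test-row
#'   index vectors), `seed`, `stratified`.
#' @export
kfold_split <- function(n, k, labels = NULL, seed = 1L, stratified = TRUE) {
  stopifnot(k >= 2L, k <= n)
  restore_rng <- preserve_rng()
  on.exit(restore_rng())
  set.seed(as.integer(seed))
  stratified <- stratified && !is.null(labels)
  if (stratified && min(table(labels)) < k) {
    warning("a class has fewer members than k; falling back to a plain split")
    stratified <- FALSE
  }
  assign_fold <- integer(n)
  offset <- 0L
  groups <- if (stratified) {
    split(seq_len(n), labels)
  } else {
    list(seq_len(n))
  }
  for (g in groups) {
    g <- g[sample.int(length(g))]
    assign_fold[g] <- ((offset + seq_along(g) - 1L) %% k) + 1L
    offset <- offset + length(g)
  }
  structure(
    list(k = as.integer(k),
         folds = split(seq_len(n), assign_fold),
         seed = as.integer(seed), stratified = stratified),
    class = "fold_plan"
  )
}

#' Conditional-forest fitter for cross-validation
#'
#' A fitter is a list with functions `fit(x, y)` and
#' `predict(model, x)`; predict returns `prob` (positive-class score)
#' and `label`.
#'
#' @param ntree,mtry,alpha,min_node,seed Forest hyperparameters.
#' @return A fitter list.
#' @export
cforest_fitter <- function(ntree = 200L, mtry = 10L, alpha = 0.05,
                           min_node = 6L, seed = 1L) {
  list(
    fit = function(x, y) fit_forest(x, y, ntree = ntree, mtry = mtry,
                                    alpha = alpha, min_node = min_node,
                                    seed = seed),
    predict = function(model, x) {
      pr <- predict(model, x)
      list(prob = pr$prob[, "class1"], label = pr$label)
    }
  )
}

#' KNN fitter for cross-validation
#' @param k Number of neighbours.
#' @return A fitter list.
#' @export
knn_fitter <- function(k = 7L) {
  list(
    fit = function(x, y) list(x = x, y = y),
    predict = function(model, x) {
      pr <- knn_classify(model$x, model$y, x, k)
      list(prob = pr$vote_frac, label = pr$label)
    }
  )
}

#' Gini random-forest fitter for cross-validation
#' @param ntree,mtry,seed Forest hyperparameters.
#' @return A fitter list.
#' @export
gini_forest_fitter <- function(ntree = 500L, mtry = NULL, seed = 1L) {
  list(
    fit = function(x, y) fit_gini_forest(x, y, ntree = ntree, mtry = mtry,
                                         seed = seed),
    predict = function(model, x) {
      pr <- predict(model, x)
      list(prob = pr$prob[, "class1"], label = pr$label)
    }
  )
}

#' Stratified k-fold cross-validation on a feature matrix
#'
#' Min-max scaling parameters are re-fit on each training fold and
#' applied to its test fold, so no information leaks across folds.
#' AUC is computed on the pooled out-of-fold predictions.
#'
#' @param fitter A fitter list, e.g. [cforest_fitter()].
#' @param x Numeric feature matrix or feature data.frame.
#' @param y Labels; taken from `x$label` when `x` is a feature
#'   data.frame and `y` is missing.
#' @param k Number of folds.
#' @param seed RNG seed for the fold plan.
#' @param stratified Stratify folds by class.
#' @param scale Re-fit min-max scaling per training fold.
#' @return List with `folds` (per-fold Sn/Sp/TA data.frame), `mean`,
#'   `sd`, pooled `auc`, `predictions`, and the `plan`.
#' @export
cross_validate <- function(fitter, x, y, k = 10L, seed = 1L,
                           stratified = TRUE, scale = TRUE) {
  if (is.data.frame(x) && all(c("id", "label") %in% names(x))) {
    xy <- feature_xy(x)
    if (missing(y)) y <- xy$y
    x <- xy$x
  }
  x <- as.matrix(x)
  y <- as_binary_labels(y)
  plan <- kfold_split(nrow(x), k, y, seed, stratified)
  score <- numeric(nrow(x))
  pred <- integer(nrow(x))
  per_fold <- vector("list", plan$k)
  for (f in seq_len(plan$k)) {
    te <- plan$folds[[f]]
    tr <- setdiff(seq_len(nrow(x)), te)
    xtr <- x[tr, , drop = FALSE]
    xte <- x[te, , drop = FALSE]
    if (scale) {
      params <- fit_feature_scaling(xtr)
      xtr <- apply_feature_scaling(xtr, params)
      xte <- apply_feature_scaling(xte, params)
    }
    model <- fitter$fit(xtr, y[tr])
    out <- fitter$predict(model, xte)
    score[te] <- out$prob
    pred[te] <- out$label
    m <- confusion_metrics(y[te], out$label)
    per_fold[[f]] <- data.frame(fold = f, Sn = m$Sn, Sp = m$Sp, TA = m$TA)
  }
  folds <- do.call(rbind, per_fold)
  list(
    folds = folds,
    mean = colMeans(folds[, c("Sn", "Sp", "TA")], na.rm = TRUE),
    sd = apply(folds[, c("Sn", "Sp", "TA")], 2L, stats::sd, na.rm = TRUE),
    auc = roc_auc(score, y)$auc,
    predictions = data.frame(row = seq_len(nrow(x)), truth = y,
                             score = score, label = pred),
    plan = plan
  )
}

#' Full-pipeline cross-validation over exons
#'
#' Cross-validates the complete pipeline without leakage: within each
#' fold, splice-site models are trained on the training exons only,
#' features are extracted for both partitions under those models,
#' scaling is fit on the training rows, and the classifier is fit and
#' evaluated. Exons whose splice scores are unavailable (clipped
#' flanks, `N` windows) are dropped with a message.
#'
#' @param genome Named character vector from [read_fasta()].
#' @param exons Exon table with cassette/constitutive labels.
#' @param fitter A fitter list, e.g. [cforest_fitter()].
#' @param k Number of folds.
#' @param seed RNG seed.
#' @param flank_len Flank length for window extraction.
#' @param constraint_order MaxEnt constraint order.
#' @param max_decoys Decoy windows per splice model.
#' @return As [cross_validate()], plus the feature data.frame of the
#'   retained exons (`features`, scored under models trained on all of
#'   them, for downstream importance analysis).
#' @export
cross_validate_exons <- function(genome, exons, fitter, k = 10L, seed = 1L,
                                 flank_len = 50L, constraint_order = 2L,
                                 max_decoys = 3000L) {
  y_all <- as_binary_labels(exons$label)
  plan <- kfold_split(nrow(exons), k, y_all, seed, stratified = TRUE)
  score <- numeric(nrow(exons))
  pred <- rep(NA_integer_, nrow(exons))
  per_fold <- vector("list", plan$k)
  for (f in seq_len(plan$k)) {
    te <- plan$folds[[f]]
    tr <- setdiff(seq_len(nrow(exons)), te)
    models <- train_genome_splice_models(genome, exons[tr, , drop = FALSE],
                                         flank_len, constraint_order,
                                         max_decoys, seed = seed + f)
    ftr <- feature_matrix(genome, exons[tr, , drop = FALSE], models, flank_len)
    fte <- feature_matrix(genome, exons[te, , drop = FALSE], models, flank_len)
    keep_tr <- stats::complete.cases(ftr[, feature_cols(ftr)])
    keep_te <- stats::complete.cases(fte[, feature_cols(fte)])
    if (any(!keep_tr) || any(!keep_te)) {
      message("fold ", f, ": dropped ", sum(!keep_tr) + sum(!keep_te),
              " exon(s) with missing splice scores")
    }
    xtr <- as.matrix(ftr[keep_tr, feature_cols(ftr)])
    xte <- as.matrix(fte[keep_te, feature_cols(fte)])
    ytr <- y_all[tr][keep_tr]
    yte_idx <- te[keep_te]
    params <- fit_feature_scaling(xtr)
    model <- fitter$fit(apply_feature_scaling(xtr, params), ytr)
    out <- fitter$predict(model, apply_feature_scaling(xte, params))
    score[yte_idx] <- out$prob
    pred[yte_idx] <- out$label
    m <- confusion_metrics(y_all[yte_idx], out$label)
    per_fold[[f]] <- data.frame(fold = f, Sn = m$Sn, Sp = m$Sp, TA = m$TA)
  }
  ok <- !is.na(pred)
  folds <- do.call(rbind, per_fold)
  full_models <- train_genome_splice_models(genome, exons, flank_len,
                                            constraint_order, max_decoys,
                                            seed = seed)
  features <- feature_matrix(genome, exons, full_models, flank_len)
  list(
    folds = folds,
    mean = colMeans(folds[, c("Sn", "Sp", "TA")], na.rm = TRUE),
    sd = apply(folds[, c("Sn", "Sp", "TA")], 2L, stats::sd, na.rm = TRUE),
    auc = roc_auc(score[ok], y_all[ok])$auc,
    predictions = data.frame(row = which(ok), truth = y_all[ok],
                             score = score[ok], label = pred[ok]),
    plan = plan,
    features = features
  )
}

#' Exhaustive grid search by cross-validated total accuracy
#'
#' @param make_fitter Function called with one grid row's parameters
#'   (as named arguments) returning a fitter list.
#' @param grid Data.frame of parameter combinations (one row each).
#' @param x,y Feature matrix and labels as in [cross_validate()].
#' @param k,seed,... Passed to [cross_validate()].
#' @return List with `best` (first row attaining the maximal mean TA)
#'   and `results` (the grid with `mean_TA`, `mean_Sn`, `mean_Sp`,
#'   `auc` columns).
#' @export
grid_search <- function(make_fitter, grid, x, y, k = 10L, seed = 1L, ...) {
  if (!is.data.frame(grid) || nrow(grid) == 0L) stop("empty parameter grid")
  res <- grid
  res$mean_Sn <- res$mean_Sp <- res$mean_TA <- res$auc <- NA_real_
  for (i in seq_len(nrow(grid))) {
    fitter <- do.call(make_fitter, as.list(grid[i, , drop = FALSE]))
    cv <- cross_validate(fitter, x, y, k = k, seed = seed, ...)
    res$mean_Sn[i] <- cv$mean[["Sn"]]
    res$mean_Sp[i] <- cv$mean[["Sp"]]
    res$mean_TA[i] <- cv$mean[["TA"]]
    res$auc[i] <- cv$auc
  }
  list(best = res[which.max(res$mean_TA), , drop = FALSE], results = res)
}

#' Per-feature comparison between cassette and constitutive exons
#'
#' Class means and a two-sided Welch (unequal-variance) t-test per
#' feature, rows sorted by p-value. Features with zero variance in
#' both groups get `t = 0`, `p = 1` and `degenerate = TRUE`.
#'
#' @param x Feature data.frame (with `label`) or numeric matrix.
#' @param y Labels when `x` is a matrix.
#' @param adjust Add a Benjamini-Hochberg `p_adj` column.
#' @return Data.frame with `feature`, `mean_cassette`,
#'   `mean_constitutive`, `t`, `p`, `degenerate` (and optionally
#'   `p_adj`).
#' @export
compare_feature_groups <- function(x, y, adjust = FALSE) {
  if (is.data.frame(x) && all(c("id", "label") %in% names(x))) {
    xy <- feature_xy(x)
    if (missing(y)) y <- xy$y
    x <- xy$x
  }
  x <- as.matrix(x)
  y <- as_binary_labels(y)
  if (!any(y == 1L) || !any(y == 0L)) stop("both classes must be nonempty")
  rows <- lapply(seq_len(ncol(x)), function(j) {
    a <- x[y == 1L, j]
    b <- x[y == 0L, j]
    a <- a[!is.na(a)]
    b <- b[!is.na(b)]
    degenerate <- stats::var(a) == 0 && stats::var(b) == 0
    if (length(a) < 2L || length(b) < 2L || degenerate) {
      tt <- list(statistic = 0, p.value = 1)
      degenerate <- TRUE
    } else {
      tt <- stats::t.test(a, b, var.equal = FALSE)
    }
    data.frame(feature = colnames(x)[j],
               mean_cassette = mean(a), mean_constitutive = mean(b),
               t = unname(tt$statistic), p = tt$p.value,
               degenerate = degenerate, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p), , drop = FALSE]
  if (adjust) out$p_adj <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}
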