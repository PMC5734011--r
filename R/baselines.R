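# Baseline classifiers: k-nearest neighbours and a Gini random forest.

#' k-nearest-neighbour classification
#'
#' Euclidean-distance majority vote on (pre-scaled) feature rows.
#' Distance ties are broken toward the lower training-row index and
#' vote ties (even `k`) toward class 0, so the result is deterministic.
#'
#' @param train_x Numeric training matrix.
#' @param train_y Binary 0/1 (or cassette/constitutive) training labels.
#' @param test_x Numeric matrix of rows to classify.
#' @param k Number of neighbours, `1 <= k <= nrow(train_x)`.
#' @return List with integer `label` and `vote_frac`, the fraction of
#'   neighbours voting class 1 (usable as a ROC score).
#' @export
knn_classify <- function(train_x, train_y, test_x, k) {
  train_x <- as.matrix(train_x)
  test_x <- as.matrix(test_x)
  train_y <- as_binary_labels(train_y)
  n <- nrow(train_x)
  if (n == 0L) stop("empty training set")
  stopifnot(k >= 1L, k <= n, ncol(test_x) == ncol(train_x))
  # squared Euclidean distances, test rows x train rows
  d2 <- outer(rowSums(test_x^2), rowSums(train_x^2), "+") -
    2 * tcrossprod(test_x, train_x)
  vote <- apply(d2, 1L, function(d) {
    nb <- order(d, seq_len(n))[seq_len(k)]
    mean(train_y[nb])
  })
  list(label = as.integer(vote > 0.5), vote_frac = unname(vote))
}

#' Gini impurity of a class-proportion vector
#'
#' `1 - sum(p^2)`; 0 for a pure node, 0.5 for a balanced binary node.
#'
#' @param props Class proportions summing to 1.
#' @return Gini impurity.
#' @export
gini_impurity <- function(props) {
  stopifnot(abs(sum(props) - 1) < 1e-8)
  1 - sum(props^2)
}

#' Fit a Gini random-forest baseline
#'
#' Classical random forest: bootstrap sampling with replacement, CART
#' base trees splitting on Gini impurity, majority-vote aggregation,
#' and mean-decrease-in-Gini variable importance (delegated to the
#' \pkg{randomForest} package).
#'
#' @param x Numeric feature matrix or feature data.frame.
#' @param y Labels (0/1 or cassette/constitutive).
#' @param ntree Number of trees.
#' @param mtry Candidate variables per split; the default uses every
#'   feature (pure bagging), matching the tuned optimum of the
#'   companion conditional forest's plain-forest baseline.
#' @param seed RNG seed.
#' @return An object of class `gini_forest`: list with the fitted `rf`
#'   and an `importance` table (`feature`, `importance`, `rank`).
#' @export
fit_gini_forest <- function(x, y, ntree = 1000L, mtry = NULL, seed = 1L) {
  if (is.data.frame(x) && all(c("id", "label") %in% names(x))) {
    xy <- feature_xy(x)
    x <- xy$x
    if (missing(y)) y <- xy$y
  }
  x <- as.matrix(x)
  y <- as_binary_labels(y)
  if (ntree < 1L) stop("ntree must be >= 1")
  if (is.null(mtry)) mtry <- ncol(x)
  if (mtry < 1L || mtry > ncol(x)) stop("mtry must be in [1, ncol(x)]")
  restore_rng <- preserve_rng()
  on.exit(restore_rng())
  set.seed(as.integer(seed))
  rf <- randomForest::randomForest(x, factor(y, levels = c(0L, 1L)),
                                   ntree = ntree, mtry = mtry,
                                   importance = FALSE)
  gini <- randomForest::importance(rf, type = 2L)[, 1L]
  imp <- data.frame(feature = names(gini), importance = unname(gini),
                    rank = rank(-gini, ties.method = "first"),
                    stringsAsFactors = FALSE)
  structure(list(rf = rf, importance = imp, ntree = as.integer(ntree),
                 mtry = as.integer(mtry), seed = as.integer(seed)),
            class = "gini_forest")
}

#' @export
predict.gini_forest <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) {
    newdata <- as.matrix(newdata[, feature_cols(newdata), drop = FALSE])
  }
  prob <- stats::predict(object$rf, newdata, type = "prob")
  colnames(prob) <- c("class0", "class1")
  list(prob = prob,
       label = as.integer(as.character(stats::predict(object$rf, newdata))))
}
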