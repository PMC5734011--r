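# Conditional-inference forest with out-of-bag permutation importance.
#
# Each tree recursively tests the global null of independence between
# the candidate predictors and the binary response; splitting stops as
# soon as the (Bonferroni-adjusted) test accepts the null, so no
# pruning is needed and variable selection is not biased toward
# predictors with many cutpoints. Trees are grown on subsamples of
# ceiling(0.632 * n) rows drawn without replacement; the complement of
# each tree's subsample is its out-of-bag (oob) set. Forest predictions
# average leaf class proportions over trees. Variable importance is the
# mean over trees of the drop in oob accuracy after permuting one
# feature's oob values, optionally within strata defined by the tree's
# own split intervals on correlated covariates (conditional scheme).

#' Permutation test of association between a feature and binary labels
#'
#' Two-sided p-value for the standardized difference of class means
#' under the permutation null. For `length(x) <= exact_max` the
#' permutation distribution is enumerated exactly; otherwise the
#' asymptotic normal approximation is used. Degenerate inputs (single
#' class, constant feature) return p = 1.
#'
#' @param x Numeric feature values.
#' @param y Binary 0/1 labels of the same length.
#' @param exact_max Largest sample size for exact enumeration.
#' @return p-value in `(0, 1]`.
#' @export
association_pvalue <- function(x, y, exact_max = 10L) {
  n <- length(x)
  stopifnot(length(y) == n)
  n1 <- sum(y == 1L)
  if (n1 == 0L || n1 == n) return(1)
  xbar <- mean(x)
  ssq <- sum((x - xbar)^2)
  if (ssq == 0) return(1)
  t_obs <- sum(x[y == 1L])
  e_t <- n1 * xbar
  if (n <= exact_max) {
    sets <- utils::combn(n, n1)
    t_perm <- colSums(matrix(x[sets], nrow = n1))
    return(mean(abs(t_perm - e_t) >= abs(t_obs - e_t) - 1e-12))
  }
  v_t <- n1 * (n - n1) * ssq / (n * (n - 1))
  min(1, 2 * stats::pnorm(-abs((t_obs - e_t) / sqrt(v_t))))
}

# best threshold of one feature: maximizes the standardized two-sample
# statistic of the labels over midpoints of consecutive distinct values;
# ties -> lowest threshold; NULL when the feature is constant
best_split_threshold <- function(xv, y) {
  n <- length(xv)
  ord <- order(xv)
  xs <- xv[ord]
  ys <- y[ord]
  cuts <- which(xs[-n] < xs[-1L])
  if (!length(cuts)) return(NULL)
  csum <- cumsum(ys)[cuts]
  stat <- abs(csum - cuts * mean(y)) / sqrt(cuts * (n - cuts))
  b <- cuts[which.max(stat)]
  (xs[b] + xs[b + 1L]) / 2
}

#' Grow a single conditional-inference tree
#'
#' At each node, `mtry` candidate features are drawn without
#' replacement; the global independence null is tested per candidate
#' with [association_pvalue()] and Bonferroni-adjusted by `mtry`. The
#' node becomes a leaf when the adjusted minimum exceeds `alpha`, the
#' node is pure, or it holds fewer than `min_node` rows; otherwise the
#' most associated candidate is split at the threshold maximizing the
#' two-sample statistic.
#'
#' @param x Numeric feature matrix.
#' @param y Binary 0/1 labels.
#' @param mtry Candidate features per node (capped at `ncol(x)`).
#' @param alpha Significance level of the stopping test.
#' @param min_node Minimum node size eligible for splitting.
#' @return An object of class `ctree_model`: parallel node vectors
#'   `leaf`, `var`, `thr`, `left`, `right`, `p0`, `p1`, `pval`, `n`.
#' @export
grow_tree <- function(x, y, mtry, alpha = 0.05, min_node = 6L) {
  stopifnot(is.matrix(x), nrow(x) == length(y), nrow(x) >= 1L)
  p <- ncol(x)
  mtry <- min(as.integer(mtry), p)
  nodes <- list()
  add_node <- function(node) {
    nodes[[length(nodes) + 1L]] <<- node
    length(nodes)
  }
  build <- function(idx) {
    yi <- y[idx]
    n <- length(idx)
    n1 <- sum(yi)
    me <- add_node(list(leaf = TRUE, var = NA_integer_, thr = NA_real_,
                        left = NA_integer_, right = NA_integer_,
                        p0 = (n - n1) / n, p1 = n1 / n,
                        pval = NA_real_, n = n))
    if (n < min_node || n1 == 0L || n1 == n) return(me)
    cand <- sample.int(p, mtry)
    pv <- vapply(cand, function(j) association_pvalue(x[idx, j], yi), 0)
    p_adj <- min(1, min(pv) * mtry)
    nodes[[me]]$pval <<- p_adj
    if (p_adj > alpha) return(me)
    j <- cand[which.min(pv)]
    thr <- best_split_threshold(x[idx, j], yi)
    if (is.null(thr)) return(me)
    go_left <- x[idx, j] <= thr
    nodes[[me]]$leaf <<- FALSE
    nodes[[me]]$var <<- j
    nodes[[me]]$thr <<- thr
    nodes[[me]]$left <<- build(idx[go_left])
    nodes[[me]]$right <<- build(idx[!go_left])
    me
  }
  build(seq_along(y))
  structure(
    list(
      leaf = vapply(nodes, `[[`, TRUE, "leaf"),
      var = vapply(nodes, `[[`, 0L, "var"),
      thr = vapply(nodes, `[[`, 0, "thr"),
      left = vapply(nodes, `[[`, 0L, "left"),
      right = vapply(nodes, `[[`, 0L, "right"),
      p0 = vapply(nodes, `[[`, 0, "p0"),
      p1 = vapply(nodes, `[[`, 0, "p1"),
      pval = vapply(nodes, `[[`, 0, "pval"),
      n = vapply(nodes, `[[`, 0L, "n")
    ),
    class = "ctree_model"
  )
}

# leaf node index of every row of X under one tree
tree_leaf_index <- function(tree, X) {
  cur <- rep(1L, nrow(X))
  repeat {
    at_split <- which(!tree$leaf[cur])
    if (!length(at_split)) break
    nd <- cur[at_split]
    go_left <- X[cbind(at_split, tree$var[nd])] <= tree$thr[nd]
    cur[at_split] <- ifelse(go_left, tree$left[nd], tree$right[nd])
  }
  cur
}

# predicted positive-class proportion per row under one tree
tree_prob1 <- function(tree, X) tree$p1[tree_leaf_index(tree, X)]

# 0/1 labels from positive-class proportions (tie -> class 0)
prob_to_label <- function(p1) as.integer(p1 > 0.5)

#' Fit a conditional-inference forest
#'
#' Grows `ntree` conditional-inference trees, each on an independent
#' subsample of `ceiling(0.632 * n)` rows drawn without replacement;
#' the complement of each subsample is recorded as that tree's
#' out-of-bag set. Deterministic given `seed`.
#'
#' @param x Numeric feature matrix without missing values.
#' @param y Labels: 0/1 or `cassette`/`constitutive` (cassette = 1).
#' @param ntree Number of trees.
#' @param mtry Candidate features per node.
#' @param alpha Stopping significance level.
#' @param min_node Minimum splittable node size.
#' @param seed RNG seed.
#' @return An object of class `cforest_model`.
#' @export
fit_forest <- function(x, y, ntree = 1050L, mtry = 10L, alpha = 0.05,
                       min_node = 6L, seed = 1L) {
  if (is.data.frame(x) && all(c("id", "label") %in% names(x))) {
    xy <- feature_xy(x)
    x <- xy$x
    if (missing(y)) y <- xy$y
  }
  x <- as.matrix(x)
  y <- as_binary_labels(y)
  n <- nrow(x)
  p <- ncol(x)
  stopifnot(length(y) == n)
  if (anyNA(x)) stop("feature matrix contains missing values; impute or drop upstream")
  ntree <- as.integer(ntree)
  if (ntree < 1L) stop("ntree must be >= 1")
  if (mtry < 1L || mtry > p) stop("mtry must be in [1, ncol(x)]")
  restore_rng <- preserve_rng()
  on.exit(restore_rng())
  set.seed(as.integer(seed))
  m <- ceiling(0.632 * n)
  trees <- vector("list", ntree)
  train_sets <- vector("list", ntree)
  oob_sets <- vector("list", ntree)
  for (t in seq_len(ntree)) {
    tr <- sort(sample.int(n, m))
    trees[[t]] <- grow_tree(x[tr, , drop = FALSE], y[tr], mtry, alpha, min_node)
    train_sets[[t]] <- tr
    oob_sets[[t]] <- setdiff(seq_len(n), tr)
  }
  structure(
    list(trees = trees, train_sets = train_sets, oob_sets = oob_sets,
         ntree = ntree, mtry = as.integer(mtry), alpha = alpha,
         min_node = as.integer(min_node), seed = as.integer(seed),
         n = n, p = p, feature_names = colnames(x)),
    class = "cforest_model"
  )
}

#' Predict with a conditional-inference forest
#'
#' Class probabilities are the mean over trees of the leaf class
#' proportions; the label is the argmax with ties broken toward
#' class 0 (constitutive).
#'
#' @param object A `cforest_model`.
#' @param newdata Numeric matrix (or feature data.frame) with the
#'   training column layout.
#' @param ... Unused.
#' @return List with `prob` (matrix, columns `class0`, `class1`) and
#'   integer `label`.
#' @export
predict.cforest_model <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) {
    newdata <- as.matrix(newdata[, feature_cols(newdata), drop = FALSE])
  }
  if (ncol(newdata) != object$p) {
    stop("newdata has ", ncol(newdata), " columns; model expects ", object$p)
  }
  p1 <- rowMeans(vapply(object$trees, function(tr) tree_prob1(tr, newdata),
                        numeric(nrow(newdata))))
  prob <- cbind(class0 = 1 - p1, class1 = p1)
  list(prob = prob, label = prob_to_label(p1))
}

#' Out-of-bag accuracy of one tree
#'
#' Fraction of the tree's out-of-bag rows predicted correctly; `NA`
#' when the oob set is empty (such trees are skipped in importance
#' averaging).
#'
#' @param model A `cforest_model`.
#' @param tree_index Tree number.
#' @param x,y Training matrix and labels the model was fit on.
#' @return Accuracy in `[0, 1]`, or `NA`.
#' @export
oob_accuracy <- function(model, tree_index, x, y) {
  y <- as_binary_labels(y)
  oob <- model$oob_sets[[tree_index]]
  if (!length(oob)) return(NA_real_)
  pred <- prob_to_label(tree_prob1(model$trees[[tree_index]],
                                   x[oob, , drop = FALSE]))
  mean(pred == y[oob])
}

# split variables used anywhere in a tree
tree_used_vars <- function(tree) unique(tree$var[!tree$leaf])

# permutation of seq_len(n) within strata (a factor/interaction)
stratified_permutation <- function(strata) {
  idx <- seq_along(strata)
  for (lev in split(idx, strata)) {
    if (length(lev) > 1L) idx[lev] <- lev[sample.int(length(lev))]
  }
  idx
}

#' Out-of-bag permutation variable importance
#'
#' For each tree t and feature j, importance is the tree's oob accuracy
#' minus its oob accuracy after permuting column j among the oob rows;
#' the forest importance is the average over trees (trees with empty
#' oob sets are skipped). A feature used by no tree has importance
#' exactly 0. Under the conditional scheme, the permutation of column j
#' is performed within strata defined by the tree's own split
#' thresholds on covariates whose absolute Spearman correlation with
#' feature j exceeds `cor_threshold`, which removes importance that a
#' feature borrows from correlated informative covariates.
#'
#' @param model A `cforest_model`.
#' @param x,y Training matrix and labels the model was fit on.
#' @param conditional Use the conditional permutation scheme.
#' @param n_draws Permutation draws averaged per tree and feature.
#' @param cor_threshold Correlation threshold of the conditional scheme.
#' @param seed RNG seed for the permutations.
#' @return Data.frame with columns `feature`, `importance`, `rank`
#'   (ranks are a permutation of `1..p`); attribute `conditional`.
#' @export
permutation_importance <- function(model, x, y, conditional = FALSE,
                                   n_draws = 1L, cor_threshold = 0.2,
                                   seed = 1L) {
  stopifnot(inherits(model, "cforest_model"))
  x <- as.matrix(x)
  y <- as_binary_labels(y)
  p <- model$p
  restore_rng <- preserve_rng()
  on.exit(restore_rng())
  set.seed(as.integer(seed))
  cors <- NULL
  if (conditional) {
    cors <- abs(suppressWarnings(stats::cor(x, method = "spearman")))
    cors[is.na(cors)] <- 0  # constant columns
  }
  vi <- matrix(0, nrow = model$ntree, ncol = p)
  skip <- logical(model$ntree)
  for (t in seq_len(model$ntree)) {
    oob <- model$oob_sets[[t]]
    if (!length(oob)) {
      skip[t] <- TRUE
      next
    }
    tree <- model$trees[[t]]
    xo <- x[oob, , drop = FALSE]
    yo <- y[oob]
    base_acc <- mean(prob_to_label(tree_prob1(tree, xo)) == yo)
    used <- tree_used_vars(tree)
    for (j in used) {
      strata <- NULL
      if (conditional) {
        zs <- setdiff(used[cors[j, used] > cor_threshold], j)
        if (length(zs)) {
          cuts <- lapply(zs, function(z) {
            thr <- sort(unique(tree$thr[!tree$leaf & tree$var == z]))
            cut(xo[, z], breaks = c(-Inf, thr, Inf))
          })
          strata <- interaction(cuts, drop = TRUE)
        }
      }
      acc_perm <- mean(vapply(seq_len(n_draws), function(d) {
        perm <- if (is.null(strata)) {
          sample.int(length(oob))
        } else {
          stratified_permutation(strata)
        }
        xp <- xo
        xp[, j] <- xo[perm, j]
        mean(prob_to_label(tree_prob1(tree, xp)) == yo)
      }, 0))
      vi[t, j] <- base_acc - acc_perm
    }
  }
  imp <- colMeans(vi[!skip, , drop = FALSE])
  fn <- model$feature_names
  if (is.null(fn)) fn <- paste0("x", seq_len(p))
  out <- data.frame(feature = fn, importance = imp,
                    rank = rank(-imp, ties.method = "first"),
                    stringsAsFactors = FALSE)
  attr(out, "conditional") <- conditional
  out
}

#' Serialize / restore a conditional forest as JSON text
#'
#' @param model A `cforest_model`.
#' @param path File path.
#' @return `path` (write) or the restored model (read).
#' @export
write_cforest <- function(model, path) {
  obj <- unclass(model)
  obj$trees <- lapply(obj$trees, unclass)
  obj$cassex_model <- "cforest_model"
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_cforest
#' @export
read_cforest <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  if (!identical(obj$cassex_model, "cforest_model")) {
    stop("not a cassex forest model file: ", path)
  }
  obj$cassex_model <- NULL
  obj$trees <- lapply(obj$trees, function(tr) {
    structure(list(
      leaf = as.logical(tr$leaf), var = as.integer(tr$var),
      thr = as.numeric(tr$thr), left = as.integer(tr$left),
      right = as.integer(tr$right), p0 = as.numeric(tr$p0),
      p1 = as.numeric(tr$p1), pval = as.numeric(tr$pval),
      n = as.integer(tr$n)
    ), class = "ctree_model")
  })
  obj$train_sets <- lapply(obj$train_sets, as.integer)
  obj$oob_sets <- lapply(obj$oob_sets, as.integer)
  for (f in c("ntree", "mtry", "min_node", "seed", "n", "p")) {
    obj[[f]] <- as.integer(obj[[f]])
  }
  obj$feature_names <- as.character(obj$feature_names)
  structure(obj, class = "cforest_model")
}

#' @export
print.cforest_model <- function(x, ...) {
  cat("<cforest_model> ", x$ntree, " conditional-inference trees, mtry=",
      x$mtry, ", alpha=", x$alpha, ", n=", x$n, ", p=", x$p, "\n", sep = "")
  invisible(x)
}
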