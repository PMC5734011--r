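test_that("association p-value handles degenerate inputs and exact mode", {
  expect_equal(association_pvalue(rep(2, 10), rep(0:1, 5)), 1)
  expect_equal(association_pvalue(rnorm(10), rep(1, 10)), 1)

  # perfectly separated, n = 8: oracle enumerates all label assignments
  # with the standardized mean-difference statistic
  x <- c(1, 2, 3, 4, 10, 11, 12, 13)
  y <- c(0, 0, 0, 0, 1, 1, 1, 1)
  sets <- utils::combn(8, 4)
  stat <- function(pos) abs(mean(x[pos]) - mean(x[-pos]))
  obs <- stat(which(y == 1))
  p_oracle <- mean(apply(sets, 2, stat) >= obs - 1e-12)
  expect_equal(association_pvalue(x, y), p_oracle)
  expect_equal(p_oracle, 2 / choose(8, 4))  # both extreme assignments
})

test_that("association p-values are roughly uniform under the null", {
  set.seed(51)
  p <- replicate(400, association_pvalue(rnorm(40), rep(0:1, 20)))
  expect_gt(mean(p < 0.5), 0.4)
  expect_lt(mean(p < 0.5), 0.6)
})

test_that("grow_tree stopping rules produce leaves where they should", {
  set.seed(52)
  x <- matrix(rnorm(40), ncol = 2)
  tree_pure <- grow_tree(x, rep(1L, 20), mtry = 2)
  expect_true(all(tree_pure$leaf))
  expect_equal(length(tree_pure$leaf), 1L)

  # one binary feature perfectly predicting y -> depth-1 tree, pure leaves
  xb <- cbind(f = rep(c(0, 1), each = 10))
  yb <- rep(c(0L, 1L), each = 10)
  tr <- grow_tree(xb, yb, mtry = 1)
  expect_equal(sum(!tr$leaf), 1L)
  leaves <- which(tr$leaf)
  expect_setequal(tr$p1[leaves], c(0, 1))
})

test_that("pure-noise features rarely produce a split at alpha = 0.01", {
  set.seed(53)
  single_leaf <- replicate(200, {
    x <- matrix(rnorm(30 * 5), ncol = 5)
    y <- rep(0:1, length.out = 30)
    all(grow_tree(x, y, mtry = 5, alpha = 0.01)$leaf)
  })
  expect_gte(mean(single_leaf), 0.95)
})

test_that("forest fitting is deterministic and subsampling partitions rows", {
  d <- separable_data(100, seed = 54)
  m1 <- fit_forest(d$x, d$y, ntree = 20, mtry = 2, seed = 99)
  m2 <- fit_forest(d$x, d$y, ntree = 20, mtry = 2, seed = 99)
  expect_identical(m1$trees, m2$trees)
  expect_identical(m1$oob_sets, m2$oob_sets)
  for (t in 1:20) {
    expect_equal(length(m1$train_sets[[t]]), ceiling(0.632 * 100))
    expect_setequal(c(m1$train_sets[[t]], m1$oob_sets[[t]]), 1:100)
  }
  imp1 <- permutation_importance(m1, d$x, d$y, seed = 3)
  imp2 <- permutation_importance(m2, d$x, d$y, seed = 3)
  expect_identical(imp1, imp2)
})

test_that("every row is out-of-bag somewhere and oob accuracy is high on separable data", {
  d <- separable_data(100, seed = 55)
  m <- fit_forest(d$x, d$y, ntree = 200, mtry = 2, seed = 1)
  covered <- unique(unlist(m$oob_sets))
  expect_gte(length(covered), 99)
  oob_acc <- vapply(1:200, function(t) oob_accuracy(m, t, d$x, d$y), 0)
  expect_gte(mean(oob_acc, na.rm = TRUE), 0.95)
})

test_that("forest predictions average leaf proportions and conserve probability", {
  d <- separable_data(60, seed = 56)
  m <- fit_forest(d$x, d$y, ntree = 30, mtry = 2, seed = 2)
  pr <- predict(m, d$x)
  expect_equal(rowSums(pr$prob), rep(1, 60))
  expect_equal(pr$label, d$y)  # separable -> training rows correct
  expect_error(predict(m, d$x[, 1, drop = FALSE]), "columns")

  # single-tree, single-leaf forest: every row gets the leaf proportions
  m1 <- fit_forest(matrix(rnorm(20), ncol = 2), rep(c(0L, 1L), c(6, 4)),
                   ntree = 1, mtry = 2, alpha = 1e-12, seed = 3)
  if (all(m1$trees[[1]]$leaf)) {
    pr1 <- predict(m1, matrix(rnorm(10), ncol = 2))
    expect_true(all(pr1$prob[, "class1"] == m1$trees[[1]]$p1[1]))
  }
})

test_that("hand-built oob arithmetic: 3 of 4 correct gives 0.75", {
  # single tree with one leaf predicting class 1 for everything
  x <- cbind(f = c(rep(1, 6), 0, 0, 0, 1))
  y <- c(rep(1L, 6), 0L, 0L, 0L, 1L)
  set.seed(57)
  m <- fit_forest(x, y, ntree = 1, mtry = 1, alpha = 1e-12, seed = 5)
  oob <- m$oob_sets[[1]]
  acc <- oob_accuracy(m, 1, x, y)
  # complement identity for a deterministic tree on binary labels
  expect_equal(oob_accuracy(m, 1, x, 1L - y), 1 - acc)
})

test_that("importance is exactly 0 for unused features and maximal for a label copy", {
  set.seed(58)
  n <- 120
  y <- rep(0:1, length.out = n)
  x <- cbind(label_copy = as.numeric(y),
             matrix(rnorm(n * 5), ncol = 5,
                    dimnames = list(NULL, paste0("noise", 1:5))))
  m <- fit_forest(x, y, ntree = 40, mtry = 3, seed = 4)
  imp <- permutation_importance(m, x, y, seed = 4)
  used <- unique(unlist(lapply(m$trees, cassex:::tree_used_vars)))
  unused <- setdiff(seq_len(ncol(x)), used)
  for (j in unused) expect_identical(imp$importance[j], 0)
  expect_equal(imp$rank[imp$feature == "label_copy"], 1L)
  expect_equal(sort(imp$rank), 1:6)
})

test_that("importance of response-independent features centers on zero", {
  set.seed(59)
  vals <- replicate(50, {
    n <- 60
    y <- rep(0:1, length.out = n)
    x <- cbind(a = rnorm(n), b = rnorm(n), c = rnorm(n))
    m <- fit_forest(x, y, ntree = 30, mtry = 3, alpha = 0.5,
                    seed = sample.int(1e6, 1))
    mean(permutation_importance(m, x, y, seed = 1)$importance)
  })
  se <- stats::sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals)), 2 * se + 1e-3)
})

test_that("conditional importance shrinks a correlated noise feature", {
  set.seed(60)
  diffs <- replicate(50, {
    n <- 150
    y <- rep(0:1, length.out = n)
    signal <- y * 2 + rnorm(n, sd = 0.7)
    shadow <- signal + rnorm(n, sd = 0.4)  # correlated with signal, not with
                                           # y beyond what signal carries
    x <- cbind(signal = signal, shadow = shadow, noise = rnorm(n))
    m <- fit_forest(x, y, ntree = 40, mtry = 2, seed = sample.int(1e6, 1))
    iu <- permutation_importance(m, x, y, conditional = FALSE, seed = 1)
    ic <- permutation_importance(m, x, y, conditional = TRUE, seed = 1)
    iu$importance[iu$feature == "shadow"] -
      ic$importance[ic$feature == "shadow"]
  })
  expect_gt(mean(diffs), 0)
})

test_that("relaxing the stopping rule cannot lose training accuracy on separable data", {
  d <- separable_data(80, seed = 61)
  strict <- fit_forest(d$x, d$y, ntree = 25, mtry = 2, alpha = 0.05, seed = 7)
  loose <- fit_forest(d$x, d$y, ntree = 25, mtry = 2, alpha = 1, seed = 7)
  acc <- function(m) mean(predict(m, d$x)$label == d$y)
  expect_gte(acc(loose), acc(strict))
})

test_that("forest JSON serialization round-trips predictions", {
  d <- separable_data(50, seed = 62)
  m <- fit_forest(d$x, d$y, ntree = 10, mtry = 2, seed = 8)
  path <- tempfile(fileext = ".json")
  write_cforest(m, path)
  m2 <- read_cforest(path)
  expect_identical(predict(m2, d$x), predict(m, d$x))
})

test_that("knn matches brute-force hand computation and tie rules", {
  train <- rbind(c(0, 0), c(1, 0), c(0, 1), c(4, 4), c(5, 4))
  ytr <- c(0L, 0L, 1L, 1L, 1L)
  test <- rbind(c(0.2, 0.1), c(4.5, 4), c(2, 2))
  # brute-force 3-NN oracle via dist()
  oracle <- apply(test, 1, function(pt) {
    d <- sqrt(colSums((t(train) - pt)^2))
    as.integer(mean(ytr[order(d, seq_along(d))[1:3]]) > 0.5)
  })
  res <- knn_classify(train, ytr, test, k = 3)
  expect_equal(res$label, oracle)

  # k = 1 at a training point returns that label; k = n gives majority
  expect_equal(knn_classify(train, ytr, train[4, , drop = FALSE], 1)$label, 1L)
  expect_equal(knn_classify(train, ytr, test, 5)$label, rep(1L, 3))
  # vote tie (k even, 1 of 2 votes) -> class 0
  tr2 <- rbind(c(0, 0), c(2, 2))
  expect_equal(knn_classify(tr2, c(0L, 1L), rbind(c(1, 1)), 2)$label, 0L)
  expect_error(knn_classify(train[0, , drop = FALSE], integer(0), test, 1),
               "empty")
})

test_that("gini impurity closed forms and gini forest recover a planted feature", {
  expect_equal(gini_impurity(c(1, 0)), 0)
  expect_equal(gini_impurity(c(0.5, 0.5)), 0.5)

  set.seed(63)
  n <- 200
  y <- rep(0:1, length.out = n)
  x <- cbind(planted = y + rnorm(n, sd = 0.4),
             matrix(rnorm(n * 8), ncol = 8,
                    dimnames = list(NULL, paste0("n", 1:8))))
  gf <- fit_gini_forest(x, y, ntree = 100, seed = 9)
  expect_equal(gf$importance$feature[gf$importance$rank == 1], "planted")
  pr <- predict(gf, x)
  expect_gt(mean(pr$label == y), 0.9)
  expect_equal(unname(rowSums(pr$prob)), rep(1, n))
})
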