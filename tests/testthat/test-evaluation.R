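test_that("confusion metrics follow the Sn/Sp/TA definitions", {
  m <- confusion_metrics(rep(1, 5), rep(1, 5))
  expect_equal(m$Sn, 1)
  expect_true(is.na(m$Sp))  # no negatives present
  expect_equal(m$TA, 1)

  # TP=3 FN=1 FP=2 TN=4
  truth <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  pred <- c(1, 1, 1, 0, 1, 1, 0, 0, 0, 0)
  m2 <- confusion_metrics(truth, pred)
  expect_equal(m2$Sn, 0.75)
  expect_equal(m2$Sp, 2 / 3)
  expect_equal(m2$TA, 0.7)

  # swapping the positive/negative convention swaps Sn and Sp
  m3 <- confusion_metrics(1 - truth, 1 - pred)
  expect_equal(m3$Sn, m2$Sp)
  expect_equal(m3$Sp, m2$Sn)
  expect_error(confusion_metrics(c(0, 1), c(0, 1, 1)), "length")
})

test_that("TA is the class-weighted mean of Sn and Sp on random tables", {
  set.seed(71)
  for (rep in 1:50) {
    n <- sample(10:60, 1)
    truth <- rbinom(n, 1, 0.5)
    if (length(unique(truth)) < 2) next
    pred <- rbinom(n, 1, 0.5)
    m <- confusion_metrics(truth, pred)
    P <- sum(truth == 1)
    N <- sum(truth == 0)
    expect_equal(m$TA, (m$Sn * P + m$Sp * N) / (P + N))
    expect_equal(m$TP + m$FN + m$FP + m$TN, n)
  }
})

test_that("AUC matches limits, the spec example, and the pairwise oracle", {
  expect_equal(roc_auc(c(3, 4, 1, 2), c(1, 1, 0, 0))$auc, 1.0)
  expect_equal(roc_auc(rep(0.7, 10), rep(0:1, 5))$auc, 0.5)
  expect_equal(roc_auc(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0))$auc, 0.75)
  expect_error(roc_auc(1:4, rep(1, 4)), "one positive and one negative")

  set.seed(72)
  for (rep in 1:100) {
    n <- sample(5:30, 1)
    scores <- round(rnorm(n), 1)  # rounding forces ties
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    expect_equal(roc_auc(scores, labels)$auc, auc_oracle(scores, labels),
                 tolerance = 1e-9)
  }
})

test_that("rank-statistic AUC equals the trapezoidal area under the ROC points", {
  set.seed(73)
  for (rep in 1:20) {
    scores <- rnorm(40)
    labels <- rbinom(40, 1, 0.5)
    if (length(unique(labels)) < 2) next
    r <- roc_auc(scores, labels)
    trap <- sum(diff(r$roc$fpr) * (utils::head(r$roc$tpr, -1) +
                                     utils::tail(r$roc$tpr, -1)) / 2)
    expect_equal(r$auc, trap, tolerance = 1e-9)
  }
})

test_that("AUC agrees with pROC on a shared example", {
  skip_if_not_installed("pROC")
  set.seed(74)
  scores <- rnorm(100)
  labels <- rbinom(100, 1, 0.4)
  ref <- as.numeric(suppressMessages(pROC::auc(labels, scores)))
  expect_equal(roc_auc(scores, labels)$auc, ref, tolerance = 1e-9)
})

test_that("kfold_split partitions rows with balanced, stratified folds", {
  p <- kfold_split(10, 10, seed = 1)
  expect_true(all(lengths(p$folds) == 1))

  labels <- rep(c("cassette", "constitutive"), each = 50)
  p2 <- kfold_split(100, 10, labels, seed = 2)
  for (f in p2$folds) {
    expect_equal(length(f), 10L)
    expect_equal(sum(labels[f] == "cassette"), 5L)
  }

  set.seed(75)
  for (rep in 1:100) {
    n <- sample(10:200, 1)
    k <- sample(2:min(10, n), 1)
    pl <- suppressWarnings(  # tiny classes may fall back to a plain split
      kfold_split(n, k, labels = rbinom(n, 1, 0.5), seed = rep))
    all_idx <- unlist(pl$folds)
    expect_setequal(all_idx, seq_len(n))
    expect_equal(length(all_idx), n)  # disjoint
    expect_lte(diff(range(lengths(pl$folds))), 1L)
  }

  expect_warning(kfold_split(10, 8, labels = c(rep(1, 9), 0), seed = 1),
                 "fewer members")
  expect_identical(kfold_split(50, 5, seed = 9)$folds,
                   kfold_split(50, 5, seed = 9)$folds)
})

test_that("cross-validation separates separable data and not permuted labels", {
  d <- separable_data(120, seed = 76)
  cv <- cross_validate(cforest_fitter(ntree = 30, mtry = 2, seed = 1),
                       d$x, d$y, k = 5, seed = 1)
  expect_gte(cv$mean[["TA"]], 0.99)
  expect_gte(cv$auc, 0.99)
  expect_equal(nrow(cv$folds), 5L)

  set.seed(77)
  y_perm <- sample(d$y)
  cv_null <- cross_validate(cforest_fitter(ntree = 30, mtry = 2, seed = 1),
                            d$x, y_perm, k = 5, seed = 1)
  majority <- max(mean(y_perm), 1 - mean(y_perm))
  expect_lt(abs(cv_null$mean[["TA"]] - majority), 0.1)
})

test_that("a constant-prediction fitter scores the majority-class rate", {
  const_fitter <- list(
    fit = function(x, y) NULL,
    predict = function(model, x) list(prob = rep(0, nrow(x)),
                                      label = rep(0L, nrow(x)))
  )
  y <- rep(c(0L, 1L), c(60, 40))
  x <- matrix(rnorm(200), ncol = 2)
  cv <- cross_validate(const_fitter, x, y, k = 5, seed = 3)
  expect_equal(cv$mean[["TA"]], 0.6)  # exact under stratification
  expect_equal(unname(cv$folds$TA), rep(0.6, 5))
})

test_that("training folds are k-1 times the test fold size", {
  p <- kfold_split(1000, 10, labels = rep(0:1, 500), seed = 4)
  for (f in p$folds) expect_equal(1000 - length(f), 9 * length(f))
})

test_that("grid search evaluates every point and prefers the sensible setting", {
  d <- separable_data(80, seed = 78)
  make <- function(mtry, alpha) cforest_fitter(ntree = 10, mtry = mtry,
                                               alpha = alpha, seed = 1)
  single <- grid_search(make, data.frame(mtry = 2, alpha = 0.05), d$x, d$y,
                        k = 4, seed = 1)
  expect_equal(nrow(single$results), 1L)
  expect_equal(single$best$mtry, 2)

  # alpha ~ 0 never splits: a known-degenerate setting loses to a
  # sensible one on separable data
  grid <- data.frame(mtry = c(1, 2), alpha = c(1e-12, 0.05))
  gs <- grid_search(make, grid, d$x, d$y, k = 4, seed = 1)
  expect_equal(nrow(gs$results), 2L)
  expect_equal(gs$best$alpha, 0.05)
  expect_error(grid_search(make, data.frame(), d$x, d$y), "empty")
})

test_that("feature comparison reproduces the Welch t-test formula", {
  set.seed(79)
  a <- rnorm(5, mean = 2)
  b <- rnorm(5)
  x <- matrix(c(a, b), ncol = 1, dimnames = list(NULL, "f"))
  y <- rep(c(1L, 0L), each = 5)
  row <- compare_feature_groups(x, y)
  t_oracle <- (mean(a) - mean(b)) /
    sqrt(stats::var(a) / length(a) + stats::var(b) / length(b))
  expect_equal(row$t, t_oracle, tolerance = 1e-12)
  expect_equal(row$mean_cassette, mean(a))
  expect_equal(row$mean_constitutive, mean(b))

  # near-identical groups -> t ~ 0; separated groups -> tiny p
  x2 <- cbind(same = rep(c(1, 2, 3, 4), 2),
              diff = c(rnorm(4, sd = 0.01), 1 + rnorm(4, sd = 0.01)))
  y2 <- rep(c(0L, 1L), each = 4)
  res <- compare_feature_groups(x2, y2, adjust = TRUE)
  expect_lt(res$p[res$feature == "diff"], 1e-6)
  expect_gt(res$p[res$feature == "same"], 0.9)
  expect_equal(res$p[1], min(res$p))  # sorted by p
  expect_true("p_adj" %in% names(res))

  x3 <- cbind(const = rep(1, 8))
  res3 <- compare_feature_groups(x3, y2)
  expect_equal(res3$p, 1)
  expect_true(res3$degenerate)
  expect_error(compare_feature_groups(x3, rep(1L, 8)), "nonempty")
})
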