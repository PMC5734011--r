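# Shared fixtures and independent oracles.

# write a temporary FASTA from raw text
write_tmp <- function(text, ext = ".fa") {
  path <- tempfile(fileext = ext)
  writeLines(text, path)
  path
}

# independent weight-matrix oracle: order-1 maxent over k positions is
# the product of pseudocounted per-position marginals, enumerated over
# the full 4^k table in lexicographic order (A<C<G<T, position 1 most
# significant)
wmm_oracle_table <- function(windows, k) {
  chars <- do.call(rbind, strsplit(windows, ""))
  marg <- lapply(seq_len(k), function(i) {
    counts <- table(factor(chars[, i], levels = c("A", "C", "G", "T")))
    (as.numeric(counts) + 0.5) / (length(windows) + 2)
  })
  grid <- expand.grid(rep(list(1:4), k))[, k:1, drop = FALSE]
  apply(grid, 1L, function(st) prod(mapply(function(m, b) m[b], marg, st)))
}

# probability vector of an enumerated single-block distribution
dist_probs <- function(dist) 2^dist$blocks[[1L]]$log2_probs

# random ACGT windows
random_windows <- function(n, k) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), k, replace = TRUE), collapse = "")
  }, "")
}

# lowercase k-mer names in lexicographic order (independent of the
# package's own feature_names())
kmer_names_for_test <- function(k) {
  b <- c("a", "c", "g", "t")
  sort(do.call(paste0, expand.grid(rep(list(b), k), stringsAsFactors = FALSE)))
}

# brute-force AUC: pairwise positive-vs-negative comparisons, ties 1/2
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  wins <- 0
  for (a in pos) for (b in neg) {
    wins <- wins + (a > b) + 0.5 * (a == b)
  }
  wins / (length(pos) * length(neg))
}

# simple separable two-feature dataset
separable_data <- function(n = 100, seed = 1) {
  set.seed(seed)
  y <- rep(0:1, length.out = n)
  x <- cbind(f1 = y * 4 + rnorm(n, sd = 0.3),
             f2 = -y * 4 + rnorm(n, sd = 0.3))
  list(x = x, y = y)
}

# memoized default synthetic bundle and its full-pipeline CV, shared by
# the acceptance checks (expensive to build)
.acceptance_cache <- new.env(parent = emptyenv())

acceptance_bundle <- function() {
  if (is.null(.acceptance_cache$bundle)) {
    .acceptance_cache$bundle <- generate_dataset(generator_config(seed = 20260924L))
  }
  .acceptance_cache$bundle
}

acceptance_cv <- function() {
  if (is.null(.acceptance_cache$cv)) {
    b <- acceptance_bundle()
    .acceptance_cache$cv <- suppressMessages(cross_validate_exons(
      b$genome, b$exons, cforest_fitter(ntree = 200L, mtry = 10L, seed = 101L),
      k = 10L, seed = 101L))
  }
  .acceptance_cache$cv
}
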