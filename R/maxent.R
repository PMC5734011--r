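# Maximum-entropy splice-site model.
#
# A splice-site model is a pair of distributions over fixed-length
# windows spanning an exon/intron boundary: a signal distribution P+
# fit on annotated sites and a decoy distribution P- fit on
# site-resembling background windows. A window x is scored by its
# log2-odds ratio log2(P+(x) / P-(x)); positive scores indicate
# signal-like windows.
#
# Each distribution is the maximum-entropy distribution consistent with
# empirical marginal constraints: per-position base frequencies
# (constraint_order = 1) or all pairwise position-pair frequencies,
# adjacent and non-adjacent (constraint_order = 2). Fitting is by
# iterative proportional scaling of the exactly enumerated k-mer table;
# marginal targets carry an add-0.5 pseudocount so all probabilities are
# strictly positive. Windows longer than 9 positions are partitioned
# into consecutive blocks of at most 8 positions, each fit exactly;
# the window score is the sum of per-block log-odds.

#' Splice-site window geometry
#'
#' Describes a fixed-length window across an exon/intron boundary.
#' A `5prime` (donor) window reads exon then intron; a `3prime`
#' (acceptor) window reads intron then exon.
#'
#' @param site_kind `"5prime"` or `"3prime"`.
#' @param exonic_len Number of exon-side positions.
#' @param intronic_len Number of intron-side positions.
#' @return An object of class `window_spec` with fields `site_kind`,
#'   `exonic_len`, `intronic_len`, `k`.
#' @export
window_spec <- function(site_kind = c("5prime", "3prime"),
                        exonic_len, intronic_len) {
  site_kind <- match.arg(site_kind)
  exonic_len <- as.integer(exonic_len)
  intronic_len <- as.integer(intronic_len)
  stopifnot(exonic_len >= 0L, intronic_len >= 0L,
            exonic_len + intronic_len >= 2L)
  structure(
    list(site_kind = site_kind, exonic_len = exonic_len,
         intronic_len = intronic_len, k = exonic_len + intronic_len),
    class = "window_spec"
  )
}

#' Default donor (5') window: 3 exonic + 6 intronic positions
#' @return A `window_spec`.
#' @export
donor_window_spec <- function() window_spec("5prime", 3L, 6L)

#' Default acceptor (3') window: 20 intronic + 3 exonic positions
#' @return A `window_spec`.
#' @export
acceptor_window_spec <- function() window_spec("3prime", 3L, 20L)

# consecutive block partition; exact enumeration for k <= 9, otherwise
# blocks as even as possible with size <= max_block
maxent_blocks <- function(k, max_block = 8L) {
  if (k <= 9L) return(list(seq_len(k)))
  nb <- ceiling(k / max_block)
  base <- k %/% nb
  extra <- k %% nb
  sizes <- base + as.integer(seq_len(nb) <= extra)
  ends <- cumsum(sizes)
  starts <- c(1L, ends[-nb] + 1L)
  Map(function(s, e) s:e, starts, ends)
}

# windows (character vector) -> n x k integer code matrix (A=1..T=4)
encode_windows <- function(windows, k) {
  if (any(nchar(windows) != k)) stop("window length must be ", k)
  m <- matrix(match(unlist(strsplit(windows, "", fixed = TRUE)),
                    c(BASES, "N")),
              ncol = k, byrow = TRUE)
  if (anyNA(m)) stop("windows contain characters outside {A,C,G,T,N}")
  m
}

# per-position base index (1..4) of every state in the enumerated 4^b
# table, position 1 most significant (lexicographic A<C<G<T order)
state_position_index <- function(b, i) {
  (((seq_len(4L^b) - 1L) %/% 4L^(b - i)) %% 4L) + 1L
}

# fit one exactly enumerated block by iterative proportional scaling
fit_maxent_block <- function(code, constraint_order, tol = 1e-6,
                             max_iter = 500L) {
  b <- ncol(code)
  n <- nrow(code)
  nstate <- 4L^b
  pos_idx <- lapply(seq_len(b), function(i) state_position_index(b, i))
  # each constraint group pre-stores the states sorted by marginal cell,
  # so the current marginal is a colSums over a reshaped view of p
  make_group <- function(idx, target) {
    ncell <- length(target)
    list(idx = idx, target = target, ord = order(idx),
         per_cell = nstate %/% ncell, ncell = ncell)
  }
  groups <- list()
  if (constraint_order >= 2L && b >= 2L) {
    for (i in seq_len(b - 1L)) {
      for (j in (i + 1L):b) {
        counts <- tabulate((code[, i] - 1L) * 4L + code[, j], nbins = 16L)
        groups[[length(groups) + 1L]] <- make_group(
          (pos_idx[[i]] - 1L) * 4L + pos_idx[[j]],
          (counts + 0.5) / (n + 8))
      }
    }
  } else {
    for (i in seq_len(b)) {
      counts <- tabulate(code[, i], nbins = 4L)
      groups[[length(groups) + 1L]] <- make_group(
        pos_idx[[i]], (counts + 0.5) / (n + 2))
    }
  }
  p <- rep(1 / nstate, nstate)
  viol <- Inf
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    viol <- 0
    for (g in groups) {
      cur <- colSums(matrix(p[g$ord], nrow = g$per_cell, ncol = g$ncell))
      viol <- max(viol, max(abs(cur - g$target)))
      p <- p * (g$target / cur)[g$idx]
    }
    if (viol <= tol) break
  }
  if (viol > tol) {
    stop("maxent fit did not converge: max constraint violation ",
         format(viol), " after ", iter, " iterations")
  }
  list(log2_probs = log2(p), iterations = iter, max_violation = viol)
}

#' Fit a maximum-entropy k-mer distribution
#'
#' Fits the distribution of maximal entropy consistent with the
#' empirical marginal constraints of a window sample (add-0.5
#' pseudocount per marginal cell), by iterative proportional scaling.
#' With `constraint_order = 1` the constraints are per-position base
#' frequencies (equivalent to a weight-matrix model); with order 2 they
#' are all pairwise position-pair frequencies, adjacent and
#' non-adjacent, which subsume the per-position marginals.
#'
#' @param windows Character vector of equal-length windows over
#'   `A/C/G/T/N`; windows containing `N` are dropped with a message.
#' @param spec A [window_spec()] whose `k` matches the window length.
#' @param constraint_order 1 or 2.
#' @param tol Maximum allowed marginal-constraint violation.
#' @param max_iter Maximum scaling sweeps before aborting.
#' @return An object of class `maxent_distribution` with the window
#'   `spec`, `constraint_order`, per-block `blocks` (positions and
#'   enumerated `log2_probs`), and `diagnostics` (iterations, maximum
#'   constraint violation, dropped-window count).
#' @export
fit_maxent <- function(windows, spec, constraint_order = 2L,
                       tol = 1e-6, max_iter = 500L) {
  stopifnot(inherits(spec, "window_spec"),
            constraint_order %in% c(1L, 2L))
  k <- spec$k
  has_n <- grepl("N", windows, fixed = TRUE)
  if (any(has_n)) {
    message("fit_maxent: dropped ", sum(has_n), " window(s) containing N")
  }
  windows <- windows[!has_n]
  if (length(windows) == 0L) stop("no windows left after N-filtering")
  code <- encode_windows(windows, k)
  blocks <- maxent_blocks(k)
  fits <- lapply(blocks, function(pos) {
    ord <- if (length(pos) >= 2L) constraint_order else 1L
    fit_maxent_block(code[, pos, drop = FALSE], ord, tol, max_iter)
  })
  structure(
    list(
      spec = spec,
      constraint_order = as.integer(constraint_order),
      blocks = Map(function(pos, f) list(positions = pos,
                                         log2_probs = f$log2_probs),
                   blocks, fits),
      diagnostics = list(
        iterations = vapply(fits, `[[`, 0L, "iterations"),
        max_violation = vapply(fits, `[[`, 0, "max_violation"),
        n_windows = length(windows),
        n_dropped = sum(has_n)
      )
    ),
    class = "maxent_distribution"
  )
}

#' Entropy of a fitted maximum-entropy distribution
#'
#' `H = -sum p * log2 p` in bits over the enumerated table; for a
#' multi-block distribution the block entropies add (blocks are
#' independent by construction), so `0 <= H <= 2k` always.
#'
#' @param dist A `maxent_distribution`.
#' @return Entropy in bits.
#' @export
entropy <- function(dist) {
  stopifnot(inherits(dist, "maxent_distribution"))
  sum(vapply(dist$blocks, function(b) {
    -sum(2^b$log2_probs * b$log2_probs)
  }, 0))
}

# per-window state index within one block; NA if any position is N (5)
block_state_index <- function(code, positions) {
  b <- length(positions)
  idx <- rep(1L, nrow(code))
  for (i in seq_len(b)) {
    v <- code[, positions[i]]
    idx <- idx + (v - 1L) * 4L^(b - i)
    idx[v == 5L] <- NA_integer_
  }
  idx
}

# log2-probability of windows under a maxent distribution
log2_prob <- function(dist, code) {
  out <- numeric(nrow(code))
  for (blk in dist$blocks) {
    idx <- block_state_index(code, blk$positions)
    out <- out + blk$log2_probs[idx]
  }
  out
}

#' Train paired signal/decoy splice-site models
#'
#' Fits the signal distribution P+ on annotated-site windows and the
#' decoy distribution P- on background windows with the same geometry
#' and constraint order.
#'
#' @param signal_windows,decoy_windows Character vectors of windows.
#' @param spec A [window_spec()].
#' @param constraint_order 1 or 2.
#' @param ... Passed to [fit_maxent()].
#' @return An object of class `splice_site_model` with fields `signal`,
#'   `decoy`, `spec`, `constraint_order`.
#' @export
train_splice_models <- function(signal_windows, decoy_windows, spec,
                                constraint_order = 2L, ...) {
  if (length(signal_windows) == 0L || length(decoy_windows) == 0L) {
    stop("signal and decoy window sets must both be nonempty")
  }
  structure(
    list(
      signal = fit_maxent(signal_windows, spec, constraint_order, ...),
      decoy = fit_maxent(decoy_windows, spec, constraint_order, ...),
      spec = spec,
      constraint_order = as.integer(constraint_order)
    ),
    class = "splice_site_model"
  )
}

#' Score splice-site windows by signal/decoy log-odds
#'
#' Returns `log2(P+(x) / P-(x))` for each window; for multi-block
#' models this is the sum of per-block log-odds. Windows containing `N`
#' score `NA`.
#'
#' @param model A `splice_site_model`.
#' @param windows Character vector of windows of length `model$spec$k`.
#' @return Numeric vector of log2-odds scores.
#' @export
score_site <- function(model, windows) {
  stopifnot(inherits(model, "splice_site_model"))
  code <- encode_windows(windows, model$spec$k)
  log2_prob(model$signal, code) - log2_prob(model$decoy, code)
}

#' Write a splice-site model to a JSON text file
#'
#' @param model A `splice_site_model` (or named list of them).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_splice_model <- function(model, path) {
  ser_dist <- function(d) {
    list(
      spec = unclass(d$spec), constraint_order = d$constraint_order,
      blocks = lapply(d$blocks, function(b)
        list(positions = b$positions, log2_probs = b$log2_probs)),
      diagnostics = d$diagnostics
    )
  }
  ser_model <- function(m) list(
    spec = unclass(m$spec), constraint_order = m$constraint_order,
    signal = ser_dist(m$signal), decoy = ser_dist(m$decoy)
  )
  obj <- if (inherits(model, "splice_site_model")) {
    c(list(cassex_model = "splice_site_model"), ser_model(model))
  } else {
    list(cassex_model = "splice_site_model_set",
         models = lapply(model, ser_model))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read a splice-site model written by [write_splice_model()]
#'
#' @param path Path to the JSON file.
#' @return A `splice_site_model` or named list of them.
#' @export
read_splice_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  de_spec <- function(s) window_spec(s$site_kind, s$exonic_len, s$intronic_len)
  de_dist <- function(d) structure(
    list(spec = de_spec(d$spec),
         constraint_order = as.integer(d$constraint_order),
         blocks = lapply(d$blocks, function(b)
           list(positions = as.integer(b$positions),
                log2_probs = as.numeric(b$log2_probs))),
         diagnostics = d$diagnostics),
    class = "maxent_distribution"
  )
  de_model <- function(m) structure(
    list(signal = de_dist(m$signal), decoy = de_dist(m$decoy),
         spec = de_spec(m$spec),
         constraint_order = as.integer(m$constraint_order)),
    class = "splice_site_model"
  )
  if (identical(obj$cassex_model, "splice_site_model")) return(de_model(obj))
  if (identical(obj$cassex_model, "splice_site_model_set")) {
    return(lapply(obj$models, de_model))
  }
  stop("not a cassex splice-site model file: ", path)
}

#' @export
print.splice_site_model <- function(x, ...) {
  cat("<splice_site_model> ", x$spec$site_kind, " site, k=", x$spec$k,
      " (", x$spec$exonic_len, " exonic + ", x$spec$intronic_len,
      " intronic), constraint order ", x$constraint_order, ", ",
      length(x$signal$blocks), " block(s)\n", sep = "")
  invisible(x)
}
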