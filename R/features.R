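# The 91 sequence features of an exon.
#
# Canonical order: length (1), mononucleotide frequencies (4),
# dinucleotide frequencies (16), trinucleotide frequencies (64),
# termination-codon frequencies taa/tag/tga (3), GC content (1),
# 5' and 3' splice-site strengths (2). Composition features are
# computed on the exon body only; splice strengths use boundary
# windows assembled from the body ends and the intronic flanks.

kmer_names <- function(k) {
  b <- c("a", "c", "g", "t")
  g <- expand.grid(rep(list(b), k), stringsAsFactors = FALSE)
  sort(do.call(paste0, g))
}

#' Canonical names of the 91 exon features
#'
#' @return Character vector of length 91.
#' @export
feature_names <- function() {
  c("length", kmer_names(1L), kmer_names(2L), kmer_names(3L),
    paste0("term_", c("taa", "tag", "tga")),
    "gc_content", "ss5_strength", "ss3_strength")
}

#' Overlapping k-mer frequencies of a sequence
#'
#' Counts overlapping k-mer windows; windows containing `N` are excluded
#' from both numerator and denominator. If no valid window remains the
#' result is all zeros with a warning.
#'
#' @param seq Single nucleotide string over `A/C/G/T/N`.
#' @param k 1, 2, or 3.
#' @return Named numeric vector of length `4^k` (lowercase k-mer names,
#'   lexicographic order) summing to 1 when any valid window exists.
#' @export
count_kmers <- function(seq, k) {
  stopifnot(length(seq) == 1L, is.character(seq))
  if (!k %in% 1:3) stop("k must be 1, 2, or 3")
  if (!nzchar(seq)) stop("empty sequence")
  if (nchar(seq) < k) stop("sequence shorter than k")
  codes <- base_codes(seq)  # 0..3, NA for N
  L <- length(codes)
  idx <- codes[seq_len(L - k + 1L)]
  if (k >= 2L) idx <- 4L * idx + codes[2L:(L - k + 2L)]
  if (k >= 3L) idx <- 4L * idx + codes[3L:L]
  counts <- tabulate(idx[!is.na(idx)] + 1L, nbins = 4L^k)
  total <- sum(counts)
  if (total == 0L) {
    warning("no valid ", k, "-mer window (all contain N); returning zeros")
    return(stats::setNames(numeric(4L^k), kmer_names(k)))
  }
  stats::setNames(counts / total, kmer_names(k))
}

# A/C/G/T -> 0..3, N -> NA; anything else errors
base_codes <- function(seq) {
  v <- utf8ToInt(seq)
  codes <- match(v, utf8ToInt("ACGT")) - 1L
  bad <- is.na(codes) & v != utf8ToInt("N")
  if (any(bad)) {
    stop("sequence contains characters outside {A,C,G,T,N}: ",
         intToUtf8(v[bad][1L]))
  }
  codes
}

#' GC content of a sequence
#'
#' `(#G + #C) / (#A + #C + #G + #T)`; `N` is excluded from the
#' denominator. An all-`N` sequence yields `NA`.
#'
#' @param seq Single nucleotide string.
#' @return Fraction in `[0, 1]`, or `NA`.
#' @export
gc_content <- function(seq) {
  stopifnot(length(seq) == 1L, nzchar(seq))
  codes <- base_codes(seq)
  codes <- codes[!is.na(codes)]
  if (length(codes) == 0L) return(NA_real_)
  mean(codes == 1L | codes == 2L)
}

#' Termination-codon frequencies
#'
#' Frame-agnostic overlapping occurrence frequencies of the three stop
#' codons, i.e. the `taa`, `tag`, `tga` entries of the trinucleotide
#' frequency vector.
#'
#' @param seq Single nucleotide string of length >= 3.
#' @return Named numeric vector `c(taa=, tag=, tga=)`.
#' @export
termination_codon_freqs <- function(seq) {
  if (nchar(seq) < 3L) stop("sequence shorter than 3")
  f3 <- count_kmers(seq, 3L)
  f3[c("taa", "tag", "tga")]
}

#' Extract the 91 features of one exon
#'
#' Composition features (k-mer frequencies, termination codons, GC) are
#' computed on the exon body; splice-site strengths score the donor and
#' acceptor boundary windows under the supplied models and are `NA`
#' when models are absent, flanks are insufficient or clipped, or the
#' window contains `N`.
#'
#' @param exon_seq An `exon_sequence` from [extract_exon_sequence()].
#' @param splice_models Optional named list with `splice_site_model`s
#'   `donor` and `acceptor`, e.g. from [train_genome_splice_models()].
#' @return Named numeric vector of length 91 in canonical order.
#' @export
extract_features <- function(exon_seq, splice_models = NULL) {
  stopifnot(inherits(exon_seq, "exon_sequence"))
  body <- exon_seq$body
  if (nchar(body) < 3L) stop("exon body shorter than 3 nt")
  f3 <- count_kmers(body, 3L)
  ss5 <- ss3 <- NA_real_
  if (!is.null(splice_models) && !exon_seq$clipped) {
    w5 <- donor_window(exon_seq, splice_models$donor$spec)
    w3 <- acceptor_window(exon_seq, splice_models$acceptor$spec)
    if (!is.null(w5)) ss5 <- score_site(splice_models$donor, w5)
    if (!is.null(w3)) ss3 <- score_site(splice_models$acceptor, w3)
  }
  out <- c(
    length = nchar(body),
    count_kmers(body, 1L),
    count_kmers(body, 2L),
    f3,
    term_taa = unname(f3[["taa"]]),
    term_tag = unname(f3[["tag"]]),
    term_tga = unname(f3[["tga"]]),
    gc_content = gc_content(body),
    ss5_strength = ss5,
    ss3_strength = ss3
  )
  stopifnot(identical(names(out), feature_names()))
  out
}

#' Build a feature matrix for a set of exons
#'
#' @param genome Named character vector from [read_fasta()].
#' @param exons Exon table from [read_exon_table()].
#' @param splice_models Optional donor/acceptor model list; if `NULL`
#'   and `train_models = TRUE`, models are trained on these exons with
#'   [train_genome_splice_models()].
#' @param flank_len Flank length for extraction.
#' @param train_models Train splice models when none are supplied.
#' @param ... Passed to [train_genome_splice_models()].
#' @return Data.frame with columns `id`, `label`, and the 91 features
#'   in canonical order.
#' @export
feature_matrix <- function(genome, exons, splice_models = NULL,
                           flank_len = 50L, train_models = TRUE, ...) {
  if (is.null(splice_models) && train_models) {
    splice_models <- train_genome_splice_models(genome, exons, flank_len, ...)
  }
  rows <- lapply(seq_len(nrow(exons)), function(i) {
    es <- extract_exon_sequence(genome, exons[i, ], flank_len)
    extract_features(es, splice_models)
  })
  mat <- do.call(rbind, rows)
  cbind(
    data.frame(id = exons$id, label = exons$label, stringsAsFactors = FALSE),
    as.data.frame(mat)
  )
}

# feature columns of a feature data.frame
feature_cols <- function(df) setdiff(names(df), c("id", "label"))

# numeric matrix + 0/1 labels from a feature data.frame
feature_xy <- function(df) {
  list(x = as.matrix(df[, feature_cols(df), drop = FALSE]),
       y = as_binary_labels(df$label))
}

#' Fit min-max scaling parameters on reference rows
#'
#' @param x Numeric matrix or feature data.frame.
#' @param reference_rows Row indices to fit on (default: all).
#' @return Data.frame with columns `feature`, `min`, `max`.
#' @export
fit_feature_scaling <- function(x, reference_rows = NULL) {
  if (is.data.frame(x)) x <- as.matrix(x[, feature_cols(x), drop = FALSE])
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (is.null(reference_rows)) reference_rows <- seq_len(nrow(x))
  if (length(reference_rows) == 0L) stop("empty reference row set")
  ref <- x[reference_rows, , drop = FALSE]
  data.frame(
    feature = colnames(x),
    min = apply(ref, 2L, min, na.rm = TRUE),
    max = apply(ref, 2L, max, na.rm = TRUE),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Apply min-max scaling parameters
#'
#' Maps each feature to `2 * (x - min) / (max - min) - 1`; a constant
#' reference feature maps to 0. Values outside the reference range fall
#' outside `[-1, 1]` and are not clipped.
#'
#' @param x Numeric matrix or feature data.frame.
#' @param params Data.frame from [fit_feature_scaling()].
#' @return Object of the same shape with scaled feature values.
#' @export
apply_feature_scaling <- function(x, params) {
  df <- NULL
  if (is.data.frame(x)) {
    df <- x
    x <- as.matrix(x[, feature_cols(x), drop = FALSE])
  }
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  stopifnot(identical(colnames(x), params$feature))
  rng <- params$max - params$min
  out <- x
  for (j in seq_len(ncol(x))) {
    out[, j] <- if (rng[j] == 0) {
      ifelse(is.na(x[, j]), NA_real_, 0)
    } else {
      2 * (x[, j] - params$min[j]) / rng[j] - 1
    }
  }
  if (!is.null(df)) {
    df[, feature_cols(df)] <- out
    return(df)
  }
  out
}

#' Min-max scale a feature matrix to `[-1, 1]`
#'
#' Scaling parameters are fit on `reference_rows` only (e.g. the
#' training fold) and applied to every row, so held-out rows may fall
#' outside `[-1, 1]`.
#'
#' @inheritParams fit_feature_scaling
#' @return List with `matrix` (scaled) and `params`.
#' @export
scale_features <- function(x, reference_rows = NULL) {
  params <- fit_feature_scaling(x, reference_rows)
  list(matrix = apply_feature_scaling(x, params), params = params)
}

#' Write / read a feature matrix as TSV
#'
#' @param df Feature data.frame from [feature_matrix()].
#' @param path File path.
#' @param header_lines Optional `#` comment lines.
#' @return `path` (write) or the data.frame (read).
#' @export
write_feature_matrix <- function(df, path, header_lines = NULL) {
  con <- file(path, "wt")
  on.exit(close(con))
  if (!is.null(header_lines)) writeLines(header_lines, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE)
}
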