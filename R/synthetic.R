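# Synthetic genome generator with planted class differences.
#
# Emulates the contrast between cassette and constitutive exons: the
# two classes differ in length, GC content, termination-codon
# frequency, and splice-site signal quality. Exons (with flanking
# intron context carrying planted donor/acceptor position weight
# matrices) are embedded in long background contigs, yielding a
# standard FASTA + exon-table round trip plus a ground-truth sidecar.

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Consensus donor position weight matrix
#'
#' 9 columns (3 exonic + 6 intronic); the canonical GT at the first two
#' intronic positions is invariant. `degradation` mixes every
#' non-anchor column toward uniform: `(1 - w) * col + w * 0.25`.
#'
#' @param degradation Mixing weight `w` in `[0, 1]`.
#' @return 4 x 9 column-stochastic matrix (rows A, C, G, T) with an
#'   `anchors` attribute marking invariant columns.
#' @export
donor_pwm <- function(degradation = 0) {
  m <- cbind(
    c(.34, .36, .18, .12),  # exon -3
    c(.62, .10, .14, .14),  # exon -2
    c(.08, .03, .82, .07),  # exon -1
    c(0, 0, 1, 0),          # intron +1 G (anchor)
    c(0, 0, 0, 1),          # intron +2 T (anchor)
    c(.60, .02, .35, .03),  # intron +3
    c(.72, .07, .09, .12),  # intron +4
    c(.05, .03, .87, .05),  # intron +5
    c(.14, .12, .16, .58)   # intron +6
  )
  rownames(m) <- BASES
  degrade_pwm(m, degradation, anchors = c(4L, 5L))
}

#' Consensus acceptor position weight matrix
#'
#' 23 columns (20 intronic + 3 exonic): a polypyrimidine tract, the
#' invariant AG at the last two intronic positions, and three exonic
#' positions.
#'
#' @inheritParams donor_pwm
#' @return 4 x 23 column-stochastic matrix with an `anchors` attribute.
#' @export
acceptor_pwm <- function(degradation = 0) {
  ppt <- c(.05, .38, .04, .53)  # strong polypyrimidine tract
  m <- cbind(
    matrix(ppt, nrow = 4L, ncol = 17L),
    c(.05, .40, .03, .52),  # intron -3 (pyrimidine-rich)
    c(1, 0, 0, 0),          # intron -2 A (anchor)
    c(0, 0, 1, 0),          # intron -1 G (anchor)
    c(.24, .14, .54, .08),  # exon +1
    c(.32, .26, .24, .18),  # exon +2
    c(.27, .24, .26, .23)   # exon +3
  )
  rownames(m) <- BASES
  degrade_pwm(m, degradation, anchors = c(19L, 20L))
}

degrade_pwm <- function(pwm, w, anchors = integer(0)) {
  stopifnot(w >= 0, w <= 1)
  out <- pwm
  keep <- setdiff(seq_len(ncol(pwm)), anchors)
  out[, keep] <- (1 - w) * pwm[, keep] + w * 0.25
  attr(out, "anchors") <- anchors
  out
}

#' Draw i.i.d. windows from a position weight matrix
#'
#' @param pwm Column-stochastic 4 x k matrix (rows A, C, G, T).
#' @param n Number of windows.
#' @param seed RNG seed.
#' @return Character vector of `n` windows of length `ncol(pwm)`.
#' @export
generate_splice_training <- function(pwm, n, seed = 1L) {
  if (!is.matrix(pwm) || nrow(pwm) != 4L ||
      any(abs(colSums(pwm) - 1) > 1e-8) || any(pwm < 0)) {
    stop("pwm must be a 4 x k matrix of column probability vectors")
  }
  restore_rng <- preserve_rng()
  on.exit(restore_rng())
  set.seed(as.integer(seed))
  draw_pwm_windows(pwm, n)
}

draw_pwm_windows <- function(pwm, n) {
  cols <- lapply(seq_len(ncol(pwm)), function(j) {
    sample(BASES, n, replace = TRUE, prob = pwm[, j])
  })
  do.call(paste0, cols)
}

random_sequence <- function(len, gc) {
  if (len <= 0L) return("")
  paste(sample(BASES, len, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# overlapping stop-codon count of a base vector
count_stops <- function(v) {
  L <- length(v)
  if (L < 3L) return(0L)
  tri <- paste0(v[1:(L - 2L)], v[2:(L - 1L)], v[3:L])
  sum(tri %in% STOP_CODONS)
}

# rejection resampling of trinucleotide windows until the overlapping
# stop-codon count reaches the target. A proposal is accepted only if
# it moves the stop count toward the target AND carries exactly the
# same number of G/C bases as the window it replaces, so the body's GC
# content is untouched by the adjustment.
adjust_stop_codons <- function(v, target_freq, gc, max_prop = 600L) {
  L <- length(v)
  if (L < 3L) return(v)
  target <- round(target_freq * (L - 2L))
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  gc_count <- function(w) sum(w == "G" | w == "C")
  cur <- count_stops(v)
  tries <- 0L
  while (cur != target && tries < max_prop) {
    tries <- tries + 1L
    if (cur > target) {
      tri <- paste0(v[1:(L - 2L)], v[2:(L - 1L)], v[3:L])
      pos <- which(tri %in% STOP_CODONS)
      i <- pos[sample.int(length(pos), 1L)]
      prop <- sample(BASES, 3L, replace = TRUE, prob = probs)
    } else {
      i <- sample.int(L - 2L, 1L)
      stop_p <- vapply(STOP_CODONS, function(s) {
        prod(probs[match(strsplit(s, "")[[1L]], BASES)])
      }, 0)
      prop <- strsplit(sample(STOP_CODONS, 1L, prob = stop_p), "")[[1L]]
    }
    old <- v[i:(i + 2L)]
    if (gc_count(prop) != gc_count(old)) next  # reject: would shift GC
    v[i:(i + 2L)] <- prop
    new_cnt <- count_stops(v)
    if (abs(new_cnt - target) < abs(cur - target)) {
      cur <- new_cnt
    } else {
      v[i:(i + 2L)] <- old  # reject
    }
  }
  v
}

#' Generator configuration
#'
#' Default class contrasts: mean lengths 142.85 / 176.39 nt, GC 0.4975
#' / 0.5062, summed stop-codon frequencies 0.0128 / 0.0117 (cassette /
#' constitutive), and splice-site PWM degradations 1 / 0 — the maximal
#' splice contrast, in which cassette boundaries carry only the
#' invariant GT/AG anchors over background composition while
#' constitutive boundaries carry the full consensus.
#'
#' @param n_cassette,n_constitutive Exon counts per class.
#' @param length_means Pair of mean exon lengths (cassette,
#'   constitutive), nucleotides.
#' @param gc_means Pair of exon GC contents in `(0, 1)`.
#' @param stop_freq_targets Pair of summed overlapping stop-codon
#'   frequencies.
#' @param splice_strength_offsets Pair of PWM degradation weights in
#'   `[0, 1]` (0 = consensus signal, 1 = uniform background).
#' @param flank_len Intronic flank retained around each exon; must be
#'   at least 20 (the acceptor window's intronic side).
#' @param length_log_sd Standard deviation of log exon length.
#' @param intron_gc GC content of intronic/background sequence.
#' @param seed RNG seed.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_cassette = 500L, n_constitutive = 500L,
                             length_means = c(cassette = 142.85,
                                              constitutive = 176.39),
                             gc_means = c(cassette = 0.4975,
                                          constitutive = 0.5062),
                             stop_freq_targets = c(cassette = 0.0128,
                                                   constitutive = 0.0117),
                             splice_strength_offsets = c(cassette = 1,
                                                         constitutive = 0),
                             flank_len = 50L, length_log_sd = 0.4,
                             intron_gc = 0.45, seed = 1L) {
  stopifnot(n_cassette >= 1L, n_constitutive >= 1L,
            all(length_means >= 10), all(gc_means > 0), all(gc_means < 1),
            all(stop_freq_targets >= 0), all(stop_freq_targets <= 1),
            all(splice_strength_offsets >= 0),
            all(splice_strength_offsets <= 1),
            flank_len >= 20L, length_log_sd > 0)
  structure(
    list(n_cassette = as.integer(n_cassette),
         n_constitutive = as.integer(n_constitutive),
         length_means = length_means, gc_means = gc_means,
         stop_freq_targets = stop_freq_targets,
         splice_strength_offsets = splice_strength_offsets,
         flank_len = as.integer(flank_len),
         length_log_sd = length_log_sd, intron_gc = intron_gc,
         seed = as.integer(seed)),
    class = "generator_config"
  )
}

#' Generate a synthetic genome with two exon classes
#'
#' Per exon: length is log-normal around the class mean; body bases are
#' i.i.d. at the class GC content; overlapping stop-codon occurrences
#' are moved to the class target by rejection resampling of
#' trinucleotide windows; the boundary positions of the body and flanks
#' carry the donor/acceptor PWMs degraded by the class offset. Exons
#' (on random strands) are embedded in background contigs of up to 1000
#' exons each with at least 200 nt spacing. Deterministic given the
#' config seed.
#'
#' @param config A [generator_config()].
#' @return An object of class `synthetic_bundle`: `genome` (named
#'   character), `exons` (exon table), `truth` (per-exon generative
#'   parameters), `config`.
#' @export
generate_dataset <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  restore_rng <- preserve_rng()
  on.exit(restore_rng())
  set.seed(config$seed)
  n <- config$n_cassette + config$n_constitutive
  label <- sample(rep(c("cassette", "constitutive"),
                      c(config$n_cassette, config$n_constitutive)))
  cls <- ifelse(label == "cassette", 1L, 2L)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  pwm5 <- lapply(config$splice_strength_offsets, donor_pwm)
  pwm3 <- lapply(config$splice_strength_offsets, acceptor_pwm)
  fl <- config$flank_len
  meanlog <- log(config$length_means) - config$length_log_sd^2 / 2

  contigs <- list()
  rows <- vector("list", n)
  truth <- vector("list", n)
  per_contig <- 1000L
  n_contig <- ceiling(n / per_contig)
  idx <- 0L
  for (ci in seq_len(n_contig)) {
    parts <- character(0)
    offset <- 0L
    cname <- paste0("synth_contig", ci)
    n_here <- min(per_contig, n - (ci - 1L) * per_contig)
    for (e in seq_len(n_here)) {
      idx <- idx + 1L
      k <- cls[idx]
      gc <- config$gc_means[k]
      len <- as.integer(max(10, round(stats::rlnorm(1L, meanlog[k],
                                                    config$length_log_sd))))
      body <- sample(BASES, len, replace = TRUE,
                     prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
      body <- adjust_stop_codons(body, config$stop_freq_targets[k], gc)
      # plant the exonic PWM positions at the body boundaries
      acc <- pwm3[[k]]
      don <- pwm5[[k]]
      for (j in 1:3) {
        body[j] <- sample(BASES, 1L, prob = acc[, 20L + j])
        body[len - 3L + j] <- sample(BASES, 1L, prob = don[, j])
      }
      uflank <- paste0(random_sequence(fl - 20L, config$intron_gc),
                       draw_pwm_windows(acc[, 1:20, drop = FALSE], 1L))
      dflank <- paste0(draw_pwm_windows(don[, 4:9, drop = FALSE], 1L),
                       random_sequence(fl - 6L, config$intron_gc))
      segment <- paste0(uflank, paste(body, collapse = ""), dflank)
      spacer <- random_sequence(200L + sample.int(100L, 1L), config$intron_gc)
      parts <- c(parts, spacer)
      offset <- offset + nchar(spacer)
      if (strand[idx] == "-") {
        parts <- c(parts, reverse_complement(segment))
        body_off <- nchar(dflank)
      } else {
        parts <- c(parts, segment)
        body_off <- nchar(uflank)
      }
      start <- offset + body_off
      rows[[idx]] <- data.frame(
        chrom = cname, start = start, end = start + len,
        strand = strand[idx], label = label[idx],
        id = sprintf("%s_%04d", substr(label[idx], 1L, 4L), idx),
        stringsAsFactors = FALSE
      )
      truth[[idx]] <- data.frame(
        id = rows[[idx]]$id, label = label[idx], strand = strand[idx],
        length = len, gc_target = unname(gc),
        stop_target = unname(config$stop_freq_targets[k]),
        splice_degradation = unname(config$splice_strength_offsets[k]),
        stringsAsFactors = FALSE
      )
      offset <- offset + nchar(segment)
    }
    parts <- c(parts, random_sequence(200L + sample.int(100L, 1L),
                                      config$intron_gc))
    contigs[[cname]] <- paste(parts, collapse = "")
  }
  structure(
    list(genome = unlist(contigs),
         exons = do.call(rbind, rows),
         truth = do.call(rbind, truth),
         config = config),
    class = "synthetic_bundle"
  )
}

#' Write a synthetic bundle to disk
#'
#' Emits `genome.fa`, `exons.tsv`, and `truth.tsv` under `dir`.
#'
#' @param bundle A `synthetic_bundle`.
#' @param dir Output directory (created if needed).
#' @param header_lines Optional `#` comment lines for the tables.
#' @return Named character vector of the three paths, invisibly.
#' @export
write_bundle <- function(bundle, dir, header_lines = NULL) {
  stopifnot(inherits(bundle, "synthetic_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             exons = file.path(dir, "exons.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_fasta(bundle$genome, paths[["genome"]])
  write_exon_table(bundle$exons, paths[["exons"]], header_lines)
  con <- file(paths[["truth"]], "wt")
  if (!is.null(header_lines)) writeLines(header_lines, con)
  utils::write.table(bundle$truth, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  invisible(paths)
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat("<synthetic_bundle> ", nrow(x$exons), " exons (",
      sum(x$exons$label == "cassette"), " cassette / ",
      sum(x$exons$label == "constitutive"), " constitutive) on ",
      length(x$genome), " contig(s), seed ", x$config$seed, "\n", sep = "")
  invisible(x)
}
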