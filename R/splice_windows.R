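# Assembling splice-site training windows from a genome + exon table.

# donor window of one exon_sequence: last exonic_len nt of the body plus
# first intronic_len nt of the downstream flank; NULL if unavailable
donor_window <- function(exon_seq, spec = donor_window_spec()) {
  body <- exon_seq$body
  bl <- nchar(body)
  if (bl < spec$exonic_len) return(NULL)
  if (nchar(exon_seq$downstream_flank) < spec$intronic_len) return(NULL)
  paste0(substr(body, bl - spec$exonic_len + 1L, bl),
         substr(exon_seq$downstream_flank, 1L, spec$intronic_len))
}

# acceptor window: last intronic_len nt of the upstream flank plus first
# exonic_len nt of the body
acceptor_window <- function(exon_seq, spec = acceptor_window_spec()) {
  body <- exon_seq$body
  ufl <- nchar(exon_seq$upstream_flank)
  if (nchar(body) < spec$exonic_len) return(NULL)
  if (ufl < spec$intronic_len) return(NULL)
  paste0(substr(exon_seq$upstream_flank, ufl - spec$intronic_len + 1L, ufl),
         substr(body, 1L, spec$exonic_len))
}

#' Collect annotated splice-site windows from exon records
#'
#' Extracts donor (5') and acceptor (3') windows for every exon with
#' sufficient flank; exons with clipped or too-short flanks are skipped
#' with a message.
#'
#' @param genome Named character vector from [read_fasta()].
#' @param exons Exon table from [read_exon_table()].
#' @param flank_len Flank length used for extraction; must cover the
#'   intronic side of both window geometries.
#' @param spec5,spec3 Donor and acceptor [window_spec()]s.
#' @return List with character vectors `donor` and `acceptor`.
#' @export
splice_training_windows <- function(genome, exons, flank_len = 50L,
                                    spec5 = donor_window_spec(),
                                    spec3 = acceptor_window_spec()) {
  don <- character(0)
  acc <- character(0)
  skipped <- 0L
  for (i in seq_len(nrow(exons))) {
    es <- extract_exon_sequence(genome, exons[i, ], flank_len)
    d <- donor_window(es, spec5)
    a <- acceptor_window(es, spec3)
    if (is.null(d) || is.null(a)) {
      skipped <- skipped + 1L
      next
    }
    don <- c(don, d)
    acc <- c(acc, a)
  }
  if (skipped > 0L) {
    message("splice_training_windows: skipped ", skipped,
            " exon(s) with insufficient flanks")
  }
  list(donor = don, acceptor = acc)
}

#' Harvest decoy splice-site windows from a genome
#'
#' Scans both strands of every contig for positions carrying the
#' canonical boundary dinucleotide (GT for donor sites, AG for acceptor
#' sites) at the intron-boundary offset of the window geometry but not
#' annotated as a site of that kind in the exon table, and returns the
#' corresponding windows. Windows containing `N` are dropped.
#'
#' @param genome Named character vector from [read_fasta()].
#' @param exons Exon table; its annotated boundaries are excluded.
#' @param spec A [window_spec()]; `5prime` harvests GT-anchored windows,
#'   `3prime` AG-anchored windows.
#' @param max_n Maximum number of windows to return (sampled without
#'   replacement if more are found).
#' @param seed RNG seed for the subsample.
#' @return Character vector of decoy windows.
#' @export
harvest_decoys <- function(genome, exons, spec, max_n = 3000L, seed = 1L) {
  stopifnot(inherits(spec, "window_spec"))
  donor <- spec$site_kind == "5prime"
  anchor <- if (donor) "GT" else "AG"
  out <- character(0)
  for (chrom in names(genome)) {
    fwd <- genome[[chrom]]
    L <- nchar(fwd)
    ex <- exons[exons$chrom == chrom, , drop = FALSE]
    for (str in c("+", "-")) {
      s <- if (str == "+") fwd else reverse_complement(fwd)
      exs <- ex[ex$strand == str, , drop = FALSE]
      # 0-based coords in this strand's string
      starts0 <- if (str == "+") exs$start else L - exs$end
      ends0 <- if (str == "+") exs$end else L - exs$start
      # anchor start position (0-based) of annotated sites
      annotated <- if (donor) ends0 else starts0 - 2L
      hits <- gregexpr(anchor, s, fixed = TRUE)[[1L]]
      if (hits[1L] == -1L) next
      q <- as.integer(hits) - 1L  # 0-based anchor starts
      q <- setdiff(q, annotated)
      # window start so that the anchor sits at the first two intronic
      # positions (donor) / last two intronic positions (acceptor)
      ws <- if (donor) q - spec$exonic_len else q - (spec$intronic_len - 2L)
      ws <- ws[ws >= 0L & ws + spec$k <= nchar(s)]
      if (!length(ws)) next
      out <- c(out, substring(s, ws + 1L, ws + spec$k))
    }
  }
  out <- out[!grepl("N", out, fixed = TRUE)]
  if (length(out) > max_n) {
    restore <- preserve_rng()
    on.exit(restore())
    set.seed(seed)
    out <- out[sort(sample.int(length(out), max_n))]
  }
  out
}

#' Train donor and acceptor splice models from an annotated genome
#'
#' Convenience wrapper: collects annotated windows with
#' [splice_training_windows()], harvests GT/AG-anchored decoys with
#' [harvest_decoys()], and fits both [train_splice_models()] pairs.
#'
#' @inheritParams splice_training_windows
#' @param constraint_order 1 or 2.
#' @param max_decoys Decoy windows per model.
#' @param seed RNG seed for the decoy subsample.
#' @return Named list with `splice_site_model`s `donor` and `acceptor`.
#' @export
train_genome_splice_models <- function(genome, exons, flank_len = 50L,
                                       constraint_order = 2L,
                                       max_decoys = 3000L, seed = 1L,
                                       spec5 = donor_window_spec(),
                                       spec3 = acceptor_window_spec()) {
  sig <- splice_training_windows(genome, exons, flank_len, spec5, spec3)
  dec5 <- harvest_decoys(genome, exons, spec5, max_decoys, seed)
  dec3 <- harvest_decoys(genome, exons, spec3, max_decoys, seed + 1L)
  list(
    donor = train_splice_models(sig$donor, dec5, spec5, constraint_order),
    acceptor = train_splice_models(sig$acceptor, dec3, spec3, constraint_order)
  )
}
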