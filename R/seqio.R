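# Sequence and exon-table input/output.
#
# Coordinates are 0-based half-open (BED convention) throughout:
# an exon [start, end) has length end - start.

BASES <- c("A", "C", "G", "T")

#' Read a genome FASTA file
#'
#' Reads a (possibly gzip-compressed) FASTA file into a named character
#' vector of uppercase nucleotide sequences. Sequence names are truncated
#' at the first whitespace; any character outside `A/C/G/T` (IUPAC
#' ambiguity codes included) is mapped to `N`.
#'
#' @param path Path to a FASTA file, plain or `.gz`.
#' @return Named character vector, one element per sequence.
#' @export
read_fasta <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    stop("FASTA file not found: ", path)
  }
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA file: ", path)
  out <- toupper(as.character(seqs))
  names(out) <- sub("\\s.*$", "", names(seqs))
  out <- gsub("[^ACGT]", "N", out)
  n_frac <- sum(nchar(gsub("[^N]", "", out))) / max(1L, sum(nchar(out)))
  if (n_frac > 0.5) {
    stop("FASTA content is not nucleotide-dominant (", round(100 * n_frac),
         "% unresolved characters): ", path)
  }
  out
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of nucleotide sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read an exon table
#'
#' Reads a tab-separated exon table with columns
#' `chrom, start, end, strand, label[, id]` (0-based half-open
#' coordinates). A header line is detected by a non-numeric second
#' column; lines starting with `#` are skipped. Records violating
#' `start < end` or shorter than 3 nt are dropped with a warning;
#' an unrecognized strand is an error. Labels are normalized to
#' lowercase and must be one of `cassette`, `constitutive`, `unknown`.
#'
#' @param path Path to a TSV file, plain or `.gz`.
#' @return A data.frame with columns `chrom`, `start`, `end`, `strand`,
#'   `label`, `id`.
#' @export
read_exon_table <- function(path) {
  if (!file.exists(path)) stop("exon table not found: ", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty exon table: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol1 <- length(fields[[1L]])
  if (ncol1 < 5L) stop("exon table needs at least 5 tab-separated columns")
  if (is.na(suppressWarnings(as.numeric(fields[[1L]][2L])))) {
    fields <- fields[-1L]  # header line
    if (length(fields) == 0L) stop("exon table has a header but no records")
  }
  bad_width <- vapply(fields, length, 0L) < 5L
  if (any(bad_width)) stop("exon table rows with fewer than 5 columns")
  chrom <- vapply(fields, `[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  strand <- vapply(fields, `[`, "", 4L)
  label <- tolower(vapply(fields, `[`, "", 5L))
  id <- vapply(fields, function(f) if (length(f) >= 6L) f[6L] else NA_character_, "")
  if (anyNA(start) || anyNA(end)) stop("non-numeric exon coordinates")
  if (!all(strand %in% c("+", "-"))) {
    stop("unknown strand value(s): ",
         paste(unique(strand[!strand %in% c("+", "-")]), collapse = ", "))
  }
  ok_label <- label %in% c("cassette", "constitutive", "unknown")
  if (!all(ok_label)) {
    stop("unknown exon label(s): ", paste(unique(label[!ok_label]), collapse = ", "))
  }
  keep <- start < end & (end - start) >= 3
  if (any(!keep)) {
    warning(sum(!keep), " exon record(s) rejected (start >= end or length < 3)")
  }
  df <- data.frame(
    chrom = chrom, start = as.integer(start), end = as.integer(end),
    strand = strand, label = label, id = id,
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  miss <- is.na(df$id)
  df$id[miss] <- paste0(df$chrom[miss], ":", df$start[miss], "-",
                        df$end[miss], ":", df$strand[miss])
  df$id <- make.unique(df$id)
  rownames(df) <- NULL
  df
}

#' Write an exon table
#'
#' @param exons Data.frame as returned by [read_exon_table()].
#' @param path Output path.
#' @param header_lines Optional character vector of `#`-prefixed comment
#'   lines written before the table.
#' @return `path`, invisibly.
#' @export
write_exon_table <- function(exons, path, header_lines = NULL) {
  con <- file(path, "wt")
  on.exit(close(con))
  if (!is.null(header_lines)) writeLines(header_lines, con)
  writeLines("chrom\tstart\tend\tstrand\tlabel\tid", con)
  utils::write.table(exons[, c("chrom", "start", "end", "strand", "label", "id")],
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Reverse-complement nucleotide sequences
#'
#' @param seq Character vector over the alphabet `A/C/G/T/N`.
#' @return Character vector of reverse complements (`N` maps to `N`).
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq))
  if (any(grepl("[^ACGTN]", seq))) {
    stop("reverse_complement: sequence contains characters outside {A,C,G,T,N}")
  }
  out <- vapply(chartr("ACGTN", "TGCAN", seq), function(s) {
    intToUtf8(rev(utf8ToInt(s)))
  }, "", USE.NAMES = FALSE)
  names(out) <- names(seq)
  out
}

#' Extract an exon sequence with intronic flanks
#'
#' Pulls the exon body and up to `flank_len` nucleotides of intronic
#' context on each side out of a genome. For minus-strand records the
#' body and flanks are reverse-complemented and the flank roles swapped,
#' so that `upstream_flank` always precedes the exon in transcript
#' orientation (it is the intron side of the 3' splice site) and
#' `downstream_flank` follows it (intron side of the 5' splice site).
#' Flanks are clipped at contig ends; clipped extractions carry
#' `clipped = TRUE` so splice features can be skipped for them.
#'
#' @param genome Named character vector from [read_fasta()].
#' @param record Single exon record: a one-row data.frame or list with
#'   fields `chrom`, `start`, `end`, `strand` (and optionally `label`, `id`).
#' @param flank_len Non-negative integer flank length.
#' @return An object of class `exon_sequence`: a list with `body`,
#'   `upstream_flank`, `downstream_flank`, `record`, `flank_len`, `clipped`.
#' @export
extract_exon_sequence <- function(genome, record, flank_len = 50L) {
  record <- as.list(record)
  stopifnot(flank_len >= 0)
  chrom <- record$chrom
  if (!chrom %in% names(genome)) stop("chromosome not in genome: ", chrom)
  contig <- genome[[chrom]]
  L <- nchar(contig)
  s <- as.integer(record$start)
  e <- as.integer(record$end)
  if (s < 0L || e > L || s >= e) {
    stop("exon ", chrom, ":", s, "-", e, " outside contig of length ", L)
  }
  body <- substr(contig, s + 1L, e)
  ls <- max(0L, s - flank_len)
  left <- if (s > ls) substr(contig, ls + 1L, s) else ""
  re <- min(L, e + flank_len)
  right <- if (re > e) substr(contig, e + 1L, re) else ""
  clipped <- (s - flank_len < 0L) || (e + flank_len > L)
  if (identical(record$strand, "-")) {
    body <- reverse_complement(body)
    up <- if (nzchar(right)) reverse_complement(right) else ""
    down <- if (nzchar(left)) reverse_complement(left) else ""
  } else if (identical(record$strand, "+")) {
    up <- left
    down <- right
  } else {
    stop("strand must be '+' or '-'")
  }
  structure(
    list(body = body, upstream_flank = up, downstream_flank = down,
         record = record, flank_len = as.integer(flank_len), clipped = clipped),
    class = "exon_sequence"
  )
}

#' @export
print.exon_sequence <- function(x, ...) {
  cat("<exon_sequence> ", x$record$chrom, ":", x$record$start, "-",
      x$record$end, " (", x$record$strand, ") body ", nchar(x$body),
      " nt, flanks ", nchar(x$upstream_flank), "/",
      nchar(x$downstream_flank), " nt",
      if (x$clipped) " [clipped]", "\n", sep = "")
  invisible(x)
}

# internal: 0/1 label coding, positives = cassette exons
as_binary_labels <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    lab <- tolower(labels)
    bad <- !lab %in% c("cassette", "constitutive")
    if (any(bad)) stop("labels must be 'cassette' or 'constitutive'")
    return(as.integer(lab == "cassette"))
  }
  if (!all(labels %in% c(0, 1))) stop("numeric labels must be 0/1")
  as.integer(labels)
}
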