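#' Build a gene model for splice-consequence prediction
#'
#' Holds the genomic sequence of a locus together with its ordered exon
#' intervals and CDS boundaries.  Minus-strand genes are normalised at
#' construction: the sequence is reverse-complemented and all coordinates
#' remapped, so internally everything is in transcription orientation with
#' introns reading `GT...AG`.
#'
#' @param id Gene identifier.
#' @param seq Genomic sequence of the locus (plain character, A/C/G/T).
#' @param exons Two-column matrix (start, end) of exon intervals, 1-based
#'   inclusive, in genomic coordinates of `seq`.
#' @param strand `"+"` or `"-"`.
#' @param cds_start,cds_end CDS boundaries in genomic coordinates of `seq`
#'   (the translation start and stop, inclusive).  Defaults span the whole
#'   exon range.
#' @param check_splice_sites Require canonical `GT..AG` intron boundaries
#'   (default `TRUE`).
#' @return An object of class `gene_model` with fields in transcription
#'   orientation: `seq`, `exons`, `cds_start`, `cds_end`, plus the original
#'   `strand`.
#' @export
gene_model <- function(id, seq, exons, strand = "+",
                       cds_start = NULL, cds_end = NULL,
                       check_splice_sites = TRUE) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (grepl("[^ACGT]", seq)) {
    stop("gene sequence must contain only A/C/G/T", call. = FALSE)
  }
  exons <- as.matrix(exons)
  if (ncol(exons) != 2L) stop("'exons' must have two columns", call. = FALSE)
  storage.mode(exons) <- "integer"
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'",
                                     call. = FALSE)
  L <- nchar(seq)
  cds_start <- cds_start %||% min(exons)
  cds_end <- cds_end %||% max(exons)

  if (strand == "-") {
    seq <- revcomp(seq)
    exons <- cbind(L - exons[, 2L] + 1L, L - exons[, 1L] + 1L)
    tmp <- L - cds_end + 1L
    cds_end <- L - cds_start + 1L
    cds_start <- tmp
  }
  exons <- exons[order(exons[, 1L]), , drop = FALSE]
  colnames(exons) <- c("start", "end")

  if (any(exons[, 1L] > exons[, 2L]) || min(exons) < 1L || max(exons) > L) {
    stop("exon intervals out of range", call. = FALSE)
  }
  if (nrow(exons) > 1L &&
      any(exons[-1L, 1L] <= exons[-nrow(exons), 2L])) {
    stop("exons must be non-overlapping and ordered", call. = FALSE)
  }
  in_exon <- function(p) any(p >= exons[, 1L] & p <= exons[, 2L])
  if (!in_exon(cds_start) || !in_exon(cds_end) || cds_start > cds_end) {
    stop("CDS boundaries must lie within the exon union", call. = FALSE)
  }
  if (check_splice_sites && nrow(exons) > 1L) {
    for (i in seq_len(nrow(exons) - 1L)) {
      is0 <- exons[i, 2L] + 1L
      ie <- exons[i + 1L, 1L] - 1L
      if (ie - is0 + 1L < 4L) stop("introns must be at least 4 nt",
                                   call. = FALSE)
      if (substr(seq, is0, is0 + 1L) != "GT" ||
          substr(seq, ie - 1L, ie) != "AG") {
        stop(sprintf("intron %d does not obey GT..AG", i), call. = FALSE)
      }
    }
  }
  structure(list(id = id, strand = strand, seq = seq, exons = exons,
                 cds_start = cds_start, cds_end = cds_end),
            class = "gene_model")
}

# mature transcript from a sequence and an exon table
splice_transcript <- function(seq, exons) {
  paste(substring(seq, exons[, 1L], exons[, 2L]), collapse = "")
}

# map a genomic position (transcription orientation) to transcript
# coordinates under an exon table; NA if the position is intronic/removed
transcript_pos <- function(pos, exons) {
  off <- 0L
  for (i in seq_len(nrow(exons))) {
    s <- exons[i, 1L]; e <- exons[i, 2L]
    if (pos >= s && pos <= e) return(off + (pos - s + 1L))
    off <- off + (e - s + 1L)
  }
  NA_integer_
}

#' Spliced coding sequence of a gene model
#'
#' @param gene A [gene_model()].
#' @return The CDS as a plain character string.
#' @export
cds_sequence <- function(gene) {
  stopifnot(inherits(gene, "gene_model"))
  tx <- splice_transcript(gene$seq, gene$exons)
  s <- transcript_pos(gene$cds_start, gene$exons)
  e <- transcript_pos(gene$cds_end, gene$exons)
  substr(tx, s, e)
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("Gene model %s (%s strand): %d exon(s), locus %d nt, CDS %d..%d\n",
              x$id, x$strand, nrow(x$exons), nchar(x$seq),
              x$cds_start, x$cds_end))
  invisible(x)
}
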