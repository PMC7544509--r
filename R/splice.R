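#' Predict the consequence of a splice-acceptor mutation
#'
#' Models the loss of an intron's 3' acceptor `AG`: the mutated base breaks
#' the acceptor, and the spliceosome is assumed to use the nearest `AG`
#' dinucleotide downstream (a cryptic acceptor).  The bases between the
#' original and the cryptic acceptor are removed from the mature
#' transcript; if the count of removed coding bases is not a multiple of 3
#' the reading frame shifts and translation typically runs into a premature
#' termination codon.  This reproduces the classic outcome of an acceptor
#' G>A mutation whose cryptic site lies 7 bp into the next exon: a 7-bp
#' deletion, a frameshift, and a premature stop.
#'
#' @param gene A [gene_model()].
#' @param intron_index Which intron's acceptor is mutated (1-based).
#' @param mutated_acceptor Position (transcription-orientation coordinate of
#'   `gene$seq`) of the mutated base; defaults to the `G` of the acceptor
#'   `AG`.  The base is replaced by its transition partner.
#' @param window Maximum distance (nt) downstream of the broken acceptor to
#'   search for a cryptic `AG` (default 300).
#' @return An object of class `splice_consequence`:
#'   \describe{
#'     \item{outcome}{`"ok"` when a cryptic acceptor was used,
#'       `"no_acceptor"` when none was found within the window
#'       (exon-skipping / intron-retention territory; no protein
#'       prediction), `"start_lost"` when the deletion removes the
#'       translation start.}
#'     \item{original_acceptor, alt_acceptor}{positions of the last base of
#'       the original and cryptic acceptor `AG`.}
#'     \item{shifted_bases}{coding bases removed from the mature transcript.}
#'     \item{frameshift}{`TRUE` iff `shifted_bases %% 3 != 0`.}
#'     \item{premature_stop_pos}{1-based position (nt, mutant CDS
#'       coordinates) of the first stop codon when it precedes the normal
#'       one, else `NA`.}
#'     \item{protein_length, wt_protein_length}{amino acids translated
#'       before the first stop in the mutant and wild-type CDS.}
#'     \item{no_stop}{`TRUE` when the mutant frame has no stop before the
#'       transcript end.}
#'   }
#' @export
predict_splice_consequence <- function(gene, intron_index,
                                       mutated_acceptor = NULL,
                                       window = 300) {
  stopifnot(inherits(gene, "gene_model"))
  n_intron <- nrow(gene$exons) - 1L
  if (n_intron < 1L || intron_index < 1L || intron_index > n_intron) {
    stop(sprintf("gene %s has no intron %s", gene$id, intron_index),
         call. = FALSE)
  }
  exons <- gene$exons
  iend <- unname(exons[intron_index + 1L, 1L]) - 1L  # last intron base (the G)
  mutated_acceptor <- mutated_acceptor %||% iend

  mseq <- gene$seq
  base <- substr(mseq, mutated_acceptor, mutated_acceptor)
  substr(mseq, mutated_acceptor, mutated_acceptor) <-
    chartr("ACGT", "GTAC", base)               # transition partner

  # wild-type protein for reference
  wt_cds <- cds_sequence(gene)
  wt_len <- aa_before_stop(translate_codons(wt_cds))

  # nearest AG whose last base is at or downstream of the original
  # acceptor; the new exon must retain at least one base
  next_start <- unname(exons[intron_index + 1L, 1L])
  next_end <- unname(exons[intron_index + 1L, 2L])
  jmax <- min(iend + window, next_end - 1L, nchar(mseq) - 1L)
  alt <- NA_integer_
  if (jmax >= iend) {
    for (j in iend:jmax) {
      if (substr(mseq, j - 1L, j) == "AG") { alt <- j; break }
    }
  }

  res <- list(gene_id = gene$id, intron_index = intron_index,
              original_acceptor = iend, alt_acceptor = alt,
              shifted_bases = NA_integer_, frameshift = NA,
              premature_stop_pos = NA_integer_,
              protein_length = NA_integer_, wt_protein_length = wt_len,
              no_stop = FALSE, outcome = "no_acceptor")
  if (is.na(alt)) return(structure(res, class = "splice_consequence"))

  # removed exonic interval [next_start, alt]; count its coding bases
  removed <- c(next_start, alt)
  shifted <- max(0L,
                 min(removed[2L], gene$cds_end) -
                 max(removed[1L], gene$cds_start) + 1L)
  res$shifted_bases <- as.integer(shifted)
  res$frameshift <- (shifted %% 3L) != 0L
  res$outcome <- "ok"

  if (gene$cds_start >= removed[1L] && gene$cds_start <= removed[2L]) {
    res$outcome <- "start_lost"
    return(structure(res, class = "splice_consequence"))
  }

  new_exons <- exons
  new_exons[intron_index + 1L, 1L] <- alt + 1L
  tx <- splice_transcript(mseq, new_exons)
  cs <- transcript_pos(gene$cds_start, new_exons)
  # translate from the start codon through the transcript end: a frameshift
  # reads through the annotated stop into downstream sequence
  mut_cds <- substr(tx, cs, nchar(tx))
  aa <- translate_codons(mut_cds)
  len <- aa_before_stop(aa)
  if (is.na(len)) {
    res$no_stop <- TRUE
    res$protein_length <- length(aa)
  } else {
    res$protein_length <- len
    if (is.na(wt_len) || len < wt_len) {
      res$premature_stop_pos <- 3L * len + 1L
    }
  }
  structure(res, class = "splice_consequence")
}

#' @export
print.splice_consequence <- function(x, ...) {
  cat(sprintf("Splice consequence for %s, intron %d [%s]\n",
              x$gene_id, x$intron_index, x$outcome))
  if (x$outcome == "ok") {
    cat(sprintf(
      "  cryptic acceptor %+d nt; %d coding base(s) removed; frameshift: %s\n",
      x$alt_acceptor - x$original_acceptor, x$shifted_bases,
      x$frameshift))
    cat(sprintf("  predicted protein: %s aa (wild type %s aa)%s\n",
                x$protein_length, x$wt_protein_length,
                if (!is.na(x$premature_stop_pos))
                  sprintf("; premature stop at CDS nt %d",
                          x$premature_stop_pos) else ""))
  }
  invisible(x)
}

#' Protein length after a small coding deletion
#'
#' Deletes `shift` bases from a CDS starting at `shift_site` and translates
#' the mutant sequence from its start codon up to (excluding) the first
#' stop, the standard way to predict the product of a frameshifting
#' lesion (for example, a 1-bp deletion yielding a 77-aa product).
#'
#' @param cds In-frame coding sequence beginning with `ATG`.
#' @param shift_site 1-based position of the first deleted base.
#' @param shift Number of deleted bases (default 1).
#' @return A list of class `frameshift_prediction` with `length` (aa before
#'   the first stop), `frameshift` (`shift %% 3 != 0`), and flags
#'   `no_stop` (no stop before the sequence end; `length` is then the full
#'   translated length) and `no_start` (the deletion destroyed the ATG).
#' @export
predict_frameshift_protein_length <- function(cds, shift_site, shift = 1) {
  stopifnot(is.character(cds), length(cds) == 1L)
  cds <- toupper(cds)
  if (grepl("[^ACGT]", cds)) stop("CDS must be A/C/G/T only", call. = FALSE)
  if (substr(cds, 1L, 3L) != "ATG") {
    stop("CDS must start with ATG", call. = FALSE)
  }
  shift_site <- check_count(shift_site, "shift_site")
  shift <- check_count(shift, "shift")
  if (shift_site + shift - 1L > nchar(cds)) {
    stop("deletion extends past the end of the CDS", call. = FALSE)
  }
  mut <- paste0(substr(cds, 1L, shift_site - 1L),
                substr(cds, shift_site + shift, nchar(cds)))
  res <- list(length = 0L, frameshift = (shift %% 3L) != 0L,
              no_stop = FALSE, no_start = FALSE)
  if (substr(mut, 1L, 3L) != "ATG") {
    res$no_start <- TRUE
    return(structure(res, class = "frameshift_prediction"))
  }
  aa <- translate_codons(mut)
  len <- aa_before_stop(aa)
  if (is.na(len)) {
    res$no_stop <- TRUE
    res$length <- length(aa)
  } else {
    res$length <- len
  }
  structure(res, class = "frameshift_prediction")
}

#' @export
print.frameshift_prediction <- function(x, ...) {
  cat(sprintf("Predicted product: %d aa%s%s%s\n", x$length,
              if (x$frameshift) " (frameshift)" else "",
              if (x$no_stop) " [no stop codon reached]" else "",
              if (x$no_start) " [start codon lost]" else ""))
  invisible(x)
}
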