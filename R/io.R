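#' Write pooled variants as a VCF with per-pool allele depths
#'
#' Emits a VCF 4.2 file with an `AD` (allelic depth) FORMAT field and two
#' samples, `WT_pool` and `Mu_pool`.  Truth labels, when present, go to a
#' sidecar TSV rather than the VCF.
#'
#' @param x A `pooled_cross` or a pooled-variant data frame.
#' @param vcf_path Output VCF path.
#' @param truth_path Optional sidecar TSV path for the truth labels.
#' @return Invisibly, `vcf_path`.
#' @export
write_pooled_variants <- function(x, vcf_path, truth_path = NULL) {
  if (inherits(x, "pooled_cross")) x <- x$variants
  stopifnot(is.data.frame(x))
  x <- x[order(x$chrom, x$pos), , drop = FALSE]
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=fruitmap",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths for the ref and alt alleles\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "WT_pool", "Mu_pool", sep = "\t")
  )
  body <- paste(x$chrom, x$pos, x$id %||% ".", x$ref, x$alt, ".", "PASS",
                ".", "AD",
                paste0(x$wt_ref_depth, ",", x$wt_alt_depth),
                paste0(x$mu_ref_depth, ",", x$mu_alt_depth), sep = "\t")
  writeLines(c(header, body), vcf_path)
  if (!is.null(truth_path) && !is.null(x$truth)) {
    utils::write.table(x[, c("id", "chrom", "pos", "truth")], truth_path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(vcf_path)
}

#' Read pooled variants from a VCF with AD fields
#'
#' Parses a VCF carrying per-sample `AD` allele depths (via `vcfR`) into
#' the pooled-variant table used by [filter_candidates()].  Multi-allelic
#' and non-SNP records are dropped with a message.
#'
#' @param vcf_path Path to the VCF.
#' @param wt_sample,mu_sample Sample names of the wild-type and mutant
#'   pools.
#' @return A pooled-variant data frame.
#' @export
read_pooled_variants <- function(vcf_path, wt_sample = "WT_pool",
                                 mu_sample = "Mu_pool") {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  ad <- vcfR::extract.gt(v, element = "AD")
  for (s in c(wt_sample, mu_sample)) {
    if (!s %in% colnames(ad)) {
      stop(sprintf("sample '%s' not found in %s", s, vcf_path),
           call. = FALSE)
    }
  }
  snp <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    !grepl(",", fix$ALT, fixed = TRUE)
  if (any(!snp)) {
    message(sum(!snp), " non-biallelic-SNP record(s) dropped")
  }
  split_ad <- function(col) {
    parts <- strsplit(col, ",", fixed = TRUE)
    cbind(ref = as.integer(vapply(parts, `[`, character(1L), 1L)),
          alt = as.integer(vapply(parts, `[`, character(1L), 2L)))
  }
  wt <- split_ad(ad[snp, wt_sample])
  mu <- split_ad(ad[snp, mu_sample])
  out <- data.frame(
    id = ifelse(is.na(fix$ID[snp]) | fix$ID[snp] == ".",
                paste0(fix$CHROM[snp], "_", fix$POS[snp]), fix$ID[snp]),
    chrom = fix$CHROM[snp], pos = as.integer(fix$POS[snp]),
    ref = fix$REF[snp], alt = fix$ALT[snp],
    wt_ref_depth = wt[, "ref"], wt_alt_depth = wt[, "alt"],
    mu_ref_depth = mu[, "ref"], mu_alt_depth = mu[, "alt"],
    stringsAsFactors = FALSE
  )
  out$wt_freq <- pool_freq(out$wt_ref_depth, out$wt_alt_depth)
  out$mu_freq <- pool_freq(out$mu_ref_depth, out$mu_alt_depth)
  out
}

#' Write and read lineage-tracked cell polygons as JSON
#'
#' Cell tracks are stored as an array of objects with `cell_id`,
#' `parent_id` and ordered vertex lists `t0` and `t1`.
#'
#' @param tracks A list of [cell_track()] objects.
#' @param path JSON file path.
#' @return `write_cell_tracks()` returns `path` invisibly;
#'   `read_cell_tracks()` returns a `cell_tracks` list.
#' @export
write_cell_tracks <- function(tracks, path) {
  payload <- lapply(tracks, function(tr) {
    list(cell_id = tr$cell_id, parent_id = tr$parent_id,
         t0 = unname(apply(tr$t0, 1L, as.numeric, simplify = FALSE)),
         t1 = unname(apply(tr$t1, 1L, as.numeric, simplify = FALSE)))
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cell_tracks
#' @export
read_cell_tracks <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  tracks <- lapply(payload, function(el) {
    cell_track(el$cell_id, el$parent_id,
               do.call(rbind, lapply(el$t0, unlist)),
               do.call(rbind, lapply(el$t1, unlist)))
  })
  structure(tracks, class = "cell_tracks")
}

#' Write protein sequences as FASTA
#'
#' @param sequences Named character vector or a `protein_sim`.
#' @param path Output FASTA path.
#' @return Invisibly, `path`.
#' @export
write_proteins <- function(sequences, path) {
  if (inherits(sequences, "protein_sim")) sequences <- sequences$sequences
  Biostrings::writeXStringSet(Biostrings::AAStringSet(sequences), path)
  invisible(path)
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_proteins <- function(path) {
  as.character(Biostrings::readAAStringSet(path))
}

#' Read gene models from GFF3 and FASTA
#'
#' Imports gene, exon and CDS features (via `rtracklayer`) and builds one
#' [gene_model()] per gene, carrying the genomic sequence of each locus.
#' Exons and CDS are associated to genes through their `Parent`/`ID`
#' attributes (mRNA level is traversed when present).
#'
#' @param gff_path GFF3 file path.
#' @param fasta_path Genome FASTA path.
#' @return Named list of `gene_model` objects.
#' @export
read_gene_models <- function(gff_path, fasta_path) {
  gr <- rtracklayer::import(gff_path)
  genome <- Biostrings::readDNAStringSet(fasta_path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  md <- S4Vectors::mcols(gr)
  typ <- as.character(md$type)
  ids <- as.character(md$ID)
  parent_of <- vapply(seq_along(gr), function(i) {
    p <- md$Parent[[i]]
    if (length(p) == 0L) NA_character_ else as.character(p[[1L]])
  }, character(1L))
  # resolve each feature to its top-level gene id
  top <- parent_of
  for (pass in 1:3) {
    up <- match(top, ids)
    has_up <- !is.na(up) & !is.na(parent_of[up])
    top[has_up] <- parent_of[up][has_up]
  }
  top[is.na(top)] <- ids[is.na(top)]

  gene_idx <- which(typ == "gene")
  models <- lapply(gene_idx, function(gi) {
    gid <- ids[gi]
    chrom <- as.character(GenomicRanges::seqnames(gr[gi]))
    if (!chrom %in% names(genome)) {
      stop(sprintf("sequence '%s' missing from FASTA", chrom),
           call. = FALSE)
    }
    g_start <- GenomicRanges::start(gr[gi])
    g_end <- GenomicRanges::end(gr[gi])
    mine <- which(top == gid)
    ex <- mine[typ[mine] == "exon"]
    if (length(ex) == 0L) ex <- mine[typ[mine] == "CDS"]
    if (length(ex) == 0L) return(NULL)
    cds <- mine[typ[mine] == "CDS"]
    locus_seq <- as.character(Biostrings::subseq(genome[[chrom]],
                                                 g_start, g_end))
    exons <- cbind(GenomicRanges::start(gr[ex]) - g_start + 1L,
                   GenomicRanges::end(gr[ex]) - g_start + 1L)
    cds_start <- if (length(cds)) min(GenomicRanges::start(gr[cds])) -
      g_start + 1L else NULL
    cds_end <- if (length(cds)) max(GenomicRanges::end(gr[cds])) -
      g_start + 1L else NULL
    gene_model(gid, locus_seq, exons,
               strand = as.character(GenomicRanges::strand(gr[gi])),
               cds_start = cds_start, cds_end = cds_end,
               check_splice_sites = FALSE)
  })
  names(models) <- ids[gene_idx]
  Filter(Negate(is.null), models)
}

#' Write a tab-separated table
#'
#' @param x Data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tab-separated table
#'
#' @param path Input path.
#' @return Data frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
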