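#' Count polymorphism and divergence at 0-fold and 4-fold sites
#'
#' Walks an in-frame alignment of ingroup sequences plus one outgroup
#' sequence codon by codon.  Each site is classified by the degeneracy of
#' its position in the ingroup major-allele (consensus) codon; only the two
#' extreme classes are used (0-fold -> non-synonymous, 4-fold ->
#' synonymous).  A site segregating within the ingroup increments `Pn` or
#' `Ps`; a site monomorphic in the ingroup but differing from the outgroup
#' increments `Dn` or `Ds`.  Sites both polymorphic and divergent count as
#' polymorphic only (the classical McDonald-Kreitman convention).  Codons
#' containing a gap or ambiguity character in any sequence are excluded
#' from both the counts and the site totals.
#'
#' @param ingroup Character vector of two or more equal-length, in-frame
#'   ingroup sequences.
#' @param outgroup A single outgroup sequence of the same length.
#' @param gene Optional gene identifier stored in the result.
#' @return A one-row data frame (class `mk_counts`) with columns `gene`,
#'   `Pn`, `Ps`, `Dn`, `Ds`, `L0`, `L4`.
#' @export
count_poly_div <- function(ingroup, outgroup, gene = NA_character_) {
  stopifnot(is.character(ingroup), length(ingroup) >= 2L,
            is.character(outgroup), length(outgroup) == 1L)
  ingroup <- toupper(ingroup); outgroup <- toupper(outgroup)
  len <- unique(nchar(c(ingroup, outgroup)))
  if (length(len) != 1L) stop("sequences must all have equal length",
                              call. = FALSE)
  if (len %% 3L != 0L) stop("alignment length must be a multiple of 3",
                            call. = FALSE)
  mat <- do.call(rbind, strsplit(c(ingroup, outgroup), ""))
  n_in <- length(ingroup)
  tab <- degeneracy_table()
  Pn <- Ps <- Dn <- Ds <- L0 <- L4 <- 0L

  for (c0 in seq_len(len %/% 3L)) {
    cols <- (3L * (c0 - 1L) + 1L):(3L * c0)
    block <- mat[, cols, drop = FALSE]
    if (any(!block %in% DNA_BASES)) next       # gap/ambiguity: drop codon
    # ingroup consensus codon (majority per site, ties by base order)
    cons <- apply(block[seq_len(n_in), , drop = FALSE], 2L, function(b) {
      cnt <- table(factor(b, levels = DNA_BASES))
      names(cnt)[which.max(cnt)]
    })
    cons_codon <- paste(cons, collapse = "")
    if (!cons_codon %in% rownames(tab)) next   # consensus is a stop codon
    folds <- tab[cons_codon, ]
    for (p in 1:3) {
      f <- folds[p]
      if (f == 0L) L0 <- L0 + 1L else if (f == 4L) L4 <- L4 + 1L
      in_alleles <- unique(block[seq_len(n_in), p])
      if (length(in_alleles) > 1L) {
        if (f == 0L) Pn <- Pn + 1L else if (f == 4L) Ps <- Ps + 1L
      } else if (in_alleles != block[n_in + 1L, p]) {
        if (f == 0L) Dn <- Dn + 1L else if (f == 4L) Ds <- Ds + 1L
      }
    }
  }
  structure(data.frame(gene = gene, Pn = Pn, Ps = Ps, Dn = Dn, Ds = Ds,
                       L0 = L0, L4 = L4, stringsAsFactors = FALSE),
            class = c("mk_counts", "data.frame"))
}

#' Two-sided Fisher exact p for a McDonald-Kreitman 2x2 table
#'
#' The table contrasts fixed differences with polymorphisms:
#' rows `(Dn, Ds)` and `(Pn, Ps)`.  Vectorised over genes.
#'
#' @param Dn,Ds,Pn,Ps Non-negative counts.
#' @return Two-sided exact p-values; `NA` where all four cells are zero.
#' @export
mk_fisher_p <- function(Dn, Ds, Pn, Ps) {
  mapply(function(a, b, c, d) {
    if (a + b + c + d == 0L) return(NA_real_)
    stats::fisher.test(matrix(c(a, b, c, d), nrow = 2L,
                              byrow = TRUE))$p.value
  }, Dn, Ds, Pn, Ps)
}

#' Direction of selection statistic
#'
#' `DoS = Dn/(Dn+Ds) - Pn/(Pn+Ps)`: positive values indicate an excess of
#' non-synonymous fixed differences (adaptive evolution), negative values
#' an excess of non-synonymous polymorphism (segregating constraint).
#'
#' @param counts A data frame or list with components `Dn`, `Ds`, `Pn`,
#'   `Ps` (vectors allowed).
#' @return Numeric vector in `[-1, 1]`; `NA` where either margin is zero.
#' @examples
#' dos(list(Dn = 10, Ds = 0, Pn = 0, Ps = 10))  # +1
#' @export
dos <- function(counts) {
  Dn <- counts$Dn; Ds <- counts$Ds; Pn <- counts$Pn; Ps <- counts$Ps
  div <- Dn + Ds
  pol <- Pn + Ps
  ifelse(div > 0 & pol > 0, Dn / div - Pn / pol, NA_real_)
}

#' McDonald-Kreitman test and summary statistics per gene
#'
#' For each gene computes the site-normalised ratios
#' `Pn/Ps = (Pn/L0)/(Ps/L4)` and `Ka/Ks = (Dn/L0)/(Ds/L4)` (omega), the
#' neutrality index `NI = (Pn/Ps)/(Dn/Ds)`, the [dos()] statistic, and the
#' two-sided Fisher exact p of the 2x2 table `[[Dn, Ds], [Pn, Ps]]`.
#' Ratios with a zero denominator are returned as `NA` and flagged, never
#' imputed.
#'
#' @param counts A data frame with columns `Pn`, `Ps`, `Dn`, `Ds` and
#'   (for the site-normalised ratios) `L0`, `L4`; optionally `gene`.
#' @return A data frame of class `mk_result` with columns `gene`, the four
#'   counts, `PnPs`, `KaKs`, `NI`, `DoS`, `fisher_p` and logical flags
#'   `PnPs_defined`, `KaKs_defined`, `NI_defined`, `DoS_defined`,
#'   `no_data` (all four MK cells zero).
#' @export
mk_test <- function(counts) {
  if (inherits(counts, "mk_sim")) counts <- counts$counts
  stopifnot(is.data.frame(counts),
            all(c("Pn", "Ps", "Dn", "Ds") %in% names(counts)))
  n <- nrow(counts)
  gene <- counts$gene %||% paste0("gene", seq_len(n))
  Pn <- counts$Pn; Ps <- counts$Ps; Dn <- counts$Dn; Ds <- counts$Ds
  if (any(c(Pn, Ps, Dn, Ds) < 0)) stop("counts must be non-negative",
                                       call. = FALSE)
  L0 <- counts$L0 %||% rep(NA_real_, n)
  L4 <- counts$L4 %||% rep(NA_real_, n)

  pnps <- ifelse(!is.na(L0) & !is.na(L4) & L0 > 0 & L4 > 0 & Ps > 0,
                 (Pn / L0) / (Ps / L4), NA_real_)
  kaks <- ifelse(!is.na(L0) & !is.na(L4) & L0 > 0 & L4 > 0 & Ds > 0,
                 (Dn / L0) / (Ds / L4), NA_real_)
  ni <- ifelse(Ps > 0 & Ds > 0 & Dn > 0, (Pn / Ps) / (Dn / Ds), NA_real_)
  d <- dos(list(Dn = Dn, Ds = Ds, Pn = Pn, Ps = Ps))
  fp <- mk_fisher_p(Dn, Ds, Pn, Ps)

  structure(data.frame(
    gene = gene, Pn = Pn, Ps = Ps, Dn = Dn, Ds = Ds, L0 = L0, L4 = L4,
    PnPs = pnps, KaKs = kaks, NI = ni, DoS = d, fisher_p = fp,
    PnPs_defined = !is.na(pnps), KaKs_defined = !is.na(kaks),
    NI_defined = !is.na(ni), DoS_defined = !is.na(d),
    no_data = (Pn + Ps + Dn + Ds) == 0,
    stringsAsFactors = FALSE
  ), class = c("mk_result", "data.frame"))
}

#' @export
print.mk_result <- function(x, ...) {
  cat(sprintf("McDonald-Kreitman results for %d gene(s)\n", nrow(x)))
  if (nrow(x) == 1L) {
    cat(sprintf("  Pn=%d Ps=%d Dn=%d Ds=%d\n", x$Pn, x$Ps, x$Dn, x$Ds))
    cat(sprintf("  Pn/Ps = %.4g, Ka/Ks = %.4g, NI = %.4g, DoS = %.4g, p = %.4g\n",
                x$PnPs, x$KaKs, x$NI, x$DoS, x$fisher_p))
  } else {
    cat(sprintf("  median Ka/Ks = %.4g (defined for %d), median DoS = %.4g\n",
                stats::median(x$KaKs, na.rm = TRUE), sum(x$KaKs_defined),
                stats::median(x$DoS, na.rm = TRUE)))
    cat(sprintf("  Fisher p < 0.05 for %d gene(s)\n",
                sum(x$fisher_p < 0.05, na.rm = TRUE)))
  }
  invisible(x)
}
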