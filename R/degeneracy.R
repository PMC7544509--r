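# 61 x 3 degeneracy table, built once from the standard genetic code
.fruitmap_cache <- new.env(parent = emptyenv())

degeneracy_table <- function() {
  tab <- .fruitmap_cache$degeneracy
  if (!is.null(tab)) return(tab)
  gc_tab <- Biostrings::GENETIC_CODE
  sense <- names(gc_tab)[gc_tab != "*"]
  tab <- matrix(NA_integer_, nrow = length(sense), ncol = 3L,
                dimnames = list(sense, NULL))
  for (cod in sense) {
    aa <- gc_tab[[cod]]
    for (p in 1:3) {
      alts <- setdiff(DNA_BASES, substr(cod, p, p))
      mut <- vapply(alts, function(b) {
        m <- cod; substr(m, p, p) <- b; m
      }, character(1L))
      n_syn <- sum(gc_tab[mut] == aa)
      # 0 synonymous alternatives -> 0-fold, 1 -> 2-fold, 2 -> 3-fold,
      # 3 -> 4-fold (the conventional fold classes)
      tab[cod, p] <- c(0L, 2L, 3L, 4L)[n_syn + 1L]
    }
  }
  .fruitmap_cache$degeneracy <- tab
  tab
}

#' Degeneracy fold class of a codon position
#'
#' The fold class counts how many of the three alternative nucleotides at a
#' codon position preserve the encoded amino acid under the standard code:
#' none preserved is 0-fold (every change is non-synonymous), all three is
#' 4-fold (every change is synonymous), with 2-fold and 3-fold in between.
#' 0-fold and 4-fold sites are the proxies for non-synonymous and
#' synonymous sites in the selection analyses.
#'
#' @param codon A sense codon (A/C/G/T; stop codons are rejected).
#' @param position Codon position, 1, 2 or 3.
#' @return Integer fold class: 0, 2, 3 or 4.
#' @examples
#' codon_degeneracy("GGA", 3)  # glycine GGN: 4-fold
#' codon_degeneracy("ATG", 1)  # methionine: 0-fold
#' @export
codon_degeneracy <- function(codon, position) {
  codon <- toupper(codon)
  stopifnot(length(codon) == 1L, length(position) == 1L,
            position %in% 1:3)
  if (nchar(codon) != 3L || grepl("[^ACGT]", codon)) {
    stop("codon must be three unambiguous bases", call. = FALSE)
  }
  tab <- degeneracy_table()
  if (!codon %in% rownames(tab)) {
    stop(sprintf("'%s' is a stop codon", codon), call. = FALSE)
  }
  unname(tab[codon, position])
}

#' Count 0-fold and 4-fold degenerate sites in a coding sequence
#'
#' Classifies every position of an in-frame CDS by its fold class and
#' totals the two extreme classes; 2-fold and 3-fold positions are counted
#' in neither.  A single terminal stop codon is tolerated and excluded from
#' the totals; internal stop codons are an error.
#'
#' @param cds In-frame coding sequence (length a multiple of 3).
#' @return Named integer vector `c(L0 = ..., L4 = ...)`.
#' @examples
#' count_sites("ATGGGA")  # L0 = 5, L4 = 1
#' @export
count_sites <- function(cds) {
  stopifnot(is.character(cds), length(cds) == 1L)
  cds <- toupper(cds)
  if (nchar(cds) %% 3L != 0L) {
    stop("CDS length must be a multiple of 3", call. = FALSE)
  }
  if (nchar(cds) == 0L) return(c(L0 = 0L, L4 = 0L))
  if (grepl("[^ACGT]", cds)) stop("CDS must be A/C/G/T only", call. = FALSE)
  cod <- codons_of(cds)
  tab <- degeneracy_table()
  is_stop <- !cod %in% rownames(tab)
  if (any(is_stop)) {
    if (sum(is_stop) > 1L || !is_stop[length(cod)]) {
      stop("internal stop codon in CDS", call. = FALSE)
    }
    cod <- cod[-length(cod)]
  }
  if (length(cod) == 0L) return(c(L0 = 0L, L4 = 0L))
  folds <- tab[cod, , drop = FALSE]
  c(L0 = sum(folds == 0L), L4 = sum(folds == 4L))
}
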