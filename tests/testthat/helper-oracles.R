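# Independent oracles and fixture builders used across the suite.

# Two-sided Fisher exact p by exhaustive hypergeometric enumeration over
# all tables with the observed margins (rows (a, b) and (c, d)).
enum_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  if (m + n == 0) return(NA_real_)
  lo <- max(0L, k - n); hi <- min(k, m)
  x <- lo:hi
  pr <- stats::dhyper(x, m, n, k)
  sum(pr[pr <= pr[x == a] * (1 + 1e-7)])
}

# translation through seqinr (codebase independent of Biostrings)
seqinr_translate <- function(dna) {
  seqinr::translate(strsplit(tolower(dna), "")[[1]])
}

# protein length up to the first stop, via the seqinr oracle
oracle_protein_length <- function(dna) {
  aa <- seqinr_translate(dna)
  stop_at <- which(aa == "*")
  if (length(stop_at) == 0) NA_integer_ else stop_at[1] - 1L
}

# degeneracy fold by substitute-and-translate with seqinr
oracle_degeneracy <- function(codon, pos) {
  aa <- seqinr_translate(codon)
  alts <- setdiff(c("A", "C", "G", "T"), substr(codon, pos, pos))
  syn <- sum(vapply(alts, function(b) {
    m <- codon
    substr(m, pos, pos) <- b
    seqinr_translate(m) == aa
  }, logical(1)))
  c(0L, 2L, 3L, 4L)[syn + 1L]
}

# scalar, spelled-out evaluation of the three BSA filter criteria
oracle_bsa_flags <- function(v, wt_tol = 0.10, mu_tol = 0.05,
                             min_depth = 20) {
  t(vapply(seq_len(nrow(v)), function(i) {
    r <- v[i, ]
    ems <- (r$ref == "G" && r$alt == "A") || (r$ref == "C" && r$alt == "T")
    call_of <- function(ref, alt) {
      tot <- ref + alt
      if (tot < min_depth) return("low_depth")
      f <- alt / tot
      if (f >= 1 - mu_tol) return("hom_alt")
      if (f <= mu_tol) return("hom_ref")
      "het"
    }
    geno <- call_of(r$wt_ref_depth, r$wt_alt_depth) == "het" &&
      call_of(r$mu_ref_depth, r$mu_alt_depth) == "hom_alt"
    wt_f <- if (r$wt_ref_depth + r$wt_alt_depth > 0)
      r$wt_alt_depth / (r$wt_ref_depth + r$wt_alt_depth) else NA_real_
    mu_f <- if (r$mu_ref_depth + r$mu_alt_depth > 0)
      r$mu_alt_depth / (r$mu_ref_depth + r$mu_alt_depth) else NA_real_
    freq <- !is.na(wt_f) && !is.na(mu_f) &&
      abs(wt_f - 1 / 3) <= wt_tol && mu_f >= 1 - mu_tol
    c(ems = ems, geno = geno, freq = freq)
  }, logical(3)))
}

# random sense codon (optionally excluding stop-adjacent M/W constraints)
random_sense_codons <- function(n) {
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  sample(sense, n, replace = TRUE)
}

# Two-exon gene with a cryptic AG planted `d` bases into exon 2 (the first
# AG reachable once the acceptor is broken).  CDS spans the whole
# transcript.  Returns the gene plus the pieces for oracle computation.
make_splice_gene <- function(d, n_codons1 = 4, n_codons2 = 20,
                             intron_len = 20) {
  stopifnot(d >= 1)
  exon1 <- paste0("ATG", paste(random_sense_codons(n_codons1), collapse = ""))
  mid <- paste(sample(c("A", "C", "G", "T"), intron_len - 4, TRUE),
               collapse = "")
  mid <- gsub("AG", "AC", mid, fixed = TRUE)  # keep interior free of AG
  intron <- paste0("GT", mid, "AG")
  tail_seq <- paste(random_sense_codons(n_codons2), collapse = "")
  exon2 <- if (d == 1) {
    paste0("G", tail_seq)
  } else {
    paste0(paste(sample(c("C", "T"), d - 2, TRUE), collapse = ""), "AG",
           tail_seq)
  }
  seq <- paste0(exon1, intron, exon2)
  e1 <- nchar(exon1)
  exons <- rbind(c(1, e1), c(e1 + nchar(intron) + 1, nchar(seq)))
  gene <- gene_model(sprintf("synth_d%d", d), seq, exons,
                     cds_start = 1, cds_end = nchar(seq))
  list(gene = gene, exon1 = exon1, exon2 = exon2, d = d)
}

# star-shaped simple polygon with n vertices
random_star_polygon <- function(n = 7) {
  ang <- sort(stats::runif(n, 0, 2 * pi))
  r <- stats::runif(n, 0.5, 2)
  cbind(r * cos(ang), r * sin(ang))
}

# fan-triangulation signed area summed over triangles (vertex 1 apex)
fan_area <- function(p) {
  n <- nrow(p)
  tri <- function(a, b, c) {
    ((b[1] - a[1]) * (c[2] - a[2]) - (c[1] - a[1]) * (b[2] - a[2])) / 2
  }
  abs(sum(vapply(2:(n - 1), function(i) tri(p[1, ], p[i, ], p[i + 1, ]),
                 numeric(1))))
}

# brute-force all-window SUMO-consensus scan
oracle_sumo_scan <- function(seq, psi = strsplit("AILMVFPC", "")[[1]]) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  hits <- integer(0)
  if (n >= 4) {
    for (i in 1:(n - 3)) {
      if (ch[i] %in% psi && ch[i + 1] == "K" && ch[i + 3] %in% c("D", "E")) {
        hits <- c(hits, i)
      }
    }
  }
  hits
}

# local reverse complement (kept out of the package namespace)
revcomp_chr <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
}
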