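test_that("a cryptic acceptor 7 bp into the next exon gives a 7-bp deletion and a frameshift", {
  set.seed(21)
  fx <- make_splice_gene(d = 7)
  sc <- predict_splice_consequence(fx$gene, 1)
  expect_identical(sc$outcome, "ok")
  expect_identical(sc$shifted_bases, 7L)
  expect_true(sc$frameshift)
  expect_identical(sc$alt_acceptor - sc$original_acceptor, 7L)
})

test_that("a cryptic acceptor 6 bp downstream is an in-frame two-codon deletion", {
  set.seed(22)
  fx <- make_splice_gene(d = 6)
  sc <- predict_splice_consequence(fx$gene, 1)
  expect_identical(sc$shifted_bases, 6L)
  expect_false(sc$frameshift)
  # the fixture CDS is built from sense codons only, so the in-frame
  # deletion never meets a stop: translation runs to the transcript end
  mutant_cds <- paste0(fx$exon1, substring(fx$exon2, fx$d + 1))
  expect_true(is.na(oracle_protein_length(mutant_cds)))
  expect_true(sc$no_stop)
  expect_identical(sc$protein_length, nchar(mutant_cds) %/% 3L)
})

test_that("an intact acceptor (mutation elsewhere) reproduces the wild-type protein", {
  set.seed(23)
  fx <- make_splice_gene(d = 7)
  # mutate a base in the middle of the intron, leaving the acceptor AG
  mut_pos <- fx$gene$exons[1, 2] + 5L
  sc <- predict_splice_consequence(fx$gene, 1, mutated_acceptor = mut_pos)
  expect_identical(sc$shifted_bases, 0L)
  expect_false(sc$frameshift)
  expect_identical(sc$protein_length, sc$wt_protein_length)
})

test_that("absence of a downstream AG within the window is flagged, not predicted", {
  exon1 <- "ATGGCTGCT"
  intron <- "GTAAATTTTTTTCTTTTCAG"
  exon2 <- paste(rep(c("CTT", "CTC"), 8), collapse = "")  # AG-free
  seq <- paste0(exon1, intron, exon2)
  g <- gene_model("noag", seq, rbind(c(1, 9), c(30, nchar(seq))),
                  cds_start = 1, cds_end = nchar(seq))
  sc <- predict_splice_consequence(g, 1)
  expect_identical(sc$outcome, "no_acceptor")
  expect_true(is.na(sc$protein_length))
})

test_that("splice predictions agree with the re-splice-and-translate oracle on random genes", {
  set.seed(24)
  for (i in 1:200) {
    d <- sample(1:40, 1)
    fx <- make_splice_gene(d, n_codons1 = sample(2:8, 1),
                           n_codons2 = sample(10:40, 1),
                           intron_len = sample(10:60, 1))
    sc <- predict_splice_consequence(fx$gene, 1)
    expect_identical(sc$shifted_bases, as.integer(d))
    expect_identical(sc$frameshift, (d %% 3) != 0)
    mutant_cds <- paste0(fx$exon1, substring(fx$exon2, d + 1))
    want <- oracle_protein_length(mutant_cds)
    if (is.na(want)) {
      expect_true(sc$no_stop)
    } else {
      expect_identical(sc$protein_length, want)
    }
  }
})

test_that("minus-strand gene models normalise to the same splice prediction", {
  set.seed(25)
  fx <- make_splice_gene(d = 7)
  g <- fx$gene
  L <- nchar(g$seq)
  flipped <- gene_model(g$id, revcomp_chr(g$seq),
                        cbind(L - g$exons[, 2] + 1L, L - g$exons[, 1] + 1L),
                        strand = "-", cds_start = 1, cds_end = L)
  sc_plus <- predict_splice_consequence(g, 1)
  sc_minus <- predict_splice_consequence(flipped, 1)
  expect_identical(sc_minus$shifted_bases, sc_plus$shifted_bases)
  expect_identical(sc_minus$protein_length, sc_plus$protein_length)
})

test_that("gene model validation enforces exon order, CDS bounds and GT..AG", {
  expect_error(gene_model("bad", "ATGGTTTAGGT", rbind(c(1, 5), c(4, 9))),
               "non-overlapping")
  expect_error(gene_model("bad", "ATGCCCGGG", rbind(c(1, 9)),
                          cds_start = 1, cds_end = 20), "CDS")
  expect_error(gene_model("bad", paste0("ATG", "CTAAGTTTTAG", "CCC"),
                          rbind(c(1, 3), c(15, 17))), "GT..AG")
})

test_that("frameshift product length matches codon-by-codon translation", {
  # an in-frame 3-base deletion shortens the product by exactly one residue
  cds <- "ATGGCTGCTGCTTGTTCTTGA"
  full <- predict_frameshift_protein_length(cds, 4, 3)
  expect_identical(full$length, 5L)
  expect_false(full$frameshift)
  # 1-base deletions across the CDS against the brute-force oracle
  set.seed(26)
  cds2 <- paste0("ATG", paste(random_sense_codons(30), collapse = ""), "TGA")
  for (site in c(4, 10, 25, 47)) {
    got <- predict_frameshift_protein_length(cds2, site, 1)
    mutant <- paste0(substr(cds2, 1, site - 1),
                     substr(cds2, site + 1, nchar(cds2)))
    want <- oracle_protein_length(mutant)
    if (is.na(want)) expect_true(got$no_stop) else
      expect_identical(got$length, want)
  }
  # destroying the start codon is flagged, not translated
  expect_true(predict_frameshift_protein_length(cds, 1, 1)$no_start)
})
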