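# site-by-site reference classifier built on the seqinr translation oracle
oracle_poly_div <- function(ingroup, outgroup) {
  m <- do.call(rbind, strsplit(c(ingroup, outgroup), ""))
  n_in <- length(ingroup)
  res <- c(Pn = 0L, Ps = 0L, Dn = 0L, Ds = 0L, L0 = 0L, L4 = 0L)
  for (cs in seq(1, ncol(m), by = 3)) {
    block <- m[, cs:(cs + 2), drop = FALSE]
    if (any(!block %in% c("A", "C", "G", "T"))) next
    cons <- sapply(1:3, function(j) {
      cnt <- table(factor(block[1:n_in, j], levels = c("A", "C", "G", "T")))
      names(cnt)[which.max(cnt)]
    })
    codon <- paste(cons, collapse = "")
    if (seqinr_translate(codon) == "*") next
    for (j in 1:3) {
      f <- oracle_degeneracy(codon, j)
      if (f == 0) res["L0"] <- res["L0"] + 1L
      if (f == 4) res["L4"] <- res["L4"] + 1L
      alle <- unique(block[1:n_in, j])
      if (length(alle) > 1) {
        if (f == 0) res["Pn"] <- res["Pn"] + 1L
        if (f == 4) res["Ps"] <- res["Ps"] + 1L
      } else if (alle != block[n_in + 1, j]) {
        if (f == 0) res["Dn"] <- res["Dn"] + 1L
        if (f == 4) res["Ds"] <- res["Ds"] + 1L
      }
    }
  }
  res
}

test_that("identical sequences yield all-zero MK counts", {
  s <- "ATGGGAGCTTGG"
  out <- count_poly_div(c(s, s), s)
  expect_identical(unlist(out[c("Pn", "Ps", "Dn", "Ds")]),
                   c(Pn = 0L, Ps = 0L, Dn = 0L, Ds = 0L))
})

test_that("a single segregating 4-fold site counts as one synonymous polymorphism", {
  out <- count_poly_div(c("ATGGGA", "ATGGGC"), "ATGGGA")
  expect_identical(out$Ps, 1L)
  expect_identical(out$Pn + out$Dn + out$Ds, 0L)
  # the same site fixed for a non-reference base is divergence, and a site
  # both polymorphic and divergent stays polymorphism-only
  out2 <- count_poly_div(c("ATGGGA", "ATGGGA"), "ATGGGC")
  expect_identical(out2$Ds, 1L)
  out3 <- count_poly_div(c("ATGGGA", "ATGGGC"), "ATGGGT")
  expect_identical(c(out3$Ps, out3$Ds), c(1L, 0L))
})

test_that("ambiguous codons are excluded from counts and site totals", {
  out <- count_poly_div(c("ATGGGA", "ATGGG-"), "ATGGGA")
  expect_identical(unlist(out[c("Pn", "Ps", "Dn", "Ds")]),
                   c(Pn = 0L, Ps = 0L, Dn = 0L, Ds = 0L))
  expect_identical(c(out$L0, out$L4), c(3L, 0L))  # only the ATG codon left
})

test_that("random alignments match the site-by-site reference classifier", {
  skip_if_not_installed("seqinr")
  set.seed(41)
  bases <- c("A", "C", "G", "T")
  for (i in 1:25) {
    len <- 3 * sample(5:20, 1)
    anc <- paste(random_sense_codons(len / 3), collapse = "")
    mutate <- function(s, k) {
      ch <- strsplit(s, "")[[1]]
      at <- sample(seq_along(ch), k)
      ch[at] <- vapply(ch[at], function(b) sample(setdiff(bases, b), 1), "")
      paste(ch, collapse = "")
    }
    ingroup <- c(anc, mutate(anc, sample(1:5, 1)), mutate(anc, sample(1:5, 1)))
    outgroup <- mutate(anc, sample(1:8, 1))
    got <- count_poly_div(ingroup, outgroup)
    want <- oracle_poly_div(ingroup, outgroup)
    expect_identical(unlist(got[names(want)]), want)
  }
})

test_that("MK summary statistics follow their defining formulas", {
  r <- mk_test(data.frame(Pn = 5, Ps = 5, Dn = 5, Ds = 5,
                          L0 = 100, L4 = 100))
  expect_identical(r$DoS, 0)              # neutral symmetry
  expect_identical(r$NI, 1)
  expect_identical(r$fisher_p, 1)
  r2 <- mk_test(data.frame(Pn = 2, Ps = 8, Dn = 10, Ds = 0,
                           L0 = 600, L4 = 200))
  expect_false(r2$KaKs_defined)           # zero synonymous divergence
  expect_true(is.na(r2$KaKs))
  expect_true(mk_test(data.frame(Pn = 0, Ps = 0, Dn = 0, Ds = 0,
                                 L0 = 10, L4 = 10))$no_data)
})

test_that("the MK Fisher p equals exhaustive hypergeometric enumeration", {
  expect_equal(mk_fisher_p(7, 2, 2, 8), enum_fisher_p(7, 2, 2, 8),
               tolerance = 1e-12)
  # exhaustive over all tables with margins <= 8
  for (m in 0:8) for (n in 0:8) for (k in 0:min(8, m + n)) {
    if (m + n == 0 || m + n - k > 8) next
    for (a in max(0, k - n):min(k, m)) {
      expect_equal(mk_fisher_p(a, m - a, k - a, n - k + a),
                   enum_fisher_p(a, m - a, k - a, n - k + a),
                   tolerance = 1e-9,
                   label = sprintf("table (%d,%d,%d,%d)",
                                   a, m - a, k - a, n - k + a))
    }
  }
})

test_that("DoS hits its bounds in the extreme selection regimes", {
  expect_identical(dos(list(Dn = 10, Ds = 0, Pn = 0, Ps = 10)), 1)
  expect_identical(dos(list(Dn = 0, Ds = 10, Pn = 10, Ps = 0)), -1)
  expect_true(is.na(dos(list(Dn = 0, Ds = 0, Pn = 3, Ps = 4))))
})

test_that("neutral simulation is centred on omega = 1 and DoS = 0; counts obey the config", {
  sim <- simulate_mk_counts(selection_config(n_genes = 2000, l0 = 500,
                                             l4 = 500, theta = 0.05,
                                             d = 0.05, seed = 42))
  res <- mk_test(sim$counts)
  # mean omega over genes within 3 SE of 1 (Poisson ratio bias is O(1/50))
  m <- mean(res$KaKs, na.rm = TRUE)
  se <- sd(res$KaKs, na.rm = TRUE) / sqrt(sum(!is.na(res$KaKs)))
  expect_lt(abs(m - 1), 3 * se + 0.05)
  md <- mean(res$DoS, na.rm = TRUE)
  sed <- sd(res$DoS, na.rm = TRUE) / sqrt(sum(!is.na(res$DoS)))
  expect_lt(abs(md), 3 * sed)
  # degenerate configurations
  z <- simulate_mk_counts(selection_config(n_genes = 50, theta = 0,
                                           seed = 1))
  expect_true(all(z$counts$Pn == 0 & z$counts$Ps == 0))
  z2 <- simulate_mk_counts(selection_config(n_genes = 50, f_div = 0,
                                            seed = 1))
  expect_true(all(z2$counts$Dn == 0))
})

test_that("mean DoS is monotone in the divergence/polymorphism acceptance ratio", {
  mean_dos <- function(f_poly, f_div, seed) {
    sim <- simulate_mk_counts(selection_config(
      n_genes = 800, l0 = 500, l4 = 500, theta = 0.05, d = 0.05,
      f_poly = f_poly, f_div = f_div, seed = seed))
    mean(mk_test(sim$counts)$DoS, na.rm = TRUE)
  }
  constrained_poly <- mean_dos(f_poly = 0.3, f_div = 1, seed = 7)
  neutral <- mean_dos(1, 1, seed = 7)
  constrained_div <- mean_dos(f_poly = 1, f_div = 0.3, seed = 7)
  expect_gt(constrained_poly, 0.05)
  expect_lt(constrained_div, -0.05)
  expect_true(constrained_div < neutral && neutral < constrained_poly)
})
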