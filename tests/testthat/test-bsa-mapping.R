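test_that("Mendelian pool expectations are the exact rationals 1/3 and 1", {
  expect_identical(expected_pool_frequency("recessive", "wild_type"), 1 / 3)
  expect_identical(expected_pool_frequency("recessive", "mutant"), 1)
  # within a pool the two allele frequencies are complementary
  expect_identical(expected_pool_frequency("recessive", "wild_type") +
                     (1 - expected_pool_frequency("recessive", "wild_type")),
                   1)
  expect_error(expected_pool_frequency("dominant", "mutant"))
})

test_that("EMS substitution typing accepts exactly G>A and C>T", {
  expect_true(all(is_ems_type(c("G", "C"), c("A", "T"))))
  expect_false(any(is_ems_type(c("A", "T", "G", "C"),
                               c("G", "C", "T", "A"))))
  expect_error(is_ems_type("R", "A"), "unambiguous")
  expect_error(is_ems_type("A", "A"), "differ")
})

test_that("pool genotype calls follow the frequency bands", {
  expect_identical(classify_pool_genotype(0, 50), "hom_alt")
  expect_identical(classify_pool_genotype(50, 0), "hom_ref")
  expect_identical(classify_pool_genotype(66, 34,
                                          filter_config(min_depth = 20)),
                   "het")
  expect_identical(classify_pool_genotype(5, 5), "low_depth")
  # exhaustive threshold table at a fixed total depth
  cfg <- filter_config()
  alt <- 0:100
  got <- classify_pool_genotype(100 - alt, alt, cfg)
  want <- ifelse(alt / 100 >= 0.95, "hom_alt",
                 ifelse(alt / 100 <= 0.05, "hom_ref", "het"))
  expect_identical(got, want)
})

test_that("an empty variant table filters to an empty candidate table", {
  empty <- data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      wt_ref_depth = integer(0), wt_alt_depth = integer(0),
                      mu_ref_depth = integer(0), mu_alt_depth = integer(0))
  out <- filter_candidates(empty)
  expect_s3_class(out, "bsa_candidates")
  expect_identical(nrow(out), 0L)
})

test_that("a perfect-frequency variant of the wrong substitution type is rejected with the right flags", {
  v <- data.frame(chrom = "chr1", pos = 100L, ref = "A", alt = "G",
                  wt_ref_depth = 67L, wt_alt_depth = 33L,
                  mu_ref_depth = 0L, mu_alt_depth = 100L)
  out <- filter_candidates(v)
  expect_false(out$candidate)
  expect_false(out$ems_pass)
  expect_true(out$freq_pass)
})

test_that("the causal site is recovered from simulated crosses", {
  x <- simulate_cross(cross_config(n_background_snps = 500, seed = 11))
  out <- filter_candidates(x)
  expect_true(x$causal_id %in% out$id[out$candidate])
  # and recovery holds for the large majority of seeds (exact per-cross
  # pass probability at 100x and pool 90 is 0.94)
  hits <- vapply(1:60, function(s) {
    xx <- simulate_cross(cross_config(n_background_snps = 0, seed = s))
    oo <- filter_candidates(xx)
    xx$causal_id %in% oo$id[oo$candidate]
  }, logical(1))
  expect_gte(mean(hits), 0.85)
})

test_that("filtering is idempotent and invariant to input order", {
  x <- simulate_cross(cross_config(n_background_snps = 300, seed = 12))
  out1 <- filter_candidates(x)
  set.seed(1)
  perm <- x$variants[sample.int(nrow(x$variants)), ]
  out2 <- filter_candidates(perm)
  rownames(out2) <- NULL
  expect_identical(out1$id, out2$id)
  expect_identical(out1$candidate, out2$candidate)
  out3 <- filter_candidates(as.data.frame(out1))
  expect_identical(out3$id, out1$id)
})

test_that("filter flags agree with a brute-force criterion evaluation", {
  set.seed(13)
  n <- 2000
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  wt_tot <- sample(0:150, n, TRUE)
  mu_tot <- sample(0:150, n, TRUE)
  wt_alt <- rbinom(n, wt_tot, runif(n))
  mu_alt <- rbinom(n, mu_tot, runif(n))
  v <- data.frame(chrom = "chr1", pos = seq_len(n), ref = ref, alt = alt,
                  wt_ref_depth = wt_tot - wt_alt, wt_alt_depth = wt_alt,
                  mu_ref_depth = mu_tot - mu_alt, mu_alt_depth = mu_alt,
                  stringsAsFactors = FALSE)
  out <- filter_candidates(v)
  out <- out[order(out$pos), ]
  want <- oracle_bsa_flags(v)
  expect_identical(out$ems_pass, unname(want[, "ems"]))
  expect_identical(out$genotype_pass, unname(want[, "geno"]))
  expect_identical(out$freq_pass, unname(want[, "freq"]))
})
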