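test_that("an AKMD tetrapeptide at residues 123-126 reports the acceptor lysine at 124", {
  prot <- paste0(strrep("G", 122), "AKMD", strrep("G", 30))
  hits <- scan_sumo(c(CrIND_like = prot))
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$k_pos, 124L)
  expect_identical(hits$start, 123L)
  expect_identical(hits$end, 126L)
  expect_identical(hits$tetrapeptide, "AKMD")
})

test_that("glycine is not accepted in the psi slot by default but the set is configurable", {
  expect_identical(nrow(scan_sumo(c(p = "GGGKMDGG"))), 0L)
  expect_identical(scan_sumo(c(p = "GGGKMDGG"), psi = "AILMVFPCG")$k_pos, 4L)
})

test_that("multiple, back-to-back hits are all reported in order", {
  hits <- scan_sumo(c(p = "AKADMKVEGG"))
  expect_identical(hits$start, c(1L, 5L))
  expect_identical(hits$tetrapeptide, c("AKAD", "MKVE"))
  expect_identical(hits$k_pos, c(2L, 6L))
})

test_that("the scan equals the brute-force all-window oracle on random proteins", {
  set.seed(61)
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P",
          "Q", "R", "S", "T", "V", "W", "Y")
  for (i in 1:50) {
    s <- paste(sample(aa, 200, TRUE), collapse = "")
    got <- scan_sumo(c(x = s))
    expect_identical(got$start, oracle_sumo_scan(s))
  }
})

test_that("scan hits recover the generator's truth set exactly", {
  sim <- simulate_proteins(40, motif_rate = 2, length = 250, seed = 62)
  hits <- scan_sumo(sim$sequences)
  expect_identical(hits[c("protein", "k_pos", "start", "end",
                          "tetrapeptide")],
                   sim$truth[c("protein", "k_pos", "start", "end",
                               "tetrapeptide")])
  expect_gt(nrow(hits), 40)  # rate 2 plus spontaneous matches
})

test_that("a K-free alphabet with no seeded motifs yields zero true motifs", {
  sim <- simulate_proteins(10, motif_rate = 0,
                           alphabet = c("G", "S", "T", "A", "D"), seed = 63)
  expect_identical(nrow(sim$truth), 0L)
  expect_identical(nrow(scan_sumo(sim$sequences)), 0L)
})

test_that("concatenation only adds junction-window hits", {
  set.seed(64)
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P",
          "Q", "R", "S", "T", "V", "W", "Y")
  for (i in 1:20) {
    a <- paste(sample(aa, 60, TRUE), collapse = "")
    b <- paste(sample(aa, 60, TRUE), collapse = "")
    ha <- scan_sumo(c(x = a))$start
    hb <- scan_sumo(c(x = b))$start + nchar(a)
    hab <- scan_sumo(c(x = paste0(a, b)))$start
    junction <- setdiff(hab, c(ha, hb))
    # junction hits span the boundary: start within 3 residues of it
    expect_true(all(junction > nchar(a) - 4 & junction <= nchar(a)))
    expect_true(all(c(ha, hb) %in% hab))
  }
})

test_that("non-standard residues are skipped with a warning", {
  expect_warning(h <- scan_sumo(c(p = "AAXKMDAKLD")), "non-standard")
  # the window containing X is dropped; the clean AKLD window remains
  expect_identical(h$k_pos, 8L)
})

test_that("the inverted consensus is only reported when requested", {
  s <- c(p = "DGKVAAA")  # D-X-K-psi at 1..4
  expect_identical(nrow(scan_sumo(s)), 0L)
  inv <- scan_sumo(s, inverted = TRUE)
  expect_identical(inv$motif, "inverted")
  expect_identical(inv$k_pos, 3L)
})
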