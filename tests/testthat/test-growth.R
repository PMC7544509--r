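unit_square <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))

test_that("the shoulder index behaves like arctan((L1-L2)/W) in degrees", {
  expect_identical(shoulder_index(5, 5, 2), 0)
  expect_equal(shoulder_index(4, 2, 2), 45)
  expect_equal(shoulder_index(2, 4, 2), -shoulder_index(4, 2, 2))
  expect_error(shoulder_index(4, 2, 0), "positive")
  # strictly increasing in L1, decreasing in L2 and (for L1 > L2) in W
  expect_true(all(diff(shoulder_index(1:10, 3, 2)) > 0))
  expect_true(all(diff(shoulder_index(5, 1:10, 2)) < 0))
  expect_true(all(diff(shoulder_index(6, 3, 1:10)) < 0))
})

test_that("polygon areas match the fan-triangulation oracle and are rigid-invariant", {
  expect_identical(polygon_area(unit_square), 1)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  moved <- t(R %*% t(unit_square)) + 3
  expect_equal(polygon_area(moved), 1, tolerance = 1e-12)
  expect_error(polygon_area(unit_square[1:2, ]), "3 vertices")
  set.seed(51)
  for (i in 1:30) {
    p <- random_star_polygon(sample(4:10, 1))
    expect_equal(polygon_area(p), fan_area(p), tolerance = 1e-9)
  }
})

test_that("the affine growth fit is exact on constructed deformations", {
  tr_id <- cell_track("a", "a", unit_square, unit_square)
  f <- fit_growth(tr_id)
  expect_equal(f$anisotropy, 1, tolerance = 1e-12)
  expect_equal(f$area_ratio, 1, tolerance = 1e-12)
  expect_equal(f$rms, 0, tolerance = 1e-12)
  stretched <- unit_square %*% diag(c(2, 1))
  f2 <- fit_growth(cell_track("b", "b", unit_square, stretched))
  expect_equal(f2$anisotropy, 2, tolerance = 1e-12)
  expect_equal(f2$area_ratio, 2, tolerance = 1e-12)
  f3 <- fit_growth(cell_track("b", "b", unit_square, stretched),
                   anisotropy_measure = "fractional")
  expect_equal(f3$anisotropy, 1 / 3, tolerance = 1e-12)
  degenerate <- cbind(0:3, 0:3)
  expect_error(fit_growth(cell_track("c", "c", degenerate,
                                     degenerate)), "collinear")
})

test_that("rigid rotation of both time points leaves the growth statistics unchanged", {
  set.seed(52)
  t0 <- random_star_polygon(6)
  A <- matrix(c(1.7, 0.2, 0.1, 1.1), 2)
  t1 <- t(A %*% t(t0))
  base <- fit_growth(cell_track("r", "r", t0, t1))
  th <- 1.1
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  rot <- fit_growth(cell_track("r", "r", t(R %*% t(t0)), t(R %*% t(t1))))
  expect_equal(rot$anisotropy, base$anisotropy, tolerance = 1e-9)
  expect_equal(rot$area_ratio, base$area_ratio, tolerance = 1e-9)
})

test_that("the mesh simulator realises its configured deformation exactly when noise-free", {
  idm <- simulate_mesh(mesh_config(grid_shape = c(3, 3), stretch_major = 1,
                                   stretch_minor = 1, rotation = 0,
                                   vertex_noise_sd = 0, division_prob = 0,
                                   seed = 1))
  for (tr in idm) expect_equal(tr$t1, tr$t0, tolerance = 1e-12)
  st <- simulate_mesh(mesh_config(grid_shape = c(3, 3), stretch_major = 2,
                                  stretch_minor = 1, vertex_noise_sd = 0,
                                  division_prob = 0.5, seed = 2))
  res <- measure_growth(st)
  expect_equal(res$anisotropy, rep(2, nrow(res)), tolerance = 1e-9)
  expect_equal(res$area_ratio, rep(2, nrow(res)), tolerance = 1e-9)
})

test_that("division produces adjacent sibling pairs that merge back to the parent", {
  tr <- simulate_mesh(mesh_config(grid_shape = c(4, 4), division_prob = 1,
                                  vertex_noise_sd = 0.01, seed = 3))
  parents <- vapply(tr, `[[`, character(1), "parent_id")
  expect_true(all(table(parents) == 2))  # every cell divided
  merged <- merge_daughters(tr)
  expect_identical(length(merged), 16L)
  # merged t1 area equals the summed daughter areas (disjoint interiors)
  for (p in unique(parents)) {
    pair <- tr[parents == p]
    m <- merged[[which(vapply(merged, `[[`, character(1), "cell_id") == p)]]
    expect_equal(polygon_area(m$t1),
                 polygon_area(pair[[1]]$t1) + polygon_area(pair[[2]]$t1),
                 tolerance = 1e-9)
    expect_equal(polygon_area(m$t0), 1, tolerance = 1e-12)
  }
  # non-adjacent "daughters" are refused
  far <- list(cell_track("x1", "p", unit_square, unit_square),
              cell_track("x2", "p", unit_square + 5, unit_square + 5))
  expect_error(merge_daughters(far), "not adjacent")
})

test_that("planted anisotropy is recovered to within 2% at 1% vertex noise", {
  tr <- simulate_mesh(mesh_config(grid_shape = c(10, 10),
                                  stretch_major = 1.8, stretch_minor = 1.2,
                                  vertex_noise_sd = 0.01,
                                  division_prob = 0.1, seed = 4))
  res <- measure_growth(tr)
  expect_identical(nrow(res), 100L)
  expect_lt(abs(mean(res$anisotropy) / 1.5 - 1), 0.02)
  expect_lt(abs(mean(res$area_ratio) / 2.16 - 1), 0.02)
})

test_that("heat maps record exactly the plotted values and honour scale bounds", {
  tr <- simulate_mesh(mesh_config(grid_shape = c(3, 3), division_prob = 0,
                                  seed = 5))
  res <- measure_growth(tr)
  fig <- file.path(tempdir(), "hm_test.png")
  side <- growth_heatmap(tr, res, "anisotropy", fig)
  expect_true(file.exists(fig))
  back <- read_tsv(paste0(fig, ".tsv"))
  expect_equal(back$value, res$anisotropy[match(back$cell_id, res$cell_id)],
               tolerance = 1e-9)
  # uniform statistic -> a single colour
  uni <- res; uni$anisotropy <- 1.5
  side_u <- growth_heatmap(tr, uni, "anisotropy", fig)
  expect_identical(length(unique(side_u$color)), 1L)
  # clipping is applied and counted
  expect_message(
    side_c <- growth_heatmap(tr, res, "anisotropy", fig,
                             bounds = c(quantile(res$anisotropy, 0.5), Inf)),
    "clipped")
  expect_identical(sum(side_c$clipped),
                   sum(res$anisotropy < quantile(res$anisotropy, 0.5)))
  expect_error(growth_heatmap(tr, res, "not_a_stat", fig))
})
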