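test_that("fiber alignment reproduces its closed forms", {
  expect_equal(fiber_alignment(rep(37, 50))$fa, 0, tolerance = 1e-12)
  expect_equal(fiber_alignment(rep(37, 50))$theta_bar_deg, 37)
  dense <- seq(0, 180, length.out = 20001)[-20001]
  expect_equal(fiber_alignment(dense)$fa, 1 - 2 / pi, tolerance = 1e-3)
  expect_equal(fiber_alignment(c(rep(0, 50), rep(90, 50)))$fa,
               1 - sqrt(2) / 2, tolerance = 1e-12)
  expect_error(fiber_alignment(rep(NA_real_, 5)), "undefined")
  # permutation invariance: depends only on the multiset of angles
  set.seed(4); ang <- runif(200, 0, 180)
  expect_equal(fiber_alignment(ang)$fa, fiber_alignment(sample(ang))$fa)
})

test_that("the doubled-angle variant treats uniform axial angles as
           fully dispersed", {
  dense <- seq(0, 180, length.out = 20001)[-20001]
  expect_equal(fiber_alignment(dense, double_angle = TRUE)$fa, 1,
               tolerance = 1e-3)
  expect_equal(fiber_alignment(rep(121, 9), double_angle = TRUE)$fa, 0,
               tolerance = 1e-12)
})

test_that("apparent fiber thickness averages the map and applies the
           calibration factor", {
  map <- matrix(0, 20, 20); mask <- matrix(FALSE, 20, 20)
  mask[10, 3:17] <- TRUE; map[10, 3:17] <- 7.5
  fp <- list(map = map, mask = mask)
  ft <- fiber_thickness(fp, p_gfp = 1000, p_endo = 0)
  expect_equal(ft$ft_gfp, 7.5)
  expect_equal(ft$ft, 7.5)
  ft2 <- fiber_thickness(fp, p_gfp = 1000, p_endo = 500)
  expect_equal(ft2$ft, 7.5 * 1.5)
  expect_error(fiber_thickness(list(map = map, mask = mask & FALSE), 1),
               "empty")
  # doubling the fiber brightness doubles FT at equal expression levels
  fp2 <- list(map = 2 * map, mask = mask)
  expect_equal(fiber_thickness(fp2, 1000, 500)$ft, 2 * ft2$ft)
})

test_that("erosion rings partition the cell into 1-px shells", {
  cellm <- fibermech:::.ellipse_mask(c(80L, 80L),
                                     small_cell(c(80L, 80L), c(30, 34)))
  ring <- erosion_rings(cellm)
  expect_true(all(ring[cellm] >= 1))
  expect_true(all(ring[!cellm] == 0))
  # shells are the level sets of the Euclidean distance transform
  dm <- as.matrix(EBImage::distmap(EBImage::Image(cellm)))
  expect_true(all(ring[cellm] == ceiling(dm[cellm])))
})

test_that("radial location finds periphery, centre, and a programmed
           annulus", {
  cellm <- fibermech:::.ellipse_mask(c(100L, 100L),
                                     small_cell(c(100L, 100L), c(40, 40)))
  ring <- erosion_rings(cellm)
  outer_map <- ifelse(ring == 1, 10, 0)
  expect_gt(radial_location(outer_map, cellm)$rl, 0.9)
  k <- max(ring)
  inner_map <- ifelse(ring >= k - 1, 10, 0)
  expect_lt(radial_location(inner_map, cellm)$rl, 0.1)
  # annulus at 70% of the normalized radius
  rad <- 1 - (ring - 1) / (k - 1)
  ann <- ifelse(abs(rad - 0.7) < 0.03, 10, 0); ann[!cellm] <- 0
  expect_equal(radial_location(ann, cellm)$rl, 0.7, tolerance = 0.05)
  # intensity scale invariance
  expect_equal(radial_location(ann * 50, cellm)$rl,
               radial_location(ann, cellm)$rl)
  expect_error(radial_location(outer_map, matrix(FALSE, 100, 100)),
               "empty")
})

test_that("cell geometry matches analytic moments", {
  sq <- matrix(FALSE, 120, 120); sq[11:110, 11:110] <- TRUE
  g <- cell_geometry(sq, pixel_size_um = 0.5)
  expect_equal(g$area_um2, 2500)
  expect_equal(g$aspect_ratio, 1, tolerance = 1e-6)
  ell <- fibermech:::.ellipse_mask(c(120L, 120L),
                                   list(center = c(60, 60),
                                        semi_axes = c(50, 10),
                                        phi_deg = 0))
  ge <- cell_geometry(ell, 1)
  expect_equal(ge$aspect_ratio, 5, tolerance = 0.1)
  rot <- fibermech:::.ellipse_mask(c(120L, 120L),
                                   list(center = c(60, 60),
                                        semi_axes = c(50, 10),
                                        phi_deg = 30))
  gr <- cell_geometry(rot, 1)
  expect_lte(axial_diff_deg(gr$major_axis_deg, 30), 2)
})
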