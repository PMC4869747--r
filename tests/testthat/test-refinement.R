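test_that("diffusion enhancement closes small gaps along a line but does
           not grow isolated pixels", {
  expect_identical(cedf_enhance(matrix(FALSE, 40, 40)),
                   matrix(FALSE, 40, 40))
  m <- matrix(FALSE, 40, 60)
  m[20, 10:50] <- TRUE
  m[20, 29:30] <- FALSE  # 2-px interior gap
  expect_equal(max(EBImage::bwlabel(EBImage::Image(m))), 2)
  e <- cedf_enhance(m)
  expect_equal(max(EBImage::bwlabel(EBImage::Image(e))), 1)
  expect_true(all(e[m]))  # enhancement is extensive
  dot <- matrix(FALSE, 40, 40); dot[20, 20] <- TRUE
  expect_lte(sum(cedf_enhance(dot)), 9)
})

test_that("orientation trimming keeps coherent regions and removes
           misfits", {
  cfg <- refinement_config()
  block <- matrix(FALSE, 40, 40); block[11:30, 11:30] <- TRUE
  uni <- matrix(45, 40, 40)
  expect_identical(orientation_trim(block, uni, cfg), block)
  # an orthogonal pixel embedded in a coherent band is removed
  band <- matrix(FALSE, 40, 60); band[19:21, 10:50] <- TRUE
  lof <- matrix(90, 40, 60); lof[20, 30] <- 0
  trimmed <- orientation_trim(band, lof, cfg)
  expect_false(trimmed[20, 30])
  # the misfit also contaminates its own neighborhood; pixels beyond the
  # comparison window are untouched
  far <- band & abs(col(band) - 30) > 5
  expect_identical(trimmed & far, far)
  # orientation must cover the mask
  expect_error(orientation_trim(band, matrix(NA_real_, 40, 60), cfg),
               "defined")
})

test_that("axial orientations wrap: 1 and 179 degrees are treated as
           nearly parallel", {
  band <- matrix(FALSE, 40, 60); band[19:21, 10:50] <- TRUE
  lof <- matrix(1, 40, 60)
  lof[, seq(10, 50, by = 2)] <- 179
  expect_identical(orientation_trim(band, lof), band)
})

test_that("the enhance/trim iteration reaches a fixed point and honours
           the cap", {
  empty <- list(mask = matrix(FALSE, 40, 40),
                angles_full_deg = matrix(0, 40, 40))
  out <- refine_segmentation(empty)
  expect_identical(out$iterations, 1L)
  expect_true(out$converged)
  im <- single_fiber_scene(theta_deg = 120, noise_sd = 4, seed = 3)
  seg <- segment_fibers(im$image, elog_bank(), im$cell_mask)
  ref <- refine_segmentation(seg)
  expect_true(ref$converged)
  expect_lte(ref$iterations, refinement_config()$max_iterations)
  # orientations cover exactly the final mask
  expect_identical(is.finite(ref$lof_deg), ref$mask)
  capped <- suppressWarnings(
    refine_segmentation(seg, refinement_config(max_iterations = 1)))
  expect_lte(capped$iterations, 1L)
})

test_that("trimming never adds pixels", {
  set.seed(1)
  for (i in 1:5) {
    m <- matrix(runif(1600) < 0.3, 40, 40)
    lof <- matrix(runif(1600, 0, 180), 40, 40)
    expect_true(all(m[orientation_trim(m, lof)]))
  }
})

test_that("bright dots inside a fiber field are removed while the fibers
           are kept", {
  cell <- small_cell()
  fib <- data.frame(r0 = c(44.5, 64.5, 84.5), c0 = 64.5, theta_deg = 90,
                    length_px = 90, width_px = 1.5, peak = 150)
  dts <- data.frame(r = c(54.5, 74.5), c = c(50.5, 80.5), sigma_px = 2,
                    peak = 200)
  im <- render_fiber_image(synthetic_image_spec(
    dim = c(128L, 128L), cell = cell, fibers = fib, dots = dts,
    background = list(type = "constant", amplitude = 20,
                      nucleus_depth = 0),
    noise_sd = 4, seed = 6))
  out <- run_image_pipeline(im)
  tm <- im$truth$mask
  expect_gte(sum(out$ref$mask & tm) / sum(tm), 0.90)
  expect_lte(sum(out$ref$mask & im$truth$dot_mask) /
               sum(im$truth$dot_mask), 0.10)
})
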