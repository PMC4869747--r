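# shared synthetic scenes used across test files

small_cell <- function(dim = c(128L, 128L), ar = c(52, 56)) {
  list(center = (dim + 1) / 2, semi_axes = ar, phi_deg = 0)
}

# one straight fiber through the centre of a small image
single_fiber_scene <- function(theta_deg = 30, length_px = 80,
                               width_px = 1.5, noise_sd = 4, seed = 1L,
                               peak = 150) {
  cell <- small_cell()
  fib <- data.frame(r0 = 64.5, c0 = 64.5, theta_deg = theta_deg,
                    length_px = length_px, width_px = width_px,
                    peak = peak)
  render_fiber_image(synthetic_image_spec(
    dim = c(128L, 128L), cell = cell, fibers = fib,
    background = list(type = "constant", amplitude = 20,
                      nucleus_depth = 0),
    noise_sd = noise_sd, seed = seed))
}

# the full benchmark scene: three parallel fiber families in disjoint
# sectors, bright dots, ramp background with a nucleus dip
benchmark_image_scene <- function(seed) {
  cell <- list(center = c(160, 160), semi_axes = c(130, 145), phi_deg = 0)
  fib <- fibers_families(30, cell, length_px = 110, spacing_px = 12)
  set.seed(seed + 100)
  dts <- dots_random(20, cell, exclude_center_px = 40)
  im <- render_fiber_image(synthetic_image_spec(
    dim = c(320L, 320L), cell = cell, fibers = fib, dots = dts,
    background = list(type = "ramp", nucleus_depth = 30,
                      nucleus_radius_px = 30),
    noise_sd = 4, seed = seed))
  list(im = im, fibers = fib, cell = cell)
}

# run segmentation -> refinement -> background -> F-protein on a rendered
# scene, using the known cell footprint
run_image_pipeline <- function(im) {
  seg <- segment_fibers(im$image, elog_bank(), im$cell_mask)
  ref <- refine_segmentation(seg)
  bg <- estimate_background(im$image, ref$mask)
  fp <- f_protein_map(im$image, ref$mask, bg)
  list(seg = seg, ref = ref, bg = bg, fp = fp)
}

# length-weighted alignment of a programmed fiber table (the closed form
# of the circular statistics on the programmed orientation distribution)
programmed_fa <- function(fibers) {
  w <- fibers$length_px / sum(fibers$length_px)
  rad <- fibers$theta_deg * pi / 180
  1 - sqrt(sum(w * cos(rad))^2 + sum(w * sin(rad))^2)
}

# synthesize a paired-calibration cohort with known P_endo
calibration_cells <- function(n = 20, p_endo_true = 1000, beta = 2,
                              noise_sd = 0, seed = 1L) {
  set.seed(seed)
  # transfection yields expression levels spread over decades
  p_gfp <- 10^runif(n, 2, 4)
  frac <- runif(n, 0.02, 0.3)
  f_gfp <- frac * p_gfp
  f_dye <- beta * f_gfp * (1 + p_endo_true / p_gfp)
  if (noise_sd > 0) f_dye <- f_dye * (1 + rnorm(n, 0, noise_sd))
  data.frame(f_gfp = f_gfp, p_gfp = p_gfp, f_dye = f_dye)
}

cohort_args <- function(preset, ...) {
  c(preset[setdiff(names(preset), c("protein", "region"))], list(...))
}
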