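#' Estimate the unbound-protein background map
#'
#' Per-pixel median of the image over a square filtering window, computed
#' from non-fiber pixels only, so the result is a smooth intensity map
#' tracking the cell thickness profile (free GFP monomer) with no fiber
#' structures.  Windows are clipped at image borders (no padding).  A
#' window that contains fewer than `min_px` non-fiber pixels is grown in
#' `grow_step`-pixel steps until enough are available, preserving locality
#' for windows fully covered by fibers.
#'
#' @param image numeric matrix (AU).
#' @param fiber_mask logical matrix of fiber pixels to exclude.
#' @param window odd window size (default 21, i.e. 21 x 21).
#' @param grow_step window growth per fallback step (pixels per side).
#' @param min_px minimum usable pixels per window.
#' @return numeric matrix, the background (unbound protein) map.
#' @export
estimate_background <- function(image, fiber_mask, window = 21L,
                                grow_step = 10L, min_px = 10L) {
  stopifnot(all(dim(image) == dim(fiber_mask)))
  if (window > min(dim(image)))
    stop("filtering window is larger than the image")
  masked_median_cpp(image, fiber_mask, as.integer(window),
                    as.integer(grow_step), as.integer(min_px))
}

#' Build the F-protein map
#'
#' Subtracts the unbound-protein background from the image and keeps only
#' pixels that belong to a fiber and have a positive residual intensity.
#' The sum of the map measures the amount of GFP-tagged protein assembled
#' in filamentous form (F_GFP).
#'
#' @param image numeric matrix (AU).
#' @param fiber_mask logical fiber mask.
#' @param background background map from [estimate_background()].
#' @return list with `map` (zero outside the retained fiber pixels),
#'   `mask` (fiber pixels with positive residual), and `f_gfp` (sum).
#' @export
f_protein_map <- function(image, fiber_mask, background) {
  stopifnot(all(dim(image) == dim(fiber_mask)),
            all(dim(image) == dim(background)))
  resid <- image - background
  keep <- fiber_mask & resid > 0
  map <- ifelse(keep, resid, 0)
  list(map = map, mask = keep, f_gfp = sum(map))
}

#' Total cell fluorescence intensity
#'
#' Sum of raw intensities over the cell footprint, measuring the total
#' amount of exogenous GFP protein (P_GFP).  An optional camera dark
#' offset is subtracted per pixel before summing.
#'
#' @param image numeric matrix (AU).
#' @param cell_mask logical cell mask, non-empty.
#' @param dark_offset camera offset (AU per pixel) subtracted first.
#' @return scalar P_GFP (AU).
#' @export
total_cell_intensity <- function(image, cell_mask, dark_offset = 0) {
  if (!any(cell_mask)) stop("cell mask is empty")
  sum(image[cell_mask] - dark_offset)
}

#' Estimate the cell footprint from unbound-GFP fluorescence
#'
#' Free GFP fills the cytoplasm, so a heavy Gaussian blur followed by
#' Otsu thresholding delineates the cell; the mask is then morphologically
#' closed, reduced to its largest connected component and hole-filled.
#'
#' @param image numeric matrix (AU).
#' @param blur_sigma Gaussian sigma (pixels) of the pre-smoothing.
#' @param close_size size of the closing brush (pixels).
#' @return logical matrix.
#' @export
estimate_cell_mask <- function(image, blur_sigma = 8, close_size = 7L) {
  sm <- .gauss_smooth(image, blur_sigma)
  rng <- range(sm)
  if (diff(rng) <= 0) stop("image is constant; no cell to segment")
  scaled <- (sm - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1))
  m <- EBImage::Image(scaled > thr)
  brush <- EBImage::makeBrush(close_size, shape = "disc")
  m <- EBImage::closing(m, brush)
  lab <- EBImage::bwlabel(m)
  tab <- tabulate(as.integer(lab))
  if (length(tab) == 0 || max(tab) == 0) stop("no cell found")
  m <- lab == which.max(tab)
  m <- EBImage::fillHull(EBImage::Image(m))
  matrix(as.logical(as.matrix(m)), nrow(image), ncol(image))
}
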