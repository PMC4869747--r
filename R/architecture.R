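#' Fiber alignment and mean orientation
#'
#' Circular variance and circular mean of the local fiber orientations:
#' \deqn{FA = 1 - \sqrt{\bar C^2 + \bar S^2}, \qquad
#'   \bar\theta = \mathrm{atan2}(\bar S, \bar C)}
#' with \eqn{\bar C, \bar S} the means of \eqn{\cos\theta_n, \sin\theta_n}
#' over all fiber pixels.  FA close to 0 indicates strongly aligned
#' fibers.  By default the statistics are computed directly on the
#' orientations in `[0, 180)` degrees; `double_angle = TRUE` switches to
#' standard axial statistics on `2 theta` (note the two conventions give
#' different values for dispersed orientations: uniform axial angles give
#' `1 - 2/pi` directly but 1 under angle doubling).
#'
#' @param lof_deg orientation map (degrees, `NA` off-mask) or a vector of
#'   orientations.
#' @param double_angle use the doubled-angle axial convention.
#' @return list with `fa`, `theta_bar_deg`, `c_bar`, `s_bar`, `n`.
#' @export
fiber_alignment <- function(lof_deg, double_angle = FALSE) {
  th <- lof_deg[is.finite(lof_deg)]
  if (length(th) == 0) stop("no fiber pixels: alignment undefined")
  mult <- if (double_angle) 2 else 1
  rad <- th * pi / 180 * mult
  c_bar <- mean(cos(rad)); s_bar <- mean(sin(rad))
  theta_bar <- (atan2(s_bar, c_bar) / mult * 180 / pi) %% 180
  list(fa = 1 - sqrt(c_bar^2 + s_bar^2), theta_bar_deg = theta_bar,
       c_bar = c_bar, s_bar = s_bar, n = length(th))
}

#' Apparent fiber thickness
#'
#' Mean F-protein intensity over the fiber pixels (`FT_GFP`), scaled by
#' the calibration factor `1 + P_endo / P_GFP` to account for the
#' unlabelled endogenous pool (`FT`).
#'
#' @param fprotein result of [f_protein_map()] (or a list with `map` and
#'   `mask`).
#' @param p_gfp total exogenous GFP of the cell (AU).
#' @param p_endo batch-level scaling factor (AU).
#' @return list with `ft_gfp` and `ft` (AU per pixel).
#' @export
fiber_thickness <- function(fprotein, p_gfp, p_endo = 0) {
  if (!any(fprotein$mask)) stop("empty fiber mask: thickness undefined")
  ft_gfp <- mean(fprotein$map[fprotein$mask])
  list(ft_gfp = ft_gfp, ft = ft_gfp * (1 + p_endo / p_gfp))
}

#' Concentric erosion rings of a cell mask
#'
#' Partitions the cell footprint into 1-pixel-thick concentric rings by
#' iterated unit erosion (realized through the Euclidean distance
#' transform, which avoids the metric distortion of square or diamond
#' structuring elements).  Ring 1 is the outermost.
#'
#' @param cell_mask logical matrix.
#' @return integer matrix: ring index per cell pixel, 0 outside.
#' @export
erosion_rings <- function(cell_mask) {
  dm <- EBImage::distmap(EBImage::Image(cell_mask))
  ring <- ceiling(as.matrix(dm))
  ring[!cell_mask] <- 0L
  storage.mode(ring) <- "integer"
  ring
}

#' Radial location of fiber density
#'
#' Average F-protein intensity in each concentric erosion ring of the
#' cell, on a radial axis normalized so the outermost ring maps to 1 and
#' the innermost to 0.  The radial location (RL) is the normalized radius
#' of the ring with the highest mean fiber density; ties are broken toward
#' the periphery.  Rings without fiber intensity contribute zero density.
#'
#' @param fprotein_map numeric matrix (the F-protein map; zero off-fiber).
#' @param cell_mask logical cell footprint.
#' @return list with `rl`, `profile` (data frame `radius`, `density`,
#'   `n_px`), `n_rings`.
#' @export
radial_location <- function(fprotein_map, cell_mask) {
  if (!any(cell_mask)) stop("cell mask is empty")
  ring <- erosion_rings(cell_mask)
  k <- max(ring)
  if (k < 2) stop("cell mask thinner than 2 rings")
  idx <- ring[cell_mask]
  dens <- vapply(seq_len(k), function(i)
    mean(fprotein_map[cell_mask][idx == i]), numeric(1))
  n_px <- tabulate(idx, nbins = k)
  radius <- 1 - (seq_len(k) - 1) / (k - 1)
  best <- which(dens == max(dens))
  rl <- radius[min(best)]  # smallest ring index = outermost
  list(rl = rl,
       profile = data.frame(radius = radius, density = dens, n_px = n_px),
       n_rings = k)
}

#' Cell geometry from the mask's second moments
#'
#' Area from the pixel count and physical pixel size; aspect ratio and
#' major-axis direction from the eigendecomposition of the pixel
#' coordinate covariance (the mask's second-moment ellipse).  The axis
#' direction uses the same convention as the orientation maps: 0 degrees
#' toward the bottom edge, 90 degrees left-right.
#'
#' @param cell_mask logical matrix.
#' @param pixel_size_um physical pixel size (micrometres per pixel).
#' @return list with `area_um2`, `aspect_ratio` (>= 1),
#'   `major_axis_deg` in `[0, 180)`.
#' @export
cell_geometry <- function(cell_mask, pixel_size_um = 1) {
  if (!any(cell_mask)) stop("cell mask is empty")
  idx <- which(cell_mask, arr.ind = TRUE)
  cv <- stats::cov(idx) + diag(1 / 12, 2)  # pixel quantization variance
  e <- eigen(cv, symmetric = TRUE)
  major <- e$vectors[, 1]
  angle <- (atan2(major[2], major[1]) * 180 / pi) %% 180
  list(area_um2 = nrow(idx) * pixel_size_um^2,
       aspect_ratio = sqrt(e$values[1] / e$values[2]),
       major_axis_deg = angle)
}
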