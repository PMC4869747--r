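#' Refinement configuration
#'
#' Parameters for the iterative fiber-map refinement: coherence-enhancing
#' diffusion filtering (CEDF) that completes interrupted lines, followed
#' by trimming of pixels whose orientation disagrees with their fiber
#' neighborhood.
#'
#' @param neighborhood odd window size for the orientation comparison
#'   (default 9, i.e. a 9 x 9 neighborhood).
#' @param cos_threshold acceptance threshold on the mean cosine of the
#'   axial orientation difference to the fiber neighbors (default 0.995).
#' @param angle_slack_deg orientation differences up to this value
#'   (default 6, one step of the default 30-kernel bank) count as perfect
#'   alignment before the cosine is taken; the orientation map is
#'   quantized to the bank's angular resolution, so one-step differences
#'   between neighbors on the same fiber carry no misalignment evidence.
#'   Set to 0 for the literal mean-cosine criterion.
#' @param min_neighbors minimum number of fiber neighbors a pixel must
#'   see in its window.  A fiber running through the window contributes
#'   roughly `neighborhood x band width` neighbors; the default demands
#'   half the count of a minimal (3-pixel-wide) through-going fiber, so
#'   tiny isolated coherent clusters -- the remnants of bright dots --
#'   are rejected while fiber interiors and ends are kept.  Set to 1 to
#'   only require a non-empty neighborhood.
#' @param sigma_grad,rho_tensor Gaussian scales (pixels) for the gradient
#'   and the structure tensor used by CEDF.
#' @param n_steps,dt number and size of the diffusion time steps.  The
#'   default 15 steps of 0.2 give a total diffusion time of 3, enough to
#'   bridge 2-3 pixel gaps along a coherent line in one enhancement pass.
#' @param coherence_contrast contrast parameter of the coherence
#'   diffusivity (scaled for unit-amplitude relaxed masks).
#' @param binarize_at re-binarization level applied to the diffused
#'   relaxation.
#' @param max_iterations cap on the enhance/trim iteration.
#' @return list of class `refinement_config`.
#' @export
refinement_config <- function(neighborhood = 9L, cos_threshold = 0.995,
                              angle_slack_deg = 6,
                              min_neighbors = (3L * neighborhood - 1L) %/%
                                2L,
                              sigma_grad = 1, rho_tensor = 4,
                              n_steps = 15L, dt = 0.2,
                              coherence_contrast = 1e-6,
                              binarize_at = 0.5, max_iterations = 50L) {
  if (cos_threshold <= 0 || cos_threshold > 1)
    stop("cos_threshold must be in (0, 1]")
  if (neighborhood < 3 || neighborhood %% 2 == 0)
    stop("neighborhood must be odd and >= 3")
  structure(list(neighborhood = as.integer(neighborhood),
                 cos_threshold = cos_threshold,
                 angle_slack_deg = angle_slack_deg,
                 min_neighbors = as.integer(min_neighbors),
                 sigma_grad = sigma_grad,
                 rho_tensor = rho_tensor, n_steps = as.integer(n_steps),
                 dt = dt, coherence_contrast = coherence_contrast,
                 binarize_at = binarize_at,
                 max_iterations = as.integer(max_iterations)),
            class = "refinement_config")
}

.gauss_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma))
  x <- -half:half
  g <- exp(-x^2 / (2 * sigma^2)); g <- g / sum(g)
  .conv_reflect(m, outer(g, g))
}

.shift <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
  m[ri, ci]
}

#' Coherence-enhancing diffusion of a binary fiber mask
#'
#' Relaxes the mask to a real-valued field, applies coherence-enhancing
#' anisotropic diffusion (diffusivity near 1 along locally coherent line
#' directions, near 0 elsewhere), and re-binarizes.  Gaps along coherent
#' structures tend to close; isolated blobs, which have no coherent
#' direction, barely spread.  The result is returned as the union with the
#' input mask, so enhancement only ever adds pixels; removal is the role
#' of [orientation_trim()].
#'
#' @param mask logical matrix.
#' @param config a [refinement_config()].
#' @return logical matrix.
#' @export
cedf_enhance <- function(mask, config = refinement_config()) {
  if (!any(mask)) return(mask)
  u <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  eps_iso <- 1e-3   # small isotropic diffusivity floor
  for (step in seq_len(config$n_steps)) {
    us <- .gauss_smooth(u, config$sigma_grad)
    gy <- (.shift(us, 1L, 0L) - .shift(us, -1L, 0L)) / 2
    gx <- (.shift(us, 0L, 1L) - .shift(us, 0L, -1L)) / 2
    j11 <- .gauss_smooth(gy * gy, config$rho_tensor)
    j12 <- .gauss_smooth(gy * gx, config$rho_tensor)
    j22 <- .gauss_smooth(gx * gx, config$rho_tensor)
    # closed-form eigenvalues of the 2x2 structure tensor
    tr <- j11 + j22
    disc <- sqrt(pmax((j11 - j22)^2 + 4 * j12^2, 0))
    mu1 <- (tr + disc) / 2
    mu2 <- (tr - disc) / 2
    coh <- (mu1 - mu2)^2
    lam2 <- eps_iso + (1 - eps_iso) *
      ifelse(coh > 0, exp(-config$coherence_contrast / coh), 0)
    # eigenvector of mu1 (gradient-dominant direction): (j12, mu1 - j11)
    v1y <- j12; v1x <- mu1 - j11
    nrm <- sqrt(v1y^2 + v1x^2)
    flat <- nrm < 1e-12
    v1y <- ifelse(flat, 1, v1y / nrm)
    v1x <- ifelse(flat, 0, v1x / nrm)
    # D = eps * v1 v1' + lam2 * v2 v2', with v2 perpendicular to v1
    d11 <- eps_iso * v1y^2 + lam2 * v1x^2
    d22 <- eps_iso * v1x^2 + lam2 * v1y^2
    d12 <- (eps_iso - lam2) * v1y * v1x
    uy <- (.shift(u, 1L, 0L) - .shift(u, -1L, 0L)) / 2
    ux <- (.shift(u, 0L, 1L) - .shift(u, 0L, -1L)) / 2
    fy <- d11 * uy + d12 * ux
    fx <- d12 * uy + d22 * ux
    div <- (.shift(fy, 1L, 0L) - .shift(fy, -1L, 0L)) / 2 +
      (.shift(fx, 0L, 1L) - .shift(fx, 0L, -1L)) / 2
    u <- u + config$dt * div
  }
  (u >= config$binarize_at) | mask
}

#' Trim fiber pixels with inconsistent orientation
#'
#' Keeps a fiber pixel only if the mean cosine of the axial orientation
#' difference to all other fiber pixels in its neighborhood exceeds the
#' configured threshold.  Orientations are compared on the minimal axial
#' difference, so 1 and 179 degrees count as 2 degrees apart.  Pixels with
#' no fiber neighbor in the window are removed.
#'
#' @param mask logical matrix.
#' @param lof_deg orientation map in degrees; must be defined (non-NA) on
#'   every mask pixel.
#' @param config a [refinement_config()].
#' @return logical matrix (a subset of `mask`).
#' @export
orientation_trim <- function(mask, lof_deg, config = refinement_config()) {
  if (any(mask & !is.finite(lof_deg)))
    stop("orientation must be defined on every mask pixel")
  theta <- lof_deg * pi / 180
  theta[!is.finite(theta)] <- 0
  orientation_trim_cpp(mask, theta, config$neighborhood,
                       config$cos_threshold,
                       config$angle_slack_deg * pi / 180,
                       config$min_neighbors)
}

#' Iterative fiber-map refinement
#'
#' Alternates [cedf_enhance()] and [orientation_trim()] until the binary
#' fiber map stops changing or the iteration cap is reached (with a
#' warning).  Pixels added by the enhancement receive the orientation of
#' the best-responding kernel at that pixel, taken from the segmentation's
#' full argmax-angle map, so the refined orientation map covers the whole
#' final mask.
#'
#' @param seg a [segment_fibers()] result (or a list with `mask` and
#'   `angles_full_deg`).
#' @param config a [refinement_config()].
#' @return `fiber_segmentation` object with the refined `mask` and
#'   `lof_deg`, plus `iterations` and `converged`.
#' @export
refine_segmentation <- function(seg, config = refinement_config()) {
  mask <- seg$mask
  angles <- seg$angles_full_deg
  converged <- FALSE
  it <- 0L
  while (it < config$max_iterations) {
    it <- it + 1L
    enhanced <- cedf_enhance(mask, config)
    trimmed <- orientation_trim(enhanced, angles, config)
    if (identical(trimmed, mask)) { converged <- TRUE; break }
    mask <- trimmed
  }
  if (!converged)
    warning("refinement reached the iteration cap before a fixed point")
  out <- seg
  out$mask <- mask
  out$lof_deg <- ifelse(mask, angles, NA_real_)
  out$iterations <- it
  out$converged <- converged
  class(out) <- "fiber_segmentation"
  out
}
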