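#' Build a rotated elongated Laplace-of-Gaussian kernel bank
#'
#' The base kernel is the (sign-flipped) Laplacian of an anisotropic
#' Gaussian elongated along the fiber axis, which responds maximally to a
#' bright ridge aligned with the kernel's long axis.  The bank holds `n`
#' copies rotated in steps of `pi/n`; convolving an image with all of them
#' and taking the per-pixel argmax yields the local orientation of fibers.
#' Each kernel is forced to be exactly zero-mean, so the response is
#' invariant to adding a constant to the image.
#'
#' @param n number of rotation steps over `[0, pi)` (default 30, i.e.
#'   6-degree steps).
#' @param sigma_along,sigma_across Gaussian sigmas (pixels) along and
#'   across the fiber axis; elongation requires `sigma_along >
#'   sigma_across`.
#' @param support kernel support (pixels, odd); default
#'   `ceiling(6 * sigma_along)` rounded up to odd.
#' @return object of class `kernel_bank`: list with `kernels` (list of
#'   matrices), `angles_deg`, `sigma_along`, `sigma_across`, `support`.
#' @export
elog_bank <- function(n = 30L, sigma_along = 6, sigma_across = 1.5,
                      support = NULL) {
  if (n < 2) stop("need at least 2 kernel orientations")
  if (sigma_along <= 0 || sigma_across <= 0) stop("sigmas must be > 0")
  if (sigma_along <= sigma_across)
    stop("kernel must be elongated: sigma_along > sigma_across")
  if (is.null(support)) support <- ceiling(6 * sigma_along)
  support <- as.integer(support)
  if (support %% 2L == 0L) support <- support + 1L
  angles <- (seq_len(n) - 1L) * pi / n
  kernels <- lapply(angles, function(th)
    .elog_kernel(th, sigma_along, sigma_across, support))
  structure(list(kernels = kernels, angles_deg = angles * 180 / pi,
                 n = as.integer(n), sigma_along = sigma_along,
                 sigma_across = sigma_across, support = support),
            class = "kernel_bank")
}

# -Laplacian of an anisotropic Gaussian whose long axis points along
# direction (cos theta, sin theta) in (row, col) coordinates; zero-meaned
.elog_kernel <- function(theta, sa, sc, support) {
  half <- (support - 1) / 2
  dy <- matrix(-half:half, support, support)
  dx <- matrix(-half:half, support, support, byrow = TRUE)
  u <- dy * cos(theta) + dx * sin(theta)   # along the fiber axis
  v <- -dy * sin(theta) + dx * cos(theta)  # across
  g <- exp(-u^2 / (2 * sa^2) - v^2 / (2 * sc^2))
  k <- -g * ((u^2 - sa^2) / sa^4 + (v^2 - sc^2) / sc^4)
  k - mean(k)
}

#' Segment fibers and their local orientation
#'
#' Convolves the image with every kernel of the bank (reflective padding),
#' takes the per-pixel maximum response, thresholds it to obtain the
#' binary fiber mask, and records for each pixel the rotation angle of the
#' kernel with the highest response -- the local orientation of fibers
#' (LOF) map.  Bright-spot artifacts are deliberately not removed at this
#' stage; the refinement stage handles them.
#'
#' @param image numeric matrix (AU).
#' @param bank a [elog_bank()].
#' @param cell_mask optional logical matrix restricting thresholding and
#'   the output mask to the cell footprint.
#' @param threshold thresholding of the max-response image: `"otsu"`
#'   (default) applies Otsu's threshold to the in-cell response histogram
#'   (parameter-free and invariant to intensity offset and scale);
#'   `"relative"` uses `value` times the maximum response; `"absolute"`
#'   uses `value` in response units.
#' @param value threshold parameter (fraction or absolute level).
#' @return object of class `fiber_segmentation`: list with `mask`
#'   (logical), `lof_deg` (orientation in degrees, `NA` off-mask),
#'   `response` (max-response image), `angles_full_deg` (argmax angle at
#'   every pixel, used to re-orient pixels added later), `threshold`.
#' @export
segment_fibers <- function(image, bank, cell_mask = NULL,
                           threshold = c("otsu", "relative", "absolute"),
                           value = NULL) {
  stopifnot(inherits(bank, "kernel_bank"))
  threshold <- match.arg(threshold)
  if (min(dim(image)) < bank$support)
    stop("image is smaller than the kernel support")
  resp_max <- matrix(-Inf, nrow(image), ncol(image))
  arg <- matrix(1L, nrow(image), ncol(image))
  for (k in seq_len(bank$n)) {
    r <- .conv_reflect(image, bank$kernels[[k]])
    upd <- r > resp_max
    resp_max[upd] <- r[upd]
    arg[upd] <- k
  }
  angles_full <- matrix(bank$angles_deg[arg], nrow(image), ncol(image))
  roi <- if (is.null(cell_mask)) rep(TRUE, length(resp_max)) else cell_mask
  rng <- range(resp_max[roi])
  # a constant image leaves only numerical round-off in the response
  if (diff(rng) < 1e-8 * (max(abs(image)) + 1)) {
    thr <- Inf  # no ridge response anywhere
  } else if (threshold == "otsu") {
    scaled <- (resp_max - rng[1]) / diff(rng)
    scaled[scaled < 0] <- 0; scaled[scaled > 1] <- 1
    t01 <- EBImage::otsu(EBImage::Image(scaled[roi], dim = c(sum(roi), 1)),
                         range = c(0, 1))
    thr <- rng[1] + t01 * diff(rng)
  } else if (threshold == "relative") {
    if (is.null(value)) stop("relative threshold needs a value")
    thr <- value * max(resp_max[roi])
  } else {
    if (is.null(value)) stop("absolute threshold needs a value")
    thr <- value
  }
  mask <- resp_max > thr
  if (!is.null(cell_mask)) mask <- mask & cell_mask
  lof <- ifelse(mask, angles_full, NA_real_)
  structure(list(mask = mask, lof_deg = lof, response = resp_max,
                 angles_full_deg = angles_full, threshold = thr,
                 bank = bank),
            class = "fiber_segmentation")
}
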