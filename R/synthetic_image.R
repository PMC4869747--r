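#' Specification of a synthetic fluorescence image
#'
#' Builds the parameter set consumed by [render_fiber_image()].  The
#' synthetic scene emulates an epifluorescence image of a GFP-transfected
#' adherent cell: an elliptical cell footprint filled with a smooth
#' unbound-protein background (highest over the thick cytosol around the
#' nucleus, with a central dip where the nucleus excludes free GFP), a set
#' of straight stress fibers with Gaussian cross-section, optional round
#' bright-dot artifacts, and additive Gaussian camera noise.
#'
#' @param dim image size in pixels, `c(rows, cols)`.
#' @param pixel_size_um physical pixel size (micrometres per pixel).
#' @param cell list with `center` (row, col), `semi_axes` (pixels,
#'   `c(along rows, along cols)`) and `phi_deg` (ellipse rotation).
#' @param fibers data frame with one row per fiber: `r0`, `c0` (centre,
#'   pixels), `theta_deg` (orientation in `[0, 180)`, 0 = toward the bottom
#'   edge, 90 = left-right), `length_px`, `width_px` (Gaussian sigma of the
#'   cross-section, >= 1), `peak` (peak intensity, AU).
#' @param background list with `type` (`"dome"`, `"ramp"` or `"constant"`),
#'   `amplitude` (AU), `offset` (AU added everywhere), `nucleus_depth` (AU)
#'   and `nucleus_radius_px` for the central dip.
#' @param dots `NULL` or data frame with `r`, `c`, `sigma_px`, `peak`:
#'   round bright-spot artifacts (not part of the fiber ground truth).
#' @param noise_sd additive Gaussian noise sigma (AU), >= 0.
#' @param seed integer seed making rendering reproducible.
#' @return object of class `synthetic_image_spec`.
#' @seealso [render_fiber_image()], [fibers_random()], [fibers_annulus()]
#' @export
synthetic_image_spec <- function(dim = c(256L, 256L),
                                 pixel_size_um = 0.5,
                                 cell = list(center = NULL,
                                             semi_axes = c(100, 110),
                                             phi_deg = 0),
                                 fibers = NULL,
                                 background = list(type = "dome",
                                                   amplitude = 60,
                                                   offset = 5,
                                                   nucleus_depth = 30,
                                                   nucleus_radius_px = 25),
                                 dots = NULL,
                                 noise_sd = 4,
                                 seed = 1L) {
  cell_def <- list(center = NULL, semi_axes = c(100, 110), phi_deg = 0)
  bg_def <- list(type = "dome", amplitude = 60, offset = 5,
                 nucleus_depth = 30, nucleus_radius_px = 25,
                 ramp_range = c(10, 70))
  cell <- modifyList(cell_def, cell)
  background <- modifyList(bg_def, background)
  if (is.null(cell$center)) cell$center <- (dim + 1) / 2
  spec <- structure(list(dim = as.integer(dim),
                         pixel_size_um = pixel_size_um,
                         cell = cell, fibers = fibers,
                         background = background, dots = dots,
                         noise_sd = noise_sd, seed = as.integer(seed)),
                    class = "synthetic_image_spec")
  validate_image_spec(spec)
  spec
}

validate_image_spec <- function(spec) {
  stopifnot(length(spec$dim) == 2, all(spec$dim >= 16))
  if (spec$noise_sd < 0) stop("noise_sd must be >= 0")
  f <- spec$fibers
  if (!is.null(f) && nrow(f) > 0) {
    if (any(f$width_px < 1)) stop("fiber widths must be >= 1 px")
    if (any(f$theta_deg < 0 | f$theta_deg >= 180))
      stop("fiber orientations must lie in [0, 180) degrees")
    ends <- .fiber_endpoints(f)
    if (any(ends$r < 1 | ends$r > spec$dim[1] |
            ends$c < 1 | ends$c > spec$dim[2]))
      stop("fiber outside image bounds")
    if (any(!.in_ellipse(ends$r, ends$c, spec$cell)))
      stop("fiber outside cell mask")
  }
  invisible(spec)
}

.fiber_endpoints <- function(f) {
  dr <- cos(f$theta_deg * pi / 180) * f$length_px / 2
  dc <- sin(f$theta_deg * pi / 180) * f$length_px / 2
  list(r = c(f$r0 - dr, f$r0 + dr), c = c(f$c0 - dc, f$c0 + dc))
}

.in_ellipse <- function(r, c, cell) {
  phi <- cell$phi_deg * pi / 180
  dy <- r - cell$center[1]; dx <- c - cell$center[2]
  u <- dy * cos(phi) + dx * sin(phi)
  v <- -dy * sin(phi) + dx * cos(phi)
  (u / cell$semi_axes[1])^2 + (v / cell$semi_axes[2])^2 <= 1
}

.ellipse_mask <- function(dim, cell) {
  rr <- matrix(seq_len(dim[1]), dim[1], dim[2])
  cc <- matrix(seq_len(dim[2]), dim[1], dim[2], byrow = TRUE)
  .in_ellipse(rr, cc, cell)
}

#' Random fibers inside the cell footprint
#'
#' Draws `n` fibers with the given orientations, uniformly positioned so
#' that both endpoints fall inside the cell ellipse.
#'
#' @param n number of fibers.
#' @param cell cell geometry as in [synthetic_image_spec()].
#' @param thetas_deg orientations; recycled to length `n`.  The default
#'   `NULL` spaces them evenly over `[0, 180)`.
#' @param length_px,width_px,peak fiber geometry and brightness.
#' @return data frame suitable for the `fibers` field of a spec.
#' @export
fibers_random <- function(n, cell, thetas_deg = NULL, length_px = 90,
                          width_px = 1.5, peak = 150) {
  if (is.null(thetas_deg)) thetas_deg <- (seq_len(n) - 0.5) * 180 / n
  thetas_deg <- rep_len(thetas_deg, n)
  r0 <- c0 <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      # sample centre in a shrunken ellipse, then verify both endpoints
      a <- runif(1, 0, 2 * pi); rad <- sqrt(runif(1))
      cand_r <- cell$center[1] + 0.8 * cell$semi_axes[1] * rad * cos(a)
      cand_c <- cell$center[2] + 0.8 * cell$semi_axes[2] * rad * sin(a)
      f1 <- data.frame(r0 = cand_r, c0 = cand_c, theta_deg = thetas_deg[i],
                       length_px = length_px)
      e <- .fiber_endpoints(f1)
      if (all(.in_ellipse(e$r, e$c, cell))) break
    }
    r0[i] <- cand_r; c0[i] <- cand_c
  }
  data.frame(r0 = r0, c0 = c0, theta_deg = thetas_deg,
             length_px = length_px, width_px = width_px, peak = peak)
}

#' Parallel fiber families in separate regions of the cell
#'
#' Adherent fibroblasts typically display stress fibers running in
#' parallel within distinct spatial domains.  This layout divides the
#' cell into angular sectors (one per family, Voronoi cells of the sector
#' bisectors on the circle); within a sector, fibers run parallel to the
#' sector bisector on a staggered grid with a fixed perpendicular
#' spacing, producing fan-like fiber domains in which fibers of different
#' orientations essentially never cross.
#'
#' @param n total number of fibers (divided between the families).
#' @param cell cell geometry as in [synthetic_image_spec()].
#' @param family_angles_deg one orientation per family, in `[0, 180)`;
#'   the default three families are 60 degrees apart.
#' @param spacing_px perpendicular distance between fibers of a family.
#' @param length_px,width_px,peak fiber geometry and brightness.
#' @return data frame suitable for the `fibers` field of a spec.
#' @export
fibers_families <- function(n, cell, family_angles_deg = c(30, 90, 150),
                            spacing_px = 12, length_px = 55, width_px = 1.5,
                            peak = 150) {
  k <- length(family_angles_deg)
  per <- diff(round(seq(0, n, length.out = k + 1)))
  # sector bisectors: alternate the two axial senses so the bisectors
  # spread around the full circle (for the default three families they
  # end up exactly 120 degrees apart)
  bis <- (family_angles_deg + 180 * (seq_len(k) %% 2)) %% 360
  circ_d <- function(a, b) {
    d <- abs(a - b) %% 360
    pmin(d, 360 - d)
  }
  sector_of <- function(r, c) {
    ang <- (atan2(c - cell$center[2], r - cell$center[1]) * 180 / pi) %%
      360
    dmat <- vapply(bis, function(b) circ_d(ang, b),
                   numeric(length(ang)))
    max.col(-matrix(dmat, ncol = k))
  }
  out <- NULL
  for (j in seq_len(k)) {
    th <- family_angles_deg[j] * pi / 180
    dirv <- c(cos(th), sin(th)); perp <- c(-sin(th), cos(th))
    bth <- bis[j] * pi / 180
    bhat <- c(cos(bth), sin(bth))
    f <- NULL
    for (len in seq(length_px, 35, by = -10)) {
      cand <- expand.grid(p = seq(-1.8 * max(cell$semi_axes),
                                  1.8 * max(cell$semi_axes),
                                  by = spacing_px),
                          rho = seq(15, max(cell$semi_axes) - 10,
                                    by = len + 12))
      fc <- data.frame(r0 = cell$center[1] + cand$rho * bhat[1] +
                         cand$p * perp[1],
                       c0 = cell$center[2] + cand$rho * bhat[2] +
                         cand$p * perp[2],
                       theta_deg = family_angles_deg[j], length_px = len,
                       width_px = width_px, peak = peak)
      e <- .fiber_endpoints(fc)
      m <- nrow(fc)
      ok <- .in_ellipse(e$r[1:m], e$c[1:m], cell) &
        .in_ellipse(e$r[m + 1:m], e$c[m + 1:m], cell)
      # the fiber's whole band (not just the centerline) must stay in the
      # sector, so families keep out of each other's trim neighborhoods
      for (off in c(-8, 0, 8)) {
        ok <- ok &
          sector_of(e$r[1:m] + off * perp[1],
                    e$c[1:m] + off * perp[2]) == j &
          sector_of(e$r[m + 1:m] + off * perp[1],
                    e$c[m + 1:m] + off * perp[2]) == j
      }
      fc <- fc[ok, , drop = FALSE]
      if (!is.null(f) && nrow(f) > 0) {
        keep <- vapply(seq_len(nrow(fc)), function(i) {
          dr <- fc$r0[i] - f$r0; dc <- fc$c0[i] - f$c0
          all(abs(dr * perp[1] + dc * perp[2]) >= spacing_px - 1e-9 |
                abs(dr * dirv[1] + dc * dirv[2]) >=
                  (fc$length_px[i] + f$length_px) / 2 + 10)
        }, logical(1))
        fc <- fc[keep, , drop = FALSE]
      }
      f <- rbind(f, fc)
      if (nrow(f) >= per[j]) break
    }
    if (is.null(f) || nrow(f) < per[j])
      stop("family ", j, " cannot host ", per[j], " fibers; ",
           "reduce n or spacing")
    # prefer fibers near the middle of the sector
    mid_rho <- 0.55 * max(cell$semi_axes)
    dr <- f$r0 - cell$center[1]; dc <- f$c0 - cell$center[2]
    rho_f <- dr * bhat[1] + dc * bhat[2]
    p_f <- dr * perp[1] + dc * perp[2]
    pref <- order(abs(rho_f - mid_rho) + 0.5 * abs(p_f))
    out <- rbind(out, f[pref[seq_len(per[j])], ])
  }
  rownames(out) <- NULL
  out
}

#' Short tangential fibers on an annulus
#'
#' Places `n` short fibers tangentially on a circle at a fixed fraction of
#' the cell radius, emulating a peripheral (or central) band of stress
#' fibers with a known radial location.
#'
#' @param n number of fibers.
#' @param cell cell geometry; the radius used is
#'   `radius_frac * min(semi_axes)` around the cell centre.
#' @param radius_frac fraction of the cell radius, in (0, 1).
#' @param length_px,width_px,peak fiber geometry and brightness.
#' @return data frame suitable for the `fibers` field of a spec.
#' @export
fibers_annulus <- function(n, cell, radius_frac = 0.7, length_px = 14,
                           width_px = 1.5, peak = 150) {
  rad <- radius_frac * min(cell$semi_axes)
  psi <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  r0 <- cell$center[1] + rad * cos(psi)
  c0 <- cell$center[2] + rad * sin(psi)
  # tangent direction at angle psi, folded to [0, 180)
  theta <- (atan2(cos(psi), -sin(psi)) * 180 / pi) %% 180
  theta[theta >= 180] <- 0  # guard the floating-point seam
  data.frame(r0 = r0, c0 = c0, theta_deg = theta,
             length_px = length_px, width_px = width_px, peak = peak)
}

#' Random bright-dot artifacts inside the cell
#'
#' Dots emulate bright protein aggregates in the cytosol.  Like free GFP
#' fusion protein, large aggregates are excluded from the nucleus, so
#' dots avoid a central disc.
#'
#' @param n number of dots.
#' @param cell cell geometry as in [synthetic_image_spec()].
#' @param sigma_px Gaussian radius of each dot.
#' @param peak peak intensity (AU).
#' @param exclude_center_px dots are kept at least this far from the cell
#'   centre (the nucleus region).
#' @return data frame for the `dots` field of a spec.
#' @export
dots_random <- function(n, cell, sigma_px = 2, peak = 200,
                        exclude_center_px = 32) {
  r <- c <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      a <- runif(1, 0, 2 * pi); rad <- sqrt(runif(1))
      ri <- cell$center[1] + 0.75 * cell$semi_axes[1] * rad * cos(a)
      ci <- cell$center[2] + 0.75 * cell$semi_axes[2] * rad * sin(a)
      if ((ri - cell$center[1])^2 + (ci - cell$center[2])^2 >=
            exclude_center_px^2) break
    }
    r[i] <- ri; c[i] <- ci
  }
  data.frame(r = r, c = c, sigma_px = sigma_px, peak = peak)
}

.render_segment_layer <- function(dim, f, cutoff_sigma = 3) {
  layer <- matrix(0, dim[1], dim[2])
  th <- f$theta_deg * pi / 180
  ur <- cos(th); uc <- sin(th)
  half <- f$length_px / 2
  margin <- ceiling(cutoff_sigma * f$width_px)
  r_lo <- max(1, floor(f$r0 - abs(ur) * half - margin))
  r_hi <- min(dim[1], ceiling(f$r0 + abs(ur) * half + margin))
  c_lo <- max(1, floor(f$c0 - abs(uc) * half - margin))
  c_hi <- min(dim[2], ceiling(f$c0 + abs(uc) * half + margin))
  rr <- matrix(r_lo:r_hi, r_hi - r_lo + 1, c_hi - c_lo + 1)
  cc <- matrix(c_lo:c_hi, r_hi - r_lo + 1, c_hi - c_lo + 1, byrow = TRUE)
  dy <- rr - f$r0; dx <- cc - f$c0
  t_along <- dy * ur + dx * uc          # signed distance along the axis
  t_clamp <- pmin(pmax(t_along, -half), half)
  pr <- f$r0 + t_clamp * ur; pc <- f$c0 + t_clamp * uc
  d2 <- (rr - pr)^2 + (cc - pc)^2
  v <- f$peak * exp(-d2 / (2 * f$width_px^2))
  v[d2 > (cutoff_sigma * f$width_px)^2] <- 0
  layer[r_lo:r_hi, c_lo:c_hi] <- v
  layer
}

.render_background <- function(spec, cell_mask) {
  dim <- spec$dim; bg <- spec$background; cell <- spec$cell
  rr <- matrix(seq_len(dim[1]), dim[1], dim[2])
  cc <- matrix(seq_len(dim[2]), dim[1], dim[2], byrow = TRUE)
  base <- matrix(bg$offset, dim[1], dim[2])
  if (bg$type == "constant") {
    base <- base + bg$amplitude
  } else if (bg$type == "ramp") {
    base <- base + bg$ramp_range[1] +
      (bg$ramp_range[2] - bg$ramp_range[1]) * (cc - 1) / (dim[2] - 1)
    base <- ifelse(cell_mask, base, bg$offset)
  } else { # dome: projected-thickness bump over the cell footprint
    phi <- cell$phi_deg * pi / 180
    dy <- rr - cell$center[1]; dx <- cc - cell$center[2]
    u <- dy * cos(phi) + dx * sin(phi)
    v <- -dy * sin(phi) + dx * cos(phi)
    q <- 1 - (u / cell$semi_axes[1])^2 - (v / cell$semi_axes[2])^2
    base <- base + bg$amplitude * sqrt(pmax(q, 0))
  }
  if (bg$nucleus_depth > 0 && bg$type != "constant") {
    dy <- rr - cell$center[1]; dx <- cc - cell$center[2]
    dip <- bg$nucleus_depth * exp(-(dy^2 + dx^2) /
                                    (2 * bg$nucleus_radius_px^2))
    base <- base - ifelse(cell_mask, dip, 0)
  }
  pmax(base, 0)
}

#' Render a synthetic fluorescence image with ground truth
#'
#' Composites background, fibers, bright-dot artifacts and noise, and
#' returns the image together with the ground truth needed to score every
#' downstream stage: the true fiber mask (pixels within one cross-section
#' sigma of a centerline), the true local fiber orientation, the painted
#' fiber intensity layer and its sums.
#'
#' @param spec a [synthetic_image_spec()].
#' @return object of class `synthetic_fiber_image`: list with `image`
#'   (matrix, AU), `pixel_size_um`, `cell_mask` (logical ground truth
#'   ellipse), and `truth` containing `mask`, `lof_deg` (NA off-mask),
#'   `fiber_layer`, `f_sum` (fiber-layer intensity summed over the truth
#'   mask), `f_sum_total` (whole layer), `background`, `dot_mask`.
#' @export
render_fiber_image <- function(spec) {
  validate_image_spec(spec)
  set.seed(spec$seed)
  dim <- spec$dim
  cell_mask <- .ellipse_mask(dim, spec$cell)
  fiber_layer <- matrix(0, dim[1], dim[2])
  best <- matrix(0, dim[1], dim[2])
  lof <- matrix(NA_real_, dim[1], dim[2])
  member <- matrix(FALSE, dim[1], dim[2])
  f <- spec$fibers
  if (!is.null(f) && nrow(f) > 0) {
    for (i in seq_len(nrow(f))) {
      li <- .render_segment_layer(dim, f[i, ])
      fiber_layer <- fiber_layer + li
      upd <- li > best
      lof[upd] <- f$theta_deg[i]
      best[upd] <- li[upd]
      member <- member | (li >= f$peak[i] * exp(-0.5))
    }
  }
  lof[!member] <- NA_real_
  dot_layer <- matrix(0, dim[1], dim[2])
  dot_mask <- matrix(FALSE, dim[1], dim[2])
  d <- spec$dots
  if (!is.null(d) && nrow(d) > 0) {
    for (i in seq_len(nrow(d))) {
      di <- .render_segment_layer(
        dim, data.frame(r0 = d$r[i], c0 = d$c[i], theta_deg = 0,
                        length_px = 0, width_px = d$sigma_px[i],
                        peak = d$peak[i]))
      dot_layer <- dot_layer + di
      dot_mask <- dot_mask | (di >= d$peak[i] * exp(-0.5))
    }
    # dot pixels that also lie on a fiber are legitimately fiber pixels
    dot_mask <- dot_mask & !member
  }
  background <- .render_background(spec, cell_mask)
  img <- background + fiber_layer + dot_layer
  if (spec$noise_sd > 0)
    img <- img + matrix(rnorm(prod(dim), 0, spec$noise_sd), dim[1], dim[2])
  img <- pmax(img, 0)
  structure(list(image = img,
                 pixel_size_um = spec$pixel_size_um,
                 cell_mask = cell_mask,
                 truth = list(mask = member, lof_deg = lof,
                              fiber_layer = fiber_layer,
                              f_sum = sum(fiber_layer[member]),
                              f_sum_total = sum(fiber_layer),
                              background = background,
                              dot_mask = dot_mask),
                 spec = spec),
            class = "synthetic_fiber_image")
}
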