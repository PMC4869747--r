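#' AFM force curve container
#'
#' One force-displacement ramp: piezo position `Z` versus cantilever
#' deflection `d`, both in nm, with the probe calibration needed to turn
#' deflection into force (`F = k d`) and the glass-contact reference used
#' to compute the local sample height (`h = Z_CP - Z_glass`).
#'
#' @param Z_nm piezo displacement samples (nm), strictly monotone.
#' @param d_nm deflection samples (nm), same length.
#' @param k_n_m cantilever spring constant (N/m), > 0.
#' @param theta_deg tip half-opening angle (degrees), in (0, 90).
#' @param z_glass_nm piezo position of the contact point on bare glass.
#' @param id curve identifier.
#' @return object of class `force_curve`.
#' @export
force_curve <- function(Z_nm, d_nm, k_n_m, theta_deg, z_glass_nm,
                        id = "curve") {
  if (length(Z_nm) != length(d_nm)) stop("Z and d differ in length")
  dz <- diff(Z_nm)
  if (!(all(dz > 0) || all(dz < 0))) stop("Z must be strictly monotone")
  if (k_n_m <= 0) stop("spring constant must be > 0")
  if (theta_deg <= 0 || theta_deg >= 90)
    stop("tip half-angle must be in (0, 90) degrees")
  if (any(dz < 0)) { Z_nm <- rev(Z_nm); d_nm <- rev(d_nm) }
  structure(list(Z_nm = Z_nm, d_nm = d_nm, k_n_m = k_n_m,
                 theta_deg = theta_deg, z_glass_nm = z_glass_nm, id = id),
            class = "force_curve")
}

# remove baseline offset/tilt: straight line fitted to the earliest
# fraction of the ramp (assumed pre-contact) and subtracted throughout
.baseline_correct <- function(curve, baseline_frac = 0.25) {
  n <- length(curve$Z_nm)
  nb <- max(5L, floor(baseline_frac * n))
  fit <- lm(d ~ Z, data = data.frame(Z = curve$Z_nm[seq_len(nb)],
                                     d = curve$d_nm[seq_len(nb)]))
  curve$d_nm <- curve$d_nm -
    predict(fit, newdata = data.frame(Z = curve$Z_nm))
  curve
}

# least-squares modulus at a fixed candidate contact point; F is linear in
# E, so the fit is closed-form: E = sum(F g) / sum(g^2) with g the unit-E
# BECC force at the observed indentations
.fit_at_cp <- function(Z, d, k, theta_deg, z_cp, z_glass, min_contact) {
  h_nm <- z_cp - z_glass
  if (h_nm <= 0) return(NULL)
  post <- Z > z_cp
  if (!any(post)) return(NULL)
  delta <- (Z[post] - z_cp) - d[post]
  keep <- delta > 0
  if (sum(keep) < min_contact) return(NULL)
  delta_um <- delta[keep] * 1e-3
  F_nN <- k * d[post][keep]
  g <- becc_force(1, theta_deg, delta_um, h_nm * 1e-3)
  E <- sum(F_nN * g) / sum(g^2)
  E <- max(E, 0)
  ss_tot <- sum((F_nN - mean(F_nN))^2)
  if (ss_tot <= 0) return(NULL)
  r2 <- 1 - sum((F_nN - E * g)^2) / ss_tot
  list(z_cp = z_cp, E_pa = E, r2 = r2, h_um = h_nm * 1e-3,
       n_contact = sum(keep))
}

#' Locate the contact point of a force curve and fit its modulus
#'
#' Sequential search for the contact point: every sample position that
#' leaves at least a minimum fraction of the ramp in contact is tried as a
#' candidate `Z_CP`; for each candidate the Young's modulus is fitted by
#' least squares through the BECC model (with the local height taken as
#' `Z_CP - Z_glass`) and the candidate maximizing the goodness of fit
#' r-squared is returned.  Ties are broken toward the larger (shallower)
#' `Z_CP`.  The curve baseline is corrected first (line fitted to the
#' earliest quarter of the ramp).
#'
#' @param curve a [force_curve()].
#' @param min_contact_frac minimum fraction of samples that must remain
#'   beyond a candidate contact point.
#' @param min_contact minimum number of positive-indentation samples.
#' @param baseline_frac fraction of early samples used for the baseline.
#' @param r2_accept acceptance gate on the fit r-squared (fits at or below
#'   it are flagged `accepted = FALSE`).
#' @param refine continuously refine the contact point between the
#'   neighbouring samples of the best grid candidate (default TRUE); set
#'   to FALSE to restrict the search to the sample grid.
#' @return object of class `indentation_fit`: list with `z_cp_nm`, `E_pa`,
#'   `r2`, `h_um`, `accepted`, `n_contact`, `id`.
#' @export
find_contact_point <- function(curve, min_contact_frac = 0.10,
                               min_contact = 10L, baseline_frac = 0.25,
                               r2_accept = 0.75, refine = TRUE) {
  stopifnot(inherits(curve, "force_curve"))
  n <- length(curve$Z_nm)
  if (n < 50) stop("curve has fewer than 50 samples")
  curve <- .baseline_correct(curve, baseline_frac)
  need <- max(min_contact, ceiling(min_contact_frac * n))
  best <- NULL; best_i <- NA_integer_
  for (i in seq_len(n - need)) {
    cand <- .fit_at_cp(curve$Z_nm, curve$d_nm, curve$k_n_m,
                       curve$theta_deg, curve$Z_nm[i], curve$z_glass_nm,
                       min_contact)
    if (is.null(cand)) next
    if (is.null(best) || cand$r2 >= best$r2) { best <- cand; best_i <- i }
  }
  if (is.null(best)) stop("no contact found")
  if (refine) {
    lo <- curve$Z_nm[max(best_i - 1L, 1L)]
    hi <- curve$Z_nm[min(best_i + 1L, n)]
    r2_of <- function(z) {
      f <- .fit_at_cp(curve$Z_nm, curve$d_nm, curve$k_n_m,
                      curve$theta_deg, z, curve$z_glass_nm, min_contact)
      if (is.null(f)) -Inf else f$r2
    }
    opt <- stats::optimize(r2_of, c(lo, hi), maximum = TRUE,
                           tol = 1e-3 * (hi - lo))
    if (is.finite(opt$objective) && opt$objective >= best$r2)
      best <- .fit_at_cp(curve$Z_nm, curve$d_nm, curve$k_n_m,
                         curve$theta_deg, opt$maximum, curve$z_glass_nm,
                         min_contact)
  }
  structure(list(z_cp_nm = best$z_cp, E_pa = best$E_pa, r2 = best$r2,
                 h_um = best$h_um, accepted = best$r2 > r2_accept,
                 n_contact = best$n_contact, id = curve$id),
            class = "indentation_fit")
}

#' Fit the Young's modulus at a known contact point
#'
#' Least-squares BECC fit of the post-contact force at a fixed contact
#' point, after baseline correction.  The modulus enters the model
#' linearly, so the estimate is closed-form and constrained to be >= 0.
#'
#' @inheritParams find_contact_point
#' @param z_cp_nm contact-point piezo position (nm).
#' @return list with `E_pa` and `r2`.
#' @export
fit_modulus <- function(curve, z_cp_nm, min_contact = 10L,
                        baseline_frac = 0.25) {
  stopifnot(inherits(curve, "force_curve"))
  curve <- .baseline_correct(curve, baseline_frac)
  fit <- .fit_at_cp(curve$Z_nm, curve$d_nm, curve$k_n_m, curve$theta_deg,
                    z_cp_nm, curve$z_glass_nm, min_contact)
  if (is.null(fit)) stop("no positive indentations beyond the contact point")
  list(E_pa = fit$E_pa, r2 = fit$r2)
}

#' Fit a batch of force curves
#'
#' @param curves list of [force_curve()] objects.
#' @param ... passed to [find_contact_point()].
#' @return data frame with one row per curve (`id`, `z_cp_nm`, `E_pa`,
#'   `r2`, `h_um`, `accepted`, `error`); curves that fail to fit get an
#'   `NA` row with the error message recorded.
#' @export
fit_curve_batch <- function(curves, ...) {
  rows <- lapply(curves, function(cu) {
    res <- tryCatch(find_contact_point(cu, ...), error = identity)
    if (inherits(res, "error")) {
      data.frame(id = if (inherits(cu, "force_curve")) cu$id else NA,
                 z_cp_nm = NA_real_, E_pa = NA_real_, r2 = NA_real_,
                 h_um = NA_real_, accepted = FALSE,
                 error = conditionMessage(res), stringsAsFactors = FALSE)
    } else {
      data.frame(id = res$id, z_cp_nm = res$z_cp_nm, E_pa = res$E_pa,
                 r2 = res$r2, h_um = res$h_um, accepted = res$accepted,
                 error = NA_character_, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Pool per-location fits into per-cell stiffness values
#'
#' Accepted fits (r-squared above the gate) are classified by local sample
#' height: locations lower than `csk_max_um` are pooled as 'cytoskeleton',
#' locations higher than `nr_min_um` as 'nuclear region'; heights in
#' between belong to neither pool.  Each pool is summarized by its median
#' modulus; an empty pool yields `NA`.
#'
#' @param fits data frame with columns `E_pa`, `h_um`, `accepted` (as from
#'   [fit_curve_batch()]), or a list of `indentation_fit` objects.
#' @param csk_max_um,nr_min_um height thresholds (micrometres).
#' @return list with `E_csk_pa`, `E_nr_pa`, and the pooled counts
#'   `n_csk`, `n_nr`.
#' @export
pool_cell_fits <- function(fits, csk_max_um = 4, nr_min_um = 5) {
  if (!is.data.frame(fits))
    fits <- do.call(rbind, lapply(fits, function(f)
      data.frame(E_pa = f$E_pa, h_um = f$h_um, accepted = f$accepted)))
  ok <- fits$accepted & !is.na(fits$E_pa)
  csk <- ok & fits$h_um < csk_max_um
  nr <- ok & fits$h_um > nr_min_um
  list(E_csk_pa = if (any(csk)) median(fits$E_pa[csk]) else NA_real_,
       E_nr_pa = if (any(nr)) median(fits$E_pa[nr]) else NA_real_,
       n_csk = sum(csk), n_nr = sum(nr))
}
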