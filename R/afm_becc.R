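#' Bottom-effect cone correction (BECC) force model
#'
#' Force exerted by a conical tip indenting an elastic layer of finite
#' thickness bonded to a rigid substrate, for an incompressible sample
#' (Poisson's ratio 0.5, baked into the constants):
#' \deqn{F = \frac{8 E \tan\theta\, \delta^2}{3\pi}\left\{1 +
#'   1.7795\,\frac{2\tan\theta}{\pi^2}\,\frac{\delta}{h} +
#'   16\,(1.7795)^2 \tan^2\theta\, \frac{\delta^2}{h^2}\right\}}
#' The braces reduce to 1 as \eqn{h \to \infty}, recovering the classical
#' conical (Sneddon-type) contact force.
#'
#' @param E_pa Young's modulus (Pa).
#' @param theta_deg half-opening angle of the cone (degrees).
#' @param delta_um indentation (micrometres); vectorized, must be >= 0.
#' @param h_um local sample height (micrometres); `Inf` drops the
#'   correction.
#' @return force in nanonewtons (nN).
#' @export
becc_force <- function(E_pa, theta_deg, delta_um, h_um) {
  if (any(h_um <= 0)) stop("sample height h must be > 0")
  if (any(delta_um < 0)) stop("indentation must be >= 0")
  tn <- tan(theta_deg * pi / 180)
  dm <- delta_um * 1e-6
  ratio <- delta_um / h_um   # 0 when h is Inf
  corr <- 1 + 1.7795 * (2 * tn / pi^2) * ratio +
    16 * 1.7795^2 * tn^2 * ratio^2
  (8 * E_pa * tn * dm^2 / (3 * pi)) * corr * 1e9
}

#' Specification of a synthetic AFM force-displacement ramp
#'
#' Parameters of one simulated approach ramp: a conical tip driven at the
#' sample by a piezo, with the cantilever deflection obtained by solving
#' the force balance `k d = F_BECC(delta)` with `delta = (Z - Z_CP) - d` at
#' every post-contact piezo position.  Before contact the deflection is
#' noise only (plus any programmed baseline offset/tilt).
#'
#' @param E_pa true Young's modulus (Pa).
#' @param h_um sample height at the probed location (micrometres); the
#'   glass reference is placed at `z_cp_nm - 1000 * h_um` so that
#'   `h = Z_CP - Z_glass` holds.
#' @param theta_deg tip half-opening angle (degrees).
#' @param k_n_m cantilever spring constant (N/m).
#' @param z_cp_nm contact-point piezo position (nm).
#' @param ramp_nm,n_samples ramp length and number of samples (default a
#'   5-micrometre ramp sampled at 300 points).
#' @param noise_sd_nm additive Gaussian deflection noise (nm).
#' @param baseline_offset_nm,baseline_tilt baseline deflection offset (nm)
#'   and tilt (nm per nm of Z) added to the whole curve.
#' @param seed integer seed.
#' @return object of class `synthetic_curve_spec`.
#' @export
synthetic_curve_spec <- function(E_pa = 1000, h_um = 4, theta_deg = 20,
                                 k_n_m = 0.1, z_cp_nm = 2500,
                                 ramp_nm = 5000, n_samples = 300L,
                                 noise_sd_nm = 0,
                                 baseline_offset_nm = 0,
                                 baseline_tilt = 0, seed = 1L) {
  spec <- structure(list(E_pa = E_pa, h_um = h_um, theta_deg = theta_deg,
                         k_n_m = k_n_m, z_cp_nm = z_cp_nm,
                         ramp_nm = ramp_nm, n_samples = as.integer(n_samples),
                         noise_sd_nm = noise_sd_nm,
                         baseline_offset_nm = baseline_offset_nm,
                         baseline_tilt = baseline_tilt,
                         seed = as.integer(seed)),
                    class = "synthetic_curve_spec")
  if (spec$E_pa <= 0) stop("E must be > 0")
  if (spec$h_um <= 0) stop("h must be > 0")
  if (spec$noise_sd_nm < 0) stop("noise sigma must be >= 0")
  if (spec$z_cp_nm >= spec$ramp_nm)
    stop("ramp has no post-contact samples")
  if (spec$z_cp_nm <= 0)
    stop("ramp has no pre-contact (baseline) samples")
  spec
}

# solve k d = F((Z - Zcp) - d) for d (nm) by bisection; monotone in d
.solve_deflection <- function(dz_nm, E_pa, theta_deg, k_n_m, h_um,
                              tol = 1e-10) {
  # with d in nm and k in N/m, k*d is directly in nN
  f <- function(d) k_n_m * d -
    becc_force(E_pa, theta_deg, (dz_nm - d) * 1e-3, h_um)
  lo <- 0; hi <- dz_nm
  if (f(hi) < 0) return(hi)     # cannot happen physically (F(0) = 0)
  for (i in 1:100) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
    if ((hi - lo) < tol) break
  }
  (lo + hi) / 2
}

#' Render a synthetic AFM force curve
#'
#' Forward-simulates the ramp described by a [synthetic_curve_spec()]
#' through the BECC contact model and returns it as a [force_curve()].
#'
#' @param spec a [synthetic_curve_spec()].
#' @return a `force_curve` whose attributes carry the ground truth
#'   (`truth` field: `E_pa`, `z_cp_nm`, `h_um`).
#' @export
render_force_curve <- function(spec) {
  stopifnot(inherits(spec, "synthetic_curve_spec"))
  set.seed(spec$seed)
  Z <- seq(0, spec$ramp_nm, length.out = spec$n_samples)
  d <- numeric(spec$n_samples)
  post <- Z > spec$z_cp_nm
  d[post] <- vapply(Z[post] - spec$z_cp_nm, .solve_deflection, numeric(1),
                    E_pa = spec$E_pa, theta_deg = spec$theta_deg,
                    k_n_m = spec$k_n_m, h_um = spec$h_um)
  d <- d + spec$baseline_offset_nm + spec$baseline_tilt * Z
  if (spec$noise_sd_nm > 0)
    d <- d + rnorm(spec$n_samples, 0, spec$noise_sd_nm)
  fc <- force_curve(Z_nm = Z, d_nm = d, k_n_m = spec$k_n_m,
                    theta_deg = spec$theta_deg,
                    z_glass_nm = spec$z_cp_nm - 1000 * spec$h_um,
                    id = sprintf("synthetic_seed%d", spec$seed))
  fc$truth <- list(E_pa = spec$E_pa, z_cp_nm = spec$z_cp_nm,
                   h_um = spec$h_um)
  fc
}
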