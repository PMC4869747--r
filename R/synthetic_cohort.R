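#' Published-style cohort parameters
#'
#' Convenience presets describing the stiffness-versus-amount cohorts:
#' intercept and slope of the linear model (kPa), the median filamentous
#' fraction, the span of fractions (decades), the binned-fit r-squared
#' and bin size used to calibrate the per-cell noise, and the typical
#' architecture-descriptor distributions.
#'
#' @param protein `"actin"`, `"myosin"` or `"tubulin"`.
#' @param region `"csk"` (cytoskeleton) or `"nr"` (nuclear region).
#' @return list of parameters accepted by [synthesize_cohort()].
#' @export
cohort_preset <- function(protein = c("actin", "myosin", "tubulin"),
                          region = c("csk", "nr")) {
  protein <- match.arg(protein); region <- match.arg(region)
  tab <- list(
    actin_csk   = list(e0_kpa = 0.37, alpha_kpa = 9.48,  r2_binned = 0.92),
    actin_nr    = list(e0_kpa = 1.14, alpha_kpa = 6.52,  r2_binned = 0.83),
    myosin_csk  = list(e0_kpa = 0.50, alpha_kpa = 14.67, r2_binned = 0.87),
    myosin_nr   = list(e0_kpa = 0.81, alpha_kpa = 8.74,  r2_binned = 0.72),
    tubulin_csk = list(e0_kpa = 0.93, alpha_kpa = 3.97,  r2_binned = 0.10),
    tubulin_nr  = list(e0_kpa = 1.98, alpha_kpa = -6.03, r2_binned = 0.10))
  p <- tab[[paste(protein, region, sep = "_")]]
  p$bin_size <- if (region == "csk") 10L else 4L
  p$f_median <- switch(protein, actin = 0.059, myosin = 0.034,
                       tubulin = 0.050)
  p$f_decades <- if (protein == "tubulin") 0.5 else 1.5
  arch <- switch(protein,
                 actin = list(fa_mean = 0.22, fa_sd = 0.10, ft_mean = 113,
                              ft_decades = 1, rl_mean = 0.70, rl_sd = 0.12),
                 myosin = list(fa_mean = 0.19, fa_sd = 0.10, ft_mean = 60,
                               ft_decades = 1, rl_mean = 0.73,
                               rl_sd = 0.12),
                 tubulin = list(fa_mean = 0.30, fa_sd = 0.10, ft_mean = 80,
                                ft_decades = 0.7, rl_mean = 0.60,
                                rl_sd = 0.12))
  c(p, list(arch = arch, protein = protein, region = region))
}

#' Synthesize a per-cell cohort for the stiffness models
#'
#' Generates cells with log-uniform filamentous fractions, architecture
#' descriptors (FA, FT, RL), and Young's moduli following the linear
#' stiffness model, optionally modulated multiplicatively by the
#' normalized architecture terms.  The per-cell noise is either given
#' directly (`sigma_e_kpa`) or calibrated so that a fit on `bin_size`-cell
#' bins attains the target binned r-squared.
#'
#' @param n number of cells.
#' @param e0_kpa,alpha_kpa linear model intercept and slope (kPa).
#' @param f_median,f_decades median and log10 span of the filamentous
#'   fraction distribution.
#' @param sigma_e_kpa additive per-cell noise sigma (kPa); if `NULL`,
#'   derived from `r2_binned` and `bin_size`.
#' @param r2_binned,bin_size calibration target for the noise.
#' @param modulation `NULL` for a purely amount-driven cohort, or a list
#'   with coefficients `a`, `b`, `c`, `d` and either `sigma_ratio` (sd of
#'   the multiplicative residual) or `r2_target` (sigma is then chosen so
#'   the modulation terms explain that fraction of the `E/E_fit`
#'   variance).
#' @param arch list describing the architecture distributions (see
#'   [cohort_preset()]).
#' @param seed integer seed.
#' @return data frame with `fraction`, `E_kpa`, `fa`, `ft`, `rl`.
#' @export
synthesize_cohort <- function(n, e0_kpa, alpha_kpa, f_median = 0.059,
                              f_decades = 1.5, sigma_e_kpa = NULL,
                              r2_binned = 0.9, bin_size = 10L,
                              modulation = NULL,
                              arch = cohort_preset("actin")$arch,
                              seed = 1L, ...) {
  set.seed(seed)
  f <- f_median * 10^runif(n, -f_decades / 2, f_decades / 2)
  fa <- pmin(pmax(rnorm(n, arch$fa_mean, arch$fa_sd), 0.02), 0.50)
  ft <- arch$ft_mean * 10^runif(n, -arch$ft_decades / 2,
                                arch$ft_decades / 2)
  rl <- pmin(pmax(rnorm(n, arch$rl_mean, arch$rl_sd), 0.30), 0.98)
  e_amount <- e0_kpa + alpha_kpa * f
  if (is.null(modulation)) {
    if (is.null(sigma_e_kpa))
      sigma_e_kpa <- sqrt(bin_size * alpha_kpa^2 * var(f) *
                            (1 / r2_binned - 1))
    e <- e_amount + rnorm(n, 0, sigma_e_kpa)
  } else {
    m <- modifyList(list(a = 1, b = 0, c = 0, d = 0, sigma_ratio = NULL,
                         r2_target = NULL), modulation)
    det <- m$a + m$b * fa / mean(fa) + m$c * ft / mean(ft) +
      m$d * rl / mean(rl)
    sr <- m$sigma_ratio
    if (is.null(sr)) {
      if (is.null(m$r2_target)) stop("need sigma_ratio or r2_target")
      sr <- sqrt(var(det) * (1 / m$r2_target - 1))
    }
    e <- e_amount * (det + rnorm(n, 0, sr))
  }
  data.frame(fraction = f, E_kpa = e, fa = fa, ft = ft, rl = rl)
}
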