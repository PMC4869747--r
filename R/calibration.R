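#' Total filamentous protein from GFP measurements
#'
#' Scales the GFP-based filamentous amount to the total (endogenous plus
#' exogenous) filamentous amount under the equal-binding-probability
#' assumption: `F_total = F_GFP * (1 + P_endo / P_GFP)`.
#'
#' @param f_gfp filamentous GFP intensity (AU).
#' @param p_gfp total exogenous GFP intensity of the cell (AU), > 0.
#' @param p_endo endogenous-pool scaling factor (AU), >= 0.
#' @return F_total (AU); vectorized.
#' @export
f_total <- function(f_gfp, p_gfp, p_endo) {
  if (any(p_gfp <= 0)) stop("P_GFP must be > 0 (untransfected cell?)")
  if (any(p_endo < 0)) stop("P_endo must be >= 0")
  f_gfp * (1 + p_endo / p_gfp)
}

#' Fraction of protein in filamentous form
#'
#' `F_total / P_total` with `P_total = P_endo + P_GFP`.  Under the equal
#' binding probability assumption this equals `F_GFP / P_GFP` and is
#' independent of the (batch-level) scaling factor.
#'
#' @param f_tot total filamentous amount (AU), from [f_total()].
#' @param p_gfp exogenous GFP amount (AU).
#' @param p_endo endogenous scaling factor (AU).
#' @return fraction in `[0, 1]` for physically consistent inputs; values
#'   above 1 are returned with a warning (quantification failure).
#' @export
filamentous_fraction <- function(f_tot, p_gfp, p_endo) {
  if (any(p_endo + p_gfp <= 0)) stop("P_endo + P_GFP must be > 0")
  fr <- f_tot / (p_endo + p_gfp)
  if (any(fr > 1))
    warning("filamentous fraction > 1: quantification failure flagged")
  fr
}

#' Estimate the endogenous-pool scaling factor P_endo
#'
#' Cells transfected with the GFP construct and then stained with a dye
#' that reports total filamentous protein give paired measurements
#' (F_GFP, P_GFP, F_dye).  The dye intensity is proportional to the true
#' F_total, so the correct P_endo makes the ordinary least-squares fit of
#' F_dye against `F_total(P_endo)` pass through the origin.  The intercept
#' is monotone in P_endo, and its root is located by bisection.
#'
#' @param cells data frame with columns `f_gfp`, `p_gfp`, `f_dye` (all
#'   non-negative; at least 3 cells spanning a range of `p_gfp`).
#' @param p_endo_max upper end of the search interval; default
#'   `100 * median(p_gfp)`.
#' @param tol relative tolerance of the bisection.
#' @return object of class `calibration_model`: list with `p_endo`,
#'   `n_cells`, `intercept`, `slope`, `r2`.
#' @export
estimate_p_endo <- function(cells, p_endo_max = NULL, tol = 1e-6) {
  stopifnot(all(c("f_gfp", "p_gfp", "f_dye") %in% names(cells)))
  if (nrow(cells) < 3) stop("need at least 3 calibration cells")
  if (any(cells$p_gfp <= 0)) stop("P_GFP must be > 0 for all cells")
  med <- median(cells$p_gfp)
  if (is.null(p_endo_max)) p_endo_max <- 100 * med
  intercept_at <- function(p) {
    ft <- f_total(cells$f_gfp, cells$p_gfp, p)
    unname(coef(lm(cells$f_dye ~ ft))[1])
  }
  # the intercept is monotone near the root but turns back toward zero
  # for very large P_endo (the fit degenerates), so bracket the first
  # sign change on a log-spaced grid before root-finding
  grid <- c(0, exp(seq(log(med / 1e3), log(p_endo_max),
                       length.out = 120)))
  ints <- vapply(grid, intercept_at, numeric(1))
  scale <- max(abs(cells$f_dye), 1e-12)
  if (abs(ints[1]) < 1e-9 * scale) {
    root <- 0
  } else {
    flip <- which(sign(ints[-1]) != sign(ints[1]))[1]
    if (is.na(flip))
      stop("no P_endo in [0, ", format(p_endo_max),
           "] zeroes the fit intercept (range ",
           format(min(ints)), " to ", format(max(ints)), ")")
    root <- uniroot(intercept_at, grid[c(flip, flip + 1)],
                    tol = tol * p_endo_max)$root
  }
  ft <- f_total(cells$f_gfp, cells$p_gfp, root)
  fit <- lm(cells$f_dye ~ ft)
  structure(list(p_endo = root, n_cells = nrow(cells),
                 intercept = unname(coef(fit)[1]),
                 slope = unname(coef(fit)[2]),
                 r2 = suppressWarnings(summary(fit)$r.squared)),
            class = "calibration_model")
}

#' Write / read a calibration model as YAML
#'
#' @param model a `calibration_model`.
#' @param path file path.
#' @return `read_calibration()` returns the restored model.
#' @export
write_calibration <- function(model, path) {
  yaml::write_yaml(unclass(model), path)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  structure(yaml::read_yaml(path), class = "calibration_model")
}
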