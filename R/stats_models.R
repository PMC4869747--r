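#' Bin cells by filamentous fraction
#'
#' Sorts the per-cell records by filamentous fraction and averages
#' consecutive groups of `bin_size` cells, reproducing the pooling used
#' for the stiffness-versus-amount plots (10-cell bins for cytoskeleton,
#' 4-cell bins for nuclear-region data).
#'
#' @param records data frame with columns `fraction` and `E_kpa`.
#' @param bin_size cells per bin.
#' @param drop_incomplete drop a final short bin (default TRUE).
#' @return data frame with per-bin mean `fraction`, mean `E_kpa` and `n`.
#' @export
bin_cells <- function(records, bin_size = 10L, drop_incomplete = TRUE) {
  stopifnot(all(c("fraction", "E_kpa") %in% names(records)))
  records <- records[!is.na(records$E_kpa) & !is.na(records$fraction), ]
  if (nrow(records) < bin_size) stop("fewer records than one bin")
  ord <- order(records$fraction)
  records <- records[ord, ]
  grp <- (seq_len(nrow(records)) - 1L) %/% bin_size
  agg <- do.call(rbind, lapply(split(records, grp), function(b)
    data.frame(fraction = mean(b$fraction), E_kpa = mean(b$E_kpa),
               n = nrow(b))))
  rownames(agg) <- NULL
  if (drop_incomplete) agg <- agg[agg$n == bin_size, , drop = FALSE]
  agg
}

#' Linear stiffness-versus-amount fit
#'
#' Ordinary least squares of Young's modulus on the filamentous fraction,
#' `E = E0 + alpha [F]`, with standard errors, the p-value of the model
#' against a constant model, and r-squared.
#'
#' @param points data frame with `fraction` and `E_kpa` (cells or bins).
#' @return object of class `stiffness_fit`: list with `e0_kpa`,
#'   `alpha_kpa`, `se_e0`, `se_alpha`, `p_vs_constant`, `p_alpha`, `r2`,
#'   `n`, and the underlying `lm` fit.
#' @export
fit_stiffness_model <- function(points) {
  stopifnot(all(c("fraction", "E_kpa") %in% names(points)))
  points <- points[!is.na(points$E_kpa) & !is.na(points$fraction), ]
  if (nrow(points) < 3) stop("need at least 3 points")
  if (sd(points$fraction) == 0) stop("degenerate fractions: all equal")
  fit <- lm(E_kpa ~ fraction, data = points)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  structure(list(e0_kpa = unname(coef(fit)[1]),
                 alpha_kpa = unname(coef(fit)[2]),
                 se_e0 = sm$coefficients[1, 2],
                 se_alpha = sm$coefficients[2, 2],
                 p_alpha = sm$coefficients[2, 4],
                 p_vs_constant = unname(pf(fstat[1], fstat[2], fstat[3],
                                           lower.tail = FALSE)),
                 r2 = sm$r.squared, n = nrow(points), lm = fit),
            class = "stiffness_fit")
}

#' Compare two stiffness fits by analysis of covariance
#'
#' Joint regression of both cohorts with a group factor: the slope
#' difference is tested by the F-test of the interaction term, the
#' intercept difference by the F-test of the group offset under a common
#' slope.  A Scheffe adjustment for simultaneous comparisons among
#' `n_groups` fitted cohorts is applied by referring the contrast
#' statistic `F / (n_groups - 1)` to an F distribution with
#' `n_groups - 1` numerator degrees of freedom; with `n_groups = 2` this
#' reduces to the unadjusted test.
#'
#' @param data_a,data_b data frames with `fraction` and `E_kpa`.
#' @param n_groups number of cohorts in the simultaneous comparison
#'   family.
#' @return list with `p_slope`, `p_intercept`, and the fitted models.
#' @export
compare_fits_ancova <- function(data_a, data_b, n_groups = 2L) {
  df <- rbind(data.frame(fraction = data_a$fraction, E_kpa = data_a$E_kpa,
                         g = "A"),
              data.frame(fraction = data_b$fraction, E_kpa = data_b$E_kpa,
                         g = "B"))
  df$g <- factor(df$g)
  full <- lm(E_kpa ~ fraction * g, data = df)
  no_int <- lm(E_kpa ~ fraction + g, data = df)
  common <- lm(E_kpa ~ fraction, data = df)
  scheffe_p <- function(small, big) {
    a <- anova(small, big)
    fstat <- a$F[2]; df2 <- a$Res.Df[2]
    if (!is.finite(fstat)) fstat <- 0  # identical models
    k <- n_groups - 1
    pf(max(fstat, 0) / k, k, df2, lower.tail = FALSE)
  }
  list(p_slope = scheffe_p(no_int, full),
       p_intercept = scheffe_p(common, no_int),
       fit_full = full)
}

#' Architecture modulation of stiffness
#'
#' Models the over/under-estimation of the measured modulus relative to
#' the amount-based prediction, `E / E_fit` with
#' `E_fit = E0 + alpha [F]`, as a linear function of the normalized
#' architecture descriptors:
#' \deqn{E/E_{fit} = a + b\,FA/\langle FA\rangle + c\,FT/\langle FT\rangle
#'   + d\,RL/\langle RL\rangle}
#' Terms are selected by exhaustively comparing all subsets of
#' `{FA, FT, RL}` with nested F-tests at the 0.05 level: a subset is
#' admissible when it improves significantly on every one of its proper
#' subsets, and the largest admissible subset (smallest residual sum of
#' squares on ties) is chosen.
#'
#' @param records data frame with `fraction`, `E_kpa`, `fa`, `ft`, `rl`.
#' @param fit a [fit_stiffness_model()] result providing `E_fit`.
#' @param term_set optional character subset of `c("fa", "ft", "rl")` to
#'   fit directly, skipping selection.
#' @param alpha_level significance level of the nested F-tests.
#' @return object of class `modulation_fit`: list with `terms`,
#'   `coefficients` (a and the included b/c/d, with SEs), `normalizers`
#'   (`fa_mean`, `ft_mean`, `rl_mean`), `r2`, `p_vs_constant`,
#'   `selection` (per-subset table), `n`, `lm`.
#' @export
fit_modulation_model <- function(records, fit, term_set = NULL,
                                 alpha_level = 0.05) {
  stopifnot(inherits(fit, "stiffness_fit"))
  need <- c("fraction", "E_kpa", "fa", "ft", "rl")
  stopifnot(all(need %in% names(records)))
  records <- records[stats::complete.cases(records[, need]), ]
  e_fit <- fit$e0_kpa + fit$alpha_kpa * records$fraction
  bad <- e_fit <= 0
  if (any(bad)) {
    warning(sum(bad), " cell(s) with non-positive predicted E excluded")
    records <- records[!bad, ]; e_fit <- e_fit[!bad]
  }
  norm <- c(fa_mean = mean(records$fa), ft_mean = mean(records$ft),
            rl_mean = mean(records$rl))
  df <- data.frame(y = records$E_kpa / e_fit,
                   fa = records$fa / norm["fa_mean"],
                   ft = records$ft / norm["ft_mean"],
                   rl = records$rl / norm["rl_mean"])
  all_terms <- c("fa", "ft", "rl")
  subsets <- lapply(0:7, function(b) all_terms[bitwAnd(b, c(1, 2, 4)) > 0])
  fit_subset <- function(s) {
    fo <- if (length(s) == 0) y ~ 1 else
      stats::as.formula(paste("y ~", paste(s, collapse = " + ")))
    lm(fo, data = df)
  }
  fits <- lapply(subsets, fit_subset)
  rss <- vapply(fits, function(f) sum(stats::residuals(f)^2), numeric(1))
  if (is.null(term_set)) {
    admissible <- vapply(seq_along(subsets), function(i) {
      s <- subsets[[i]]
      if (length(s) == 0) return(TRUE)
      subs <- which(vapply(subsets, function(t)
        all(t %in% s) && length(t) < length(s), logical(1)))
      all(vapply(subs, function(j)
        anova(fits[[j]], fits[[i]])$`Pr(>F)`[2] < alpha_level, logical(1)))
    }, logical(1))
    sizes <- lengths(subsets)
    cand <- which(admissible)
    cand <- cand[sizes[cand] == max(sizes[cand])]
    pick <- cand[which.min(rss[cand])]
    term_set <- subsets[[pick]]
  } else {
    if (length(term_set) > 0 && !all(term_set %in% all_terms))
      stop("term_set must be a subset of {fa, ft, rl}")
    pick <- which(vapply(subsets, function(s) setequal(s, term_set),
                         logical(1)))
  }
  best <- fits[[pick]]
  sm <- summary(best)
  p_const <- if (length(term_set) == 0) NA_real_ else
    anova(fits[[1]], best)$`Pr(>F)`[2]
  structure(list(terms = term_set,
                 coefficients = sm$coefficients,
                 normalizers = norm, r2 = sm$r.squared,
                 p_vs_constant = p_const,
                 selection = data.frame(
                   subset = vapply(subsets, function(s)
                     if (length(s)) paste(s, collapse = "+") else "(const)",
                     character(1)),
                   rss = rss),
                 n = nrow(df), lm = best),
            class = "modulation_fit")
}

#' Quantities derived from the stiffness fits
#'
#' Two desk-scale consequences of the linear stiffness models: the
#' asymptotic myosin-to-actin ratio obtained by equating the actin and
#' myosin cytoskeletal models at high filamentous fractions (the slope of
#' `[M]` as a function of `[A]`, `alpha_actin / alpha_myosin`), and the
#' critical actin fraction at which the predicted nuclear-region and
#' cytoskeletal moduli coincide.
#'
#' @param actin_csk,myosin_csk,actin_nr numeric `c(E0, alpha)` pairs
#'   (kPa) for the respective fits; each may also be a `stiffness_fit`.
#' @return list with `m_vs_a_slope` and `critical_a_pct` (per cent); a
#'   critical point with equal slopes is flagged `NA` with a warning.
#' @export
derived_quantities <- function(actin_csk, myosin_csk, actin_nr) {
  pars <- function(x) {
    if (inherits(x, "stiffness_fit")) c(x$e0_kpa, x$alpha_kpa) else x
  }
  a <- pars(actin_csk); m <- pars(myosin_csk); nr <- pars(actin_nr)
  slope <- a[2] / m[2]
  if (a[2] == nr[2]) {
    warning("equal cytoskeletal and nuclear slopes: no critical point")
    crit <- NA_real_
  } else {
    crit <- 100 * (nr[1] - a[1]) / (a[2] - nr[2])
  }
  list(m_vs_a_slope = slope, critical_a_pct = crit)
}
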