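#' Quantify one fluorescence image
#'
#' Runs the full image pipeline: cell-mask estimation, eLoG segmentation,
#' CEDF refinement with orientation trimming, masked-median background
#' estimation, F-protein map construction, and the per-cell descriptors
#' (F_GFP, P_GFP, filamentous fraction, fiber alignment, apparent fiber
#' thickness, radial location, cell geometry).
#'
#' @param image numeric matrix (AU) or path to a TIFF readable by
#'   [read_intensity_tiff()].
#' @param pixel_size_um physical pixel size.
#' @param config a [pipeline_config()].
#' @param cell_mask optional logical matrix overriding the automatic cell
#'   mask.
#' @return list with `record` (one-row data frame of per-cell scalars)
#'   and `maps` (cell mask, refined segmentation, background, F-protein
#'   map).
#' @export
quantify_image <- function(image, pixel_size_um = 0.5,
                           config = pipeline_config(), cell_mask = NULL) {
  if (is.character(image)) image <- read_intensity_tiff(image)
  if (length(image) == 0 || all(!is.finite(image)))
    stop("empty or unreadable image")
  if (is.null(cell_mask))
    cell_mask <- estimate_cell_mask(image,
                                    config$cell_mask$blur_sigma,
                                    config$cell_mask$close_size)
  sg <- config$segmentation
  bank <- elog_bank(sg$n_kernels, sg$sigma_along, sg$sigma_across)
  thr_value <- sg$threshold_value
  if (!is.null(thr_value) && is.na(thr_value)) thr_value <- NULL
  seg <- segment_fibers(image, bank, cell_mask,
                        threshold = sg$threshold, value = thr_value)
  rcfg <- do.call(refinement_config, config$refinement)
  ref <- refine_segmentation(seg, rcfg)
  bg <- estimate_background(image, ref$mask, config$background$window,
                            config$background$grow_step,
                            config$background$min_px)
  fp <- f_protein_map(image, ref$mask, bg)
  p_gfp <- total_cell_intensity(image, cell_mask)
  p_endo <- config$calibration$p_endo
  fa <- fiber_alignment(ref$lof_deg)
  ft <- fiber_thickness(fp, p_gfp, p_endo)
  rl <- radial_location(fp$map, cell_mask)
  geo <- cell_geometry(cell_mask, pixel_size_um)
  frac <- filamentous_fraction(f_total(fp$f_gfp, p_gfp, p_endo),
                               p_gfp, p_endo)
  record <- data.frame(f_gfp = fp$f_gfp, p_gfp = p_gfp, fraction = frac,
                       fa = fa$fa, theta_bar_deg = fa$theta_bar_deg,
                       ft_gfp = ft$ft_gfp, ft = ft$ft, rl = rl$rl,
                       area_um2 = geo$area_um2,
                       aspect_ratio = geo$aspect_ratio,
                       major_axis_deg = geo$major_axis_deg,
                       n_fiber_px = sum(fp$mask))
  list(record = record,
       maps = list(cell_mask = cell_mask, segmentation = ref,
                   background = bg, fprotein = fp),
       radial_profile = rl$profile)
}

#' Correlate per-cell stiffness with fiber amount and architecture
#'
#' Bins the cohort by filamentous fraction, fits the linear stiffness
#' model on the binned points, and fits the architecture modulation model
#' on the unbinned cells using that linear fit as the amount-based
#' prediction.
#'
#' @param records data frame with at least `fraction` and `E_kpa`;
#'   columns `fa`, `ft`, `rl` enable the modulation model.
#' @param bin_size cells per bin for the linear fit.
#' @param modulation_terms optional fixed term subset passed to
#'   [fit_modulation_model()].
#' @return list with `binned`, `stiffness_fit`, and (when architecture
#'   columns are present) `modulation_fit`.
#' @export
correlate_cells <- function(records, bin_size = 10L,
                            modulation_terms = NULL) {
  need <- c("fraction", "E_kpa")
  if (!all(need %in% names(records)))
    stop("records must contain columns: ", paste(need, collapse = ", "))
  binned <- bin_cells(records, bin_size)
  sfit <- fit_stiffness_model(binned)
  out <- list(binned = binned, stiffness_fit = sfit)
  if (all(c("fa", "ft", "rl") %in% names(records)))
    out$modulation_fit <- fit_modulation_model(records, sfit,
                                               term_set = modulation_terms)
  out
}
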