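#' Read and write force curves in the package CSV dialect
#'
#' A curve file holds `#`-prefixed metadata lines (`k_n_m`, `theta_deg`,
#' `z_glass_nm`, `id`) followed by a CSV header `Z_nm,d_nm` and the
#' samples.
#'
#' @param curve a [force_curve()].
#' @param path file path.
#' @return `read_force_curve()` returns a `force_curve`.
#' @export
write_force_curve <- function(curve, path) {
  stopifnot(inherits(curve, "force_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# k_n_m=%.10g", curve$k_n_m),
               sprintf("# theta_deg=%.10g", curve$theta_deg),
               sprintf("# z_glass_nm=%.10g", curve$z_glass_nm),
               sprintf("# id=%s", curve$id),
               "Z_nm,d_nm"), con)
  writeLines(sprintf("%.10g,%.10g", curve$Z_nm, curve$d_nm), con)
  invisible(path)
}

#' @rdname write_force_curve
#' @export
read_force_curve <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- strsplit(sub("^#\\s*", "", ml), "=", fixed = TRUE)[[1]]
    meta[[trimws(kv[1])]] <- trimws(kv[2])
  }
  need <- c("k_n_m", "theta_deg", "z_glass_nm")
  if (!all(need %in% names(meta)))
    stop("malformed curve file: missing metadata ",
         paste(setdiff(need, names(meta)), collapse = ", "))
  body <- lines[!grepl("^#", lines)]
  dat <- read.csv(text = paste(body, collapse = "\n"))
  if (!all(c("Z_nm", "d_nm") %in% names(dat)))
    stop("malformed curve file: expected Z_nm,d_nm columns")
  force_curve(dat$Z_nm, dat$d_nm, as.numeric(meta$k_n_m),
              as.numeric(meta$theta_deg), as.numeric(meta$z_glass_nm),
              id = if (is.null(meta$id)) basename(path) else meta$id)
}

#' Write intensity, mask and orientation maps as TIFF
#'
#' Intensity maps are stored as 32-bit TIFF after division by `scale`
#' (the maps are in arbitrary units; `scale` defaults to the image
#' maximum and is returned so values can be restored).  Masks are stored
#' as 8-bit 0/1.  Orientation maps are stored as `(degrees + 90) / 360`
#' (so the on-mask range is strictly inside (0, 1)) with off-mask `NA`
#' encoded as 0.
#'
#' @param x matrix to write (intensity, logical mask, or degrees).
#' @param path file path.
#' @param scale intensity scale divisor.
#' @return `write_intensity_tiff()` invisibly returns the scale used;
#'   readers return the decoded matrix.
#' @export
write_intensity_tiff <- function(x, path, scale = max(x, 1e-12)) {
  tiff::writeTIFF(pmin(pmax(x / scale, 0), 1), path,
                  bits.per.sample = 32L)
  invisible(scale)
}

#' @rdname write_intensity_tiff
#' @export
read_intensity_tiff <- function(path, scale = 1) {
  as.matrix(tiff::readTIFF(path)) * scale
}

#' @rdname write_intensity_tiff
#' @export
write_mask_tiff <- function(x, path) {
  tiff::writeTIFF(matrix(as.numeric(x), nrow(x)), path,
                  bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_intensity_tiff
#' @export
read_mask_tiff <- function(path) {
  as.matrix(tiff::readTIFF(path)) > 0.5
}

#' @rdname write_intensity_tiff
#' @export
write_lof_tiff <- function(x, path) {
  enc <- ifelse(is.finite(x), (x + 90) / 360, 0)
  tiff::writeTIFF(enc, path, bits.per.sample = 32L)
  invisible(path)
}

#' @rdname write_intensity_tiff
#' @export
read_lof_tiff <- function(path) {
  enc <- as.matrix(tiff::readTIFF(path))
  out <- enc * 360 - 90
  out[enc == 0] <- NA_real_
  out
}

#' Read and write per-cell record tables (TSV)
#'
#' @param records data frame of per-cell quantities.
#' @param path file path.
#' @return `read_cell_records()` returns the data frame.
#' @export
write_cell_records <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cell_records
#' @export
read_cell_records <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Pipeline configuration
#'
#' All tunable parameters of the image and force-curve pipelines with
#' their defaults; any subset can be overridden, and configurations
#' round-trip through YAML unchanged.
#'
#' @param ... named overrides of the defaults.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    segmentation = list(n_kernels = 30L, sigma_along = 6,
                        sigma_across = 1.5, threshold = "otsu",
                        threshold_value = NA),
    refinement = unclass(refinement_config()),
    background = list(window = 21L, grow_step = 10L, min_px = 10L),
    cell_mask = list(blur_sigma = 8, close_size = 7L),
    calibration = list(p_endo = 0),
    afm = list(min_contact_frac = 0.10, min_contact = 10L,
               baseline_frac = 0.25, r2_accept = 0.75),
    pooling = list(csk_max_um = 4, nr_min_um = 5),
    stats = list(bin_size_csk = 10L, bin_size_nr = 4L),
    seed = 1L)
  over <- list(...)
  for (nm in names(over)) {
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(over[[nm]]))
      modifyList(cfg[[nm]], over[[nm]]) else over[[nm]]
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @param cfg a `pipeline_config`.
#' @param path file path.
#' @export
write_pipeline_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}
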