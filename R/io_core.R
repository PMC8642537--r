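#' Construct an enface angiogram image
#'
#' The basic container for a 2D enface OCTA decorrelation image: a square
#' matrix of intensities in \[0, 1\] together with the physical width of the
#' field of view. The pixel size in micrometres is derived from the field
#' width, so all physically specified thresholds (e.g. inter-capillary
#' distance bounds) can be converted to pixels unambiguously.
#'
#' @param pixels numeric matrix of intensities in \[0, 1\]; must be square.
#' @param field_width_mm physical width of the field of view in millimetres
#'   (default 3, the macular 3 x 3 mm scan).
#' @param plexus `"SCP"` or `"DCP"` (superficial / deep capillary plexus).
#' @return An object of class `enface_image` with elements `pixels`,
#'   `n_rows`, `n_cols`, `field_width_mm`, `plexus` and `pixel_size_um`.
#' @export
enface_image <- function(pixels, field_width_mm = 3, plexus = c("SCP", "DCP")) {
  plexus <- match.arg(plexus)
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix")
  }
  if (nrow(pixels) != ncol(pixels) || nrow(pixels) < 1) {
    stop("enface image must be square and non-empty (got ",
         nrow(pixels), " x ", ncol(pixels), ")")
  }
  if (anyNA(pixels) || any(!is.finite(pixels))) {
    stop("all intensities must be finite")
  }
  if (min(pixels) < 0 || max(pixels) > 1) {
    stop("intensities must lie in [0, 1]")
  }
  if (!is.numeric(field_width_mm) || field_width_mm <= 0) {
    stop("`field_width_mm` must be positive")
  }
  structure(
    list(
      pixels = pixels,
      n_rows = nrow(pixels),
      n_cols = ncol(pixels),
      field_width_mm = field_width_mm,
      plexus = plexus,
      pixel_size_um = field_width_mm * 1000 / ncol(pixels)
    ),
    class = "enface_image"
  )
}

#' @export
print.enface_image <- function(x, ...) {
  cat(sprintf("enface_image: %d x %d px, %.1f mm field (%.3f um/px), plexus %s\n",
              x$n_rows, x$n_cols, x$field_width_mm, x$pixel_size_um, x$plexus))
  invisible(x)
}

#' Validate a binary mask against a parent image or matrix
#'
#' Masks (FAZ, truth vessel masks, nonperfusion masks) are plain logical
#' matrices whose shape must match the image they refer to.
#'
#' @param mask logical matrix.
#' @param parent an `enface_image` or a matrix of the required shape, or
#'   `NULL` to skip the shape check.
#' @return The mask, invisibly coerced to logical.
#' @export
as_mask <- function(mask, parent = NULL) {
  if (is.numeric(mask)) mask <- mask != 0
  if (!is.matrix(mask) || !is.logical(mask)) {
    stop("mask must be a logical matrix")
  }
  if (anyNA(mask)) stop("mask must not contain NA")
  if (!is.null(parent)) {
    dims <- if (inherits(parent, "enface_image")) {
      c(parent$n_rows, parent$n_cols)
    } else {
      dim(parent)
    }
    if (!identical(dim(mask), as.integer(dims))) {
      stop("mask shape ", paste(dim(mask), collapse = "x"),
           " does not match parent ", paste(dims, collapse = "x"))
    }
  }
  mask
}

#' Analysis configuration
#'
#' Bundles every tunable parameter of the quantification pipeline. Defaults
#' follow the conventions of the enface OCTA quantification literature; see
#' the methods vignette for the rationale behind each value.
#'
#' @param threshold_multiplier multiplier k in the FAZ-referenced binarization
#'   threshold mean + k * SD of the FAZ intensities (default 1.2).
#' @param sd_type `"population"` (divide by n, default) or `"sample"` for the
#'   FAZ standard deviation.
#' @param frangi_scales Gaussian scales (pixels) for the vesselness filter;
#'   capillaries are 1-2 px wide at ~10 um/px.
#' @param threshold_on `"gated"` (default: threshold the raw decorrelation
#'   image at the FAZ-referenced value and keep only pixels with nonzero
#'   vesselness, so the Frangi filter acts as the noise suppressor),
#'   `"raw"` (threshold the raw image only) or `"enhanced"` (threshold the
#'   vesselness-enhanced image itself).
#' @param min_object_px connected vessel components smaller than this are
#'   removed from the binary map as speckle (default 20 px).
#' @param cnp_distance_threshold_um,gpd_distance_threshold_um distance bounds
#'   (micrometres) above which a pixel counts as nonperfused; 30 um is the
#'   usual normal inter-capillary bound.
#' @param cnp_min_region_px2 minimum deficit region area kept by the
#'   attribute filter in the capillary-nonperfusion chain (px^2).
#' @param cnp_erosion_radius_px erosion radius applied to the CNP deficit
#'   mask after attribute filtering (px).
#' @param cnp_morphology logical; apply the attribute filter + erosion in the
#'   CNP chain (default TRUE). Disable for the raw thresholded fraction.
#' @param denominator `"image"` (percent of the whole image, default) or
#'   `"image_minus_faz"` for the nonperfusion percent denominators.
#' @param fd_box_sizes strictly increasing box sizes (px) for the
#'   box-counting fractal dimension fit.
#' @param vti_min_segment_px skeleton segments shorter than this are excluded
#'   from the tortuosity index (default 3 px; 1-2 px spurs are thinning
#'   artifacts).
#' @param vti_weighted arc-length-weighted (default) or unweighted mean of
#'   the per-segment arc/chord ratios.
#' @param vci_pooled if TRUE use pooled perimeter/area counts for the
#'   complexity index instead of the per-component area-weighted mean.
#' @param vci_perimeter `"chain_corrected"` (corner-corrected boundary
#'   length, default) or `"pixel_count"` (literal perimeter-pixel count)
#'   for the complexity index.
#' @param vdi_inverted if TRUE report VLD/VD instead of VD/VLD for the
#'   diameter index.
#' @param bonferroni_m multiple-comparison family size (default 15, one per
#'   reported metric).
#' @param seed integer seed for any stochastic step.
#' @return An object of class `analysis_config` (a named list).
#' @export
analysis_config <- function(threshold_multiplier = 1.2,
                            sd_type = c("population", "sample"),
                            frangi_scales = c(1, 1.5, 2),
                            threshold_on = c("gated", "raw", "enhanced"),
                            min_object_px = 20,
                            cnp_distance_threshold_um = 30,
                            gpd_distance_threshold_um = 30,
                            cnp_min_region_px2 = 500,
                            cnp_erosion_radius_px = 1,
                            cnp_morphology = TRUE,
                            denominator = c("image", "image_minus_faz"),
                            fd_box_sizes = c(2, 4, 8, 16, 32, 64),
                            vti_min_segment_px = 3,
                            vti_weighted = TRUE,
                            vci_pooled = FALSE,
                            vci_perimeter = c("chain_corrected",
                                              "pixel_count"),
                            vdi_inverted = FALSE,
                            bonferroni_m = 15,
                            seed = 1L) {
  sd_type <- match.arg(sd_type)
  threshold_on <- match.arg(threshold_on)
  denominator <- match.arg(denominator)
  vci_perimeter <- match.arg(vci_perimeter)
  stopifnot(
    threshold_multiplier >= 0,
    length(frangi_scales) >= 1, all(frangi_scales > 0),
    cnp_distance_threshold_um > 0, gpd_distance_threshold_um > 0,
    cnp_min_region_px2 >= 0, cnp_erosion_radius_px >= 0,
    length(fd_box_sizes) >= 2, all(diff(fd_box_sizes) > 0),
    all(fd_box_sizes >= 1),
    min_object_px >= 0, vti_min_segment_px >= 1, bonferroni_m >= 1
  )
  structure(
    list(
      threshold_multiplier = threshold_multiplier,
      sd_type = sd_type,
      frangi_scales = frangi_scales,
      threshold_on = threshold_on,
      min_object_px = min_object_px,
      cnp_distance_threshold_um = cnp_distance_threshold_um,
      gpd_distance_threshold_um = gpd_distance_threshold_um,
      cnp_min_region_px2 = cnp_min_region_px2,
      cnp_erosion_radius_px = cnp_erosion_radius_px,
      cnp_morphology = cnp_morphology,
      denominator = denominator,
      fd_box_sizes = fd_box_sizes,
      vti_min_segment_px = vti_min_segment_px,
      vti_weighted = vti_weighted,
      vci_pooled = vci_pooled,
      vci_perimeter = vci_perimeter,
      vdi_inverted = vdi_inverted,
      bonferroni_m = bonferroni_m,
      seed = as.integer(seed)
    ),
    class = "analysis_config"
  )
}

#' Read or write an analysis configuration as JSON
#'
#' @param path file path.
#' @param config an `analysis_config`.
#' @return `read_config` returns an `analysis_config`.
#' @export
read_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(analysis_config, vals)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "analysis_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a grayscale enface image from PNG or TIFF
#'
#' Intensities are rescaled linearly to \[0, 1\] by the file's bit-depth
#' maximum (255 or 65535). Only square single-channel images are accepted.
#'
#' @param path PNG or TIFF file path.
#' @param field_width_mm physical field width in millimetres.
#' @param plexus `"SCP"` or `"DCP"`.
#' @return An [enface_image].
#' @export
read_enface <- function(path, field_width_mm = 3, plexus = c("SCP", "DCP")) {
  plexus <- match.arg(plexus)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    arr <- png::readPNG(path)  # already scaled to [0,1] by bit depth
  } else if (ext %in% c("tif", "tiff")) {
    arr <- tiff::readTIFF(path)
  } else {
    stop("unsupported image format '.", ext, "': use PNG or TIFF")
  }
  if (length(dim(arr)) == 3) {
    if (dim(arr)[3] != 1) {
      stop("multi-channel image rejected: a single-channel grayscale ",
           "enface image is required")
    }
    arr <- arr[, , 1]
  }
  if (nrow(arr) != ncol(arr)) {
    stop("non-square image rejected (", nrow(arr), " x ", ncol(arr),
         "): enface scans are square")
  }
  enface_image(arr, field_width_mm = field_width_mm, plexus = plexus)
}

#' Write an image or mask as an 8- or 16-bit grayscale PNG
#'
#' Masks are written as 0/255; intensity images are quantized to the
#' requested bit depth.
#'
#' @param x an `enface_image`, a logical mask matrix, or a numeric matrix in
#'   \[0, 1\].
#' @param path output PNG path.
#' @param bit_depth 8 or 16.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(x, path, bit_depth = 8) {
  stopifnot(bit_depth %in% c(8, 16))
  m <- if (inherits(x, "enface_image")) x$pixels else x
  if (is.logical(m)) m <- m * 1
  m[m < 0] <- 0
  m[m > 1] <- 1
  png::writePNG(m, path, dpi = NULL)  # writePNG quantizes from [0,1]
  invisible(path)
}

#' Read a FAZ (or other) mask from a PNG file
#'
#' Any nonzero pixel is part of the mask.
#'
#' @param path PNG path.
#' @param parent optional `enface_image` for a shape check.
#' @return Logical matrix.
#' @export
read_mask <- function(path, parent = NULL) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3) arr <- arr[, , 1]
  as_mask(arr != 0, parent)
}

#' Write a per-eye metrics table to CSV
#'
#' One row per eye with the clinical covariates and every metric for each
#' plexus. Missing metric values are written as empty cells (never zeros) so
#' that absence is unambiguous downstream.
#'
#' @param records a data frame as produced by [cohort_metrics_table] or
#'   [make_cohort].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics_table <- function(records, path) {
  stopifnot(is.data.frame(records), nrow(records) >= 1)
  write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_metrics_table
#' @export
read_metrics_table <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Emit a structured log line
#'
#' @param stage pipeline stage name.
#' @param ... named values to report.
#' @param level one of "debug", "info", "warn".
#' @keywords internal
log_line <- function(stage, ..., level = "info") {
  opts <- getOption("octaquant.log_level", "warn")
  ranks <- c(debug = 1, info = 2, warn = 3)
  if (ranks[[level]] < ranks[[opts]]) return(invisible(NULL))
  vals <- list(...)
  kv <- paste(names(vals), vapply(vals, format, ""), sep = "=", collapse = " ")
  message(sprintf("[%s] %s %s", level, stage, kv))
  invisible(NULL)
}
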