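#' Euclidean distance map to a vessel or skeleton reference
#'
#' Exact Euclidean distance (micrometres) from every pixel to the nearest
#' reference pixel; zero on the reference itself.
#'
#' @param reference logical mask of reference pixels (vessel map or skeleton).
#' @param pixel_size_um pixel size in micrometres.
#' @param which `"BINARY"` or `"SKELETON"`, recorded for provenance.
#' @return An object of class `distance_map`: `um` (numeric matrix of
#'   distances in micrometres) and `reference` (the enum label).
#' @export
distance_map <- function(reference, pixel_size_um,
                         which = c("BINARY", "SKELETON")) {
  which <- match.arg(which)
  reference <- as_mask(reference)
  stopifnot(pixel_size_um > 0)
  if (!any(reference)) {
    stop("reference mask is empty: all distances would be infinite")
  }
  structure(
    list(um = edt_to_reference(reference) * pixel_size_um, reference = which),
    class = "distance_map"
  )
}

# Shared deficit computation: threshold a distance map and exclude FAZ.
deficit_from_distance <- function(dist_um, reference, faz, threshold_um,
                                  denominator) {
  mask <- dist_um > threshold_um
  mask <- mask & !faz
  mask[reference] <- FALSE  # reference pixels are perfused by definition
  denom <- if (denominator == "image_minus_faz") {
    length(mask) - sum(faz)
  } else {
    length(mask)
  }
  list(mask = mask, percent = 100 * sum(mask) / denom)
}

#' Capillary nonperfusion (CNP)
#'
#' Pixels farther from the nearest vessel pixel than the normal
#' inter-capillary bound form the raw deficit; an area attribute filter
#' (removing deficit regions below a minimum size) followed by erosion
#' suppresses spurious slivers, and the FAZ — physiologically avascular —
#' is excluded last.
#'
#' @param binary logical vessel mask.
#' @param faz logical FAZ mask.
#' @param config an [analysis_config]; uses `cnp_distance_threshold_um`,
#'   `cnp_min_region_px2`, `cnp_erosion_radius_px`, `cnp_morphology`,
#'   `denominator`.
#' @param pixel_size_um pixel size in micrometres.
#' @return An object of class `nonperfusion_result`: `mask`, `percent`,
#'   `method = "CNP"`, `threshold_um`.
#' @export
cnp_quantify <- function(binary, faz, config = analysis_config(),
                         pixel_size_um) {
  binary <- as_mask(binary)
  faz <- as_mask(faz, binary)
  dm <- distance_map(binary, pixel_size_um, which = "BINARY")
  raw <- dm$um > config$cnp_distance_threshold_um
  if (isTRUE(config$cnp_morphology)) {
    raw <- remove_small_components(raw, config$cnp_min_region_px2)
    raw <- erode_disk(raw, config$cnp_erosion_radius_px)
  }
  mask <- raw & !faz
  mask[binary] <- FALSE
  denom <- if (config$denominator == "image_minus_faz") {
    length(mask) - sum(faz)
  } else {
    length(mask)
  }
  structure(
    list(mask = mask, percent = 100 * sum(mask) / denom,
         method = "CNP", threshold_um = config$cnp_distance_threshold_um),
    class = "nonperfusion_result"
  )
}

#' Geometric perfusion deficit (GPD)
#'
#' Same construction as [cnp_quantify] but measured from the skeletonized
#' vessels: pixels farther from the nearest centerline pixel than the
#' threshold, FAZ excluded, with no morphological post-filtering.
#'
#' @param skeleton logical skeleton mask.
#' @param faz logical FAZ mask.
#' @param config an [analysis_config]; uses `gpd_distance_threshold_um` and
#'   `denominator`.
#' @param pixel_size_um pixel size in micrometres.
#' @return A `nonperfusion_result` with `method = "GPD"`.
#' @export
gpd_quantify <- function(skeleton, faz, config = analysis_config(),
                         pixel_size_um) {
  skeleton <- as_mask(skeleton)
  faz <- as_mask(faz, skeleton)
  dm <- distance_map(skeleton, pixel_size_um, which = "SKELETON")
  res <- deficit_from_distance(dm$um, skeleton, faz,
                               config$gpd_distance_threshold_um,
                               config$denominator)
  structure(
    list(mask = res$mask, percent = res$percent,
         method = "GPD", threshold_um = config$gpd_distance_threshold_um),
    class = "nonperfusion_result"
  )
}

#' @export
print.nonperfusion_result <- function(x, ...) {
  cat(sprintf("%s: %.3f%% of image area (threshold %.1f um)\n",
              x$method, x$percent, x$threshold_um))
  invisible(x)
}

#' Fallback FAZ detector
#'
#' When no FAZ mask file is supplied, the FAZ is taken as the connected
#' avascular (background) region containing the image center, after closing
#' 1-pixel gaps in the vessel map so that near-touching capillaries seal the
#' FAZ boundary.
#'
#' @param binary logical vessel mask.
#' @param pixel_size_um pixel size in micrometres (kept for interface
#'   symmetry; the detection itself is pixel-based).
#' @return Logical FAZ mask.
#' @export
faz_fallback <- function(binary, pixel_size_um = NULL) {
  binary <- as_mask(binary)
  closed <- erode_disk(dilate_disk(binary, 1), 1)  # close 1-px gaps
  ctr <- (dim(binary) + 1) %/% 2
  if (closed[ctr[1], ctr[2]]) {
    stop("image center is a vessel pixel: no central avascular zone found; ",
         "supply a FAZ mask file")
  }
  lab <- EBImage::bwlabel(!closed)
  mask <- lab == lab[ctr[1], ctr[2]]
  matrix(mask, nrow(binary), ncol(binary))
}

#' Write a deficit overlay PNG (red over grayscale)
#'
#' @param image an [enface_image].
#' @param mask logical deficit mask.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_overlay_png <- function(image, mask, path) {
  stopifnot(inherits(image, "enface_image"))
  mask <- as_mask(mask, image)
  g <- image$pixels
  rgb <- array(g, dim = c(nrow(g), ncol(g), 3))
  r <- rgb[, , 1]; r[mask] <- 1; rgb[, , 1] <- r
  g2 <- rgb[, , 2]; g2[mask] <- 0.2 * g2[mask]; rgb[, , 2] <- g2
  b <- rgb[, , 3]; b[mask] <- 0.2 * b[mask]; rgb[, , 3] <- b
  png::writePNG(rgb, path)
  invisible(path)
}
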