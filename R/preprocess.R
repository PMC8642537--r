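#' Frangi vesselness enhancement
#'
#' Multi-scale ridge filter: at each Gaussian scale the Hessian eigenvalues
#' are computed per pixel, tubular (bright-on-dark) structures score high
#' through the blobness ratio and structure-ness terms, and the per-pixel
#' maximum over scales is taken. The response is rescaled to \[0, 1\].
#'
#' @param image an [enface_image] (or a numeric matrix in \[0, 1\]).
#' @param scales Gaussian scales in pixels; must be non-empty and positive.
#' @param beta blobness sensitivity (default 0.5, the standard choice).
#' @return An `enface_image` of vesselness values in \[0, 1\] with the same
#'   geometry as the input.
#' @export
frangi_enhance <- function(image, scales = c(1, 1.5, 2), beta = 0.5) {
  if (length(scales) < 1 || any(scales <= 0)) {
    stop("`scales` must be a non-empty vector of positive pixel scales")
  }
  x <- if (inherits(image, "enface_image")) image$pixels else image
  best <- matrix(0, nrow(x), ncol(x))
  for (s in scales) {
    k <- gauss_kernels(s)
    # scale-normalized Hessian (gamma = 2)
    hrr <- conv1d(conv1d(x, k$g2, dim = 1), k$g, dim = 2) * s^2
    hcc <- conv1d(conv1d(x, k$g, dim = 1), k$g2, dim = 2) * s^2
    hrc <- conv1d(conv1d(x, k$g1, dim = 1), k$g1, dim = 2) * s^2
    tmp <- sqrt(((hrr - hcc) / 2)^2 + hrc^2)
    mu1 <- (hrr + hcc) / 2 + tmp
    mu2 <- (hrr + hcc) / 2 - tmp
    # order by absolute value: |l1| <= |l2|
    swap <- abs(mu1) > abs(mu2)
    l1 <- ifelse(swap, mu2, mu1)
    l2 <- ifelse(swap, mu1, mu2)
    s2 <- l1^2 + l2^2
    smax <- sqrt(max(s2))
    # flat image at this scale: the structure-ness normalization c = smax/2
    # is scale free, so guard against amplifying numerical dust
    if (smax < 1e-8) next
    rb2 <- ifelse(l2 != 0, (l1 / l2)^2, 0)
    c2 <- (smax / 2)^2
    v <- exp(-rb2 / (2 * beta^2)) * (1 - exp(-s2 / (2 * c2)))
    v[l2 >= 0] <- 0  # dark-on-bright or flat: not a bright vessel
    best <- pmax(best, v)
  }
  mx <- max(best)
  if (mx > 1e-10) best <- best / mx else best[] <- 0
  if (inherits(image, "enface_image")) {
    enface_image(best, field_width_mm = image$field_width_mm,
                 plexus = image$plexus)
  } else {
    best
  }
}

#' FAZ-referenced binarization threshold
#'
#' The interior of the foveal avascular zone carries no flow signal, so its
#' intensity distribution is pure noise; the vessel/background threshold is
#' set at `mean + k * SD` of the intensities inside the FAZ mask.
#'
#' @param image an [enface_image] or numeric matrix.
#' @param faz logical FAZ mask (same shape); needs at least 2 pixels so the
#'   SD is defined.
#' @param k multiplier on the SD (default 1.2).
#' @param sd_type `"population"` (divide by n, default) or `"sample"`.
#' @return The threshold intensity.
#' @export
faz_threshold <- function(image, faz, k = 1.2,
                          sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  x <- if (inherits(image, "enface_image")) image$pixels else image
  faz <- as_mask(faz, x)
  n <- sum(faz)
  if (n < 2) {
    stop("FAZ mask must contain at least 2 pixels (SD undefined for n = ",
         n, ")")
  }
  vals <- x[faz]
  s <- sd(vals)
  if (sd_type == "population") s <- s * sqrt((n - 1) / n)
  mean(vals) + k * s
}

#' Binarize an image at a fixed threshold
#'
#' @param image an [enface_image] or numeric matrix.
#' @param threshold intensity in \[0, 1\]; a pixel is foreground iff its
#'   intensity is strictly greater.
#' @return Logical vessel mask.
#' @export
binarize <- function(image, threshold) {
  stopifnot(threshold >= 0, threshold <= 1)
  x <- if (inherits(image, "enface_image")) image$pixels else image
  x > threshold
}

#' Topology-preserving skeletonization
#'
#' Thins the binary vessel map to single-pixel-wide centerlines by
#' sequential deletion of simple points (8-connected foreground,
#' 4-connected background), which preserves connected components and holes
#' — and hence the Euler number — by construction. Endpoints are retained.
#'
#' @param binary logical vessel mask.
#' @return Logical skeleton mask, a subset of `binary` with no 2x2 block of
#'   foreground.
#' @export
skeletonize_map <- function(binary) {
  binary <- as_mask(binary)
  if (!any(binary)) return(binary)
  .thin_cpp(binary)
}

#' Vessel perimeter map
#'
#' Marks foreground pixels that are 4-adjacent to at least one background
#' pixel; the image border counts as background.
#'
#' @param binary logical vessel mask.
#' @return Logical perimeter mask, a subset of `binary`.
#' @export
perimeter_of <- function(binary) {
  binary <- as_mask(binary)
  has_bg <- !shift_mat(binary, 1, 0, fill = FALSE) |
    !shift_mat(binary, -1, 0, fill = FALSE) |
    !shift_mat(binary, 0, 1, fill = FALSE) |
    !shift_mat(binary, 0, -1, fill = FALSE)
  binary & has_bg
}

#' Derive the vessel, skeleton and perimeter maps of one enface image
#'
#' The full preprocessing chain: vesselness enhancement, FAZ-referenced
#' binarization, speckle removal, skeletonization and perimeter extraction.
#'
#' @param image an [enface_image].
#' @param faz logical FAZ mask used as the noise reference.
#' @param config an [analysis_config].
#' @return An object of class `vessel_maps` with elements `binary`,
#'   `skeleton`, `perimeter` (logical matrices) and `threshold_used`.
#' @export
make_vessel_maps <- function(image, faz, config = analysis_config()) {
  stopifnot(inherits(image, "enface_image"))
  faz <- as_mask(faz, image)
  work <- if (config$threshold_on == "enhanced") {
    frangi_enhance(image, scales = config$frangi_scales)
  } else {
    image
  }
  thr <- faz_threshold(work, faz, k = config$threshold_multiplier,
                       sd_type = config$sd_type)
  thr <- min(max(thr, 0), 1)
  binary <- binarize(work, thr)
  if (config$threshold_on == "gated") {
    # vesselness gate: keep only tubular structure, discarding bright
    # speckle that clears the intensity threshold
    ves <- frangi_enhance(image, scales = config$frangi_scales)
    binary <- binary & (ves$pixels > 0)
  }
  binary <- remove_small_components(binary, config$min_object_px)
  maps <- structure(
    list(
      binary = binary,
      skeleton = skeletonize_map(binary),
      perimeter = perimeter_of(binary),
      threshold_used = thr
    ),
    class = "vessel_maps"
  )
  log_line("preprocess", threshold = round(thr, 4),
           vessel_px = sum(binary), skeleton_px = sum(maps$skeleton))
  maps
}

#' @export
print.vessel_maps <- function(x, ...) {
  cat(sprintf(
    "vessel_maps: %d x %d px, %d vessel px, %d skeleton px, threshold %.4f\n",
    nrow(x$binary), ncol(x$binary), sum(x$binary), sum(x$skeleton),
    x$threshold_used))
  invisible(x)
}
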