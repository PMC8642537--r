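#' Vessel (area) density
#'
#' Percent of image pixels occupied by vessels.
#'
#' @param binary logical vessel mask.
#' @return VD in percent of the image area.
#' @export
vessel_density <- function(binary) {
  binary <- as_mask(binary)
  100 * sum(binary) / length(binary)
}

#' Vessel length density
#'
#' Percent of image pixels occupied by the single-pixel skeleton; with each
#' vessel reduced to its centerline, large and small vessels contribute to
#' density in proportion to length, not caliber.
#'
#' @param skeleton logical skeleton mask.
#' @return VLD in percent of the image area.
#' @export
vessel_length_density <- function(skeleton) {
  skeleton <- as_mask(skeleton)
  100 * sum(skeleton) / length(skeleton)
}

#' Vessel diameter index
#'
#' Mean vessel caliber surrogate: the ratio of vessel area density to
#' skeleton length density, i.e. average vessel width in pixels. The
#' inverted quotient (VLD/VD) is available via `inverted = TRUE`.
#'
#' @param vd vessel density (percent).
#' @param vld vessel length density (percent).
#' @param inverted report VLD/VD instead of VD/VLD.
#' @return The diameter index, or `NA` when the denominator is 0.
#' @export
vessel_diameter_index <- function(vd, vld, inverted = FALSE) {
  if (inverted) {
    if (is.na(vd) || vd == 0) return(NA_real_)
    return(vld / vd)
  }
  if (is.na(vld) || vld == 0) return(NA_real_)
  vd / vld
}

# Box-occupancy counts N(s) over a fixed grid anchored at the image origin.
box_counts <- function(skeleton, box_sizes) {
  pix <- which(skeleton, arr.ind = TRUE)
  vapply(box_sizes, function(s) {
    br <- (pix[, 1] - 1L) %/% s
    bc <- (pix[, 2] - 1L) %/% s
    length(unique(br * (ncol(skeleton) %/% s + 2L) + bc))
  }, integer(1))
}

#' Box-counting fractal dimension
#'
#' Slope of the least-squares fit of `log N(s)` against `log(1/s)` over the
#' configured box sizes, with the box grid anchored at the image origin for
#' determinism. A space-filling region scores close to 2, a smooth curve
#' close to 1.
#'
#' @param skeleton logical skeleton mask.
#' @param box_sizes strictly increasing box edge lengths in pixels.
#' @return The fitted dimension, or `NA` for an empty skeleton.
#' @export
fractal_dimension <- function(skeleton, box_sizes = c(2, 4, 8, 16, 32, 64)) {
  skeleton <- as_mask(skeleton)
  stopifnot(length(box_sizes) >= 2, all(diff(box_sizes) > 0))
  if (!any(skeleton)) return(NA_real_)
  n <- box_counts(skeleton, box_sizes)
  if (all(n == n[1])) return(0)  # e.g. a single pixel: flat count curve
  fit <- lm(log(n) ~ log(1 / box_sizes))
  unname(coef(fit)[2])
}

#' Decompose a skeleton into vessel segments
#'
#' Partitions the skeleton into maximal paths between nodes, where a node is
#' a pixel with a number of 8-connected skeleton neighbors different from 2
#' (an endpoint or a branch point). Isolated closed loops are split into two
#' halves so that both carry a nonzero chord.
#'
#' @param skeleton logical skeleton mask.
#' @return A list of segments; each has `path` (n x 2 matrix of (row, col)),
#'   `arc_length_px` (chain-code length: 1 per axial step, sqrt(2) per
#'   diagonal step) and `chord_length_px` (Euclidean endpoint distance).
#' @export
decompose_segments <- function(skeleton) {
  skeleton <- as_mask(skeleton)
  if (!any(skeleton)) return(list())
  raw <- .trace_segments_cpp(skeleton)
  lapply(raw, function(p) {
    if (nrow(p) < 2) {
      arc <- 0
      chord <- 0
    } else {
      steps <- abs(diff(p))
      arc <- sum(ifelse(rowSums(steps) == 2, sqrt(2), 1))
      chord <- sqrt(sum((p[nrow(p), ] - p[1, ])^2))
    }
    list(path = p, arc_length_px = arc, chord_length_px = chord)
  })
}

#' Vascular tortuosity index
#'
#' Mean over skeleton segments of the arc-length (geodesic) to chord-length
#' (Euclidean) ratio; 1 for perfectly straight vessels. Short spur segments
#' and zero-chord segments (loops attached at a single node) are excluded.
#'
#' @param segments output of [decompose_segments].
#' @param min_segment_px minimum segment pixel count (default 3).
#' @param weighted arc-length-weighted mean (default) or unweighted.
#' @return VTI (>= 1), or `NA` if no valid segment exists.
#' @export
vascular_tortuosity_index <- function(segments, min_segment_px = 3,
                                      weighted = TRUE) {
  if (length(segments) == 0) return(NA_real_)
  keep <- vapply(segments, function(s) {
    nrow(s$path) >= min_segment_px && s$chord_length_px > 0
  }, logical(1))
  segments <- segments[keep]
  if (length(segments) == 0) return(NA_real_)
  ratio <- vapply(segments, function(s) s$arc_length_px / s$chord_length_px,
                  numeric(1))
  if (weighted) {
    w <- vapply(segments, function(s) s$arc_length_px, numeric(1))
    sum(w * ratio) / sum(w)
  } else {
    mean(ratio)
  }
}

#' Vascular complexity index
#'
#' Isoperimetric-type shape measure `P^2 / (4 pi A)` of the binarized vessel
#' map, where `P` is the boundary length of the vessel perimeter map and `A`
#' the vessel pixel count. A circle scores 1; more convoluted shapes score
#' higher. By default the index is computed per 8-connected vessel component
#' and averaged with area weights, which keeps it on the order of 1 for a
#' capillary network; `pooled = TRUE` uses pooled image-wide quantities
#' instead.
#'
#' The boundary length is the corner-corrected chain-code length of the
#' perimeter map (0.980 per axial and 1.406 per diagonal step), which is
#' close to unbiased on rasterized smooth shapes; a raw perimeter-pixel
#' count systematically underestimates the length of diagonal boundary runs
#' and is available via `perimeter_measure = "pixel_count"`.
#'
#' @param binary logical vessel mask.
#' @param perimeter logical perimeter mask (see [perimeter_of]); recomputed
#'   when `NULL`.
#' @param pooled use pooled image-wide quantities.
#' @param perimeter_measure `"chain_corrected"` (default) or
#'   `"pixel_count"`.
#' @return VCI, or `NA` for an empty mask.
#' @export
vascular_complexity_index <- function(binary, perimeter = NULL,
                                      pooled = FALSE,
                                      perimeter_measure = c("chain_corrected",
                                                            "pixel_count")) {
  perimeter_measure <- match.arg(perimeter_measure)
  binary <- as_mask(binary)
  if (!any(binary)) return(NA_real_)
  if (is.null(perimeter)) perimeter <- perimeter_of(binary)
  perimeter <- as_mask(perimeter, binary)
  lab <- .label8_cpp(binary)
  n_labels <- max(lab)
  area <- tabulate(lab[lab > 0], nbins = n_labels)
  plen <- if (perimeter_measure == "chain_corrected") {
    chain_length_by_label(perimeter, lab, n_labels)
  } else {
    tabulate(lab[perimeter], nbins = n_labels)
  }
  if (pooled) {
    return(sum(plen)^2 / (4 * pi * sum(area)))
  }
  vci_comp <- plen^2 / (4 * pi * area)
  sum(area * vci_comp) / sum(area)
}

#' Compute the full per-plexus metric set
#'
#' Runs every vascular index and both nonperfusion measures on one set of
#' vessel maps.
#'
#' @param maps a `vessel_maps` object (see [make_vessel_maps]).
#' @param faz logical FAZ mask.
#' @param config an [analysis_config].
#' @param pixel_size_um pixel size in micrometres (taken from the image the
#'   maps came from).
#' @return A named list of class `metric_set`: `vd`, `vld`, `vdi`, `fd`,
#'   `vti`, `vci`, `cnp_pct`, `gpd_pct`, `faz_area_mm2`.
#' @export
compute_metric_set <- function(maps, faz, config = analysis_config(),
                               pixel_size_um) {
  stopifnot(inherits(maps, "vessel_maps"))
  faz <- as_mask(faz, maps$binary)
  vd <- vessel_density(maps$binary)
  vld <- vessel_length_density(maps$skeleton)
  segs <- decompose_segments(maps$skeleton)
  cnp <- if (any(maps$binary)) {
    cnp_quantify(maps$binary, faz, config, pixel_size_um)$percent
  } else NA_real_
  gpd <- if (any(maps$skeleton)) {
    gpd_quantify(maps$skeleton, faz, config, pixel_size_um)$percent
  } else NA_real_
  out <- list(
    vd = vd,
    vld = vld,
    vdi = vessel_diameter_index(vd, vld, inverted = config$vdi_inverted),
    fd = fractal_dimension(maps$skeleton, config$fd_box_sizes),
    vti = vascular_tortuosity_index(segs, config$vti_min_segment_px,
                                    config$vti_weighted),
    vci = vascular_complexity_index(maps$binary, maps$perimeter,
                                    pooled = config$vci_pooled,
                                    perimeter_measure = config$vci_perimeter),
    cnp_pct = cnp,
    gpd_pct = gpd,
    faz_area_mm2 = sum(faz) * (pixel_size_um / 1000)^2
  )
  class(out) <- "metric_set"
  out
}

#' @export
print.metric_set <- function(x, ...) {
  cat("metric_set:\n")
  for (nm in names(x)) {
    cat(sprintf("  %-12s %s\n", nm,
                ifelse(is.na(x[[nm]]), "NA", sprintf("%.4f", x[[nm]]))))
  }
  invisible(x)
}
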