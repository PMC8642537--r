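#' Quantify one enface angiogram end to end
#'
#' Runs the full chain on a single image: FAZ mask resolution
#' (user-supplied mask takes priority over the fallback detector),
#' vesselness enhancement, FAZ-referenced binarization, skeletonization,
#' and every vascular and nonperfusion metric.
#'
#' @param image an [enface_image].
#' @param faz optional logical FAZ mask; when `NULL` the fallback detector
#'   ([faz_fallback]) is applied to a provisional vessel map.
#' @param config an [analysis_config].
#' @return A list with `metrics` (a `metric_set`), `maps` (the
#'   `vessel_maps`) and `faz` (the FAZ mask used).
#' @export
quantify_enface <- function(image, faz = NULL, config = analysis_config()) {
  stopifnot(inherits(image, "enface_image"))
  if (is.null(faz)) {
    # bootstrap FAZ: binarize with a conservative global threshold, then
    # take the central avascular component
    x <- image$pixels
    prelim <- x > stats::median(x)
    prelim <- remove_small_components(prelim, config$min_object_px)
    faz <- faz_fallback(prelim, image$pixel_size_um)
  } else {
    faz <- as_mask(faz, image)
  }
  maps <- make_vessel_maps(image, faz, config)
  metrics <- compute_metric_set(maps, faz, config, image$pixel_size_um)
  list(metrics = metrics, maps = maps, faz = faz)
}

#' Flatten per-plexus metric sets into one eye row
#'
#' @param scp,dcp `metric_set` objects (either may be `NULL`).
#' @param id eye identifier.
#' @return A one-row data frame with `scp_`/`dcp_`-prefixed columns; absent
#'   plexus metrics are `NA` (written as empty CSV cells).
#' @export
metrics_row <- function(scp = NULL, dcp = NULL, id = "eye1") {
  fields <- c("vd", "vld", "vdi", "fd", "vti", "vci", "cnp_pct", "gpd_pct")
  row <- list(eye_id = id)
  faz <- NA_real_
  for (pre in c("scp", "dcp")) {
    ms <- if (pre == "scp") scp else dcp
    for (f in fields) {
      row[[paste0(pre, "_", f)]] <- if (is.null(ms)) NA_real_ else ms[[f]]
    }
    if (!is.null(ms)) faz <- ms$faz_area_mm2
  }
  row$faz_area_mm2 <- faz
  as.data.frame(row, stringsAsFactors = FALSE)
}
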