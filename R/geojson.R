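#' Write crown polygons to GeoJSON
#'
#' Serializes the 2D convex crown envelopes as a FeatureCollection of
#' polygons with properties `id`, `H_m`, `Ar_m2`, `r_m`, `n_points` and,
#' when attributed, `V_m3`, `AGB_Mg`, `agb_sd_Mg`. Coordinates are
#' written in the cloud's projected CRS (no reprojection).
#'
#' @param crowns a [crown_set()].
#' @param path output `.geojson` path.
#' @return `path`, invisibly.
#' @export
write_crowns_geojson <- function(crowns, path) {
  features <- lapply(crowns$crowns, function(cr) {
    hull <- cr$hull
    if (nrow(hull) < 3) {
      # degenerate crowns still serialize; emit a thin triangle ring
      hull <- rbind(hull, hull[1, ] + c(1e-6, 0), hull[1, ] + c(0, 1e-6))
    }
    ring <- rbind(hull, hull[1, , drop = FALSE])
    props <- list(id = cr$id, H_m = cr$H, Ar_m2 = cr$Ar, r_m = cr$r,
                  n_points = cr$n_points)
    if (!is.na(cr$V)) props$V_m3 <- cr$V
    if (!is.na(cr$AGB)) props$AGB_Mg <- cr$AGB
    if (!is.na(cr$agb_sd)) props$agb_sd_Mg <- cr$agb_sd
    list(type = "Feature",
         properties = props,
         geometry = list(type = "Polygon",
                         coordinates = list(unname(
                           lapply(seq_len(nrow(ring)),
                                  function(i) as.numeric(ring[i, ]))))))
  })
  obj <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read crown polygons from GeoJSON
#'
#' Restores a crown set written by [write_crowns_geojson()]. Member
#' points are not stored in GeoJSON, so the restored crowns carry hulls
#' and metrics only (sufficient for attribution, rasterization and
#' Monte Carlo runs with precomputed measurement PDFs).
#'
#' @param path `.geojson` path.
#' @return A [crown_set()].
#' @export
read_crowns_geojson <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  crowns <- lapply(obj$features, function(f) {
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]], unlist))
    hull <- ring[-nrow(ring), , drop = FALSE]
    p <- f$properties
    structure(list(id = p$id,
                   points = NULL,
                   n_points = p$n_points,
                   H = p$H_m, Ar = p$Ar_m2, r = p$r_m,
                   hull = hull,
                   centroid = if (nrow(hull) >= 3) polygon_centroid(hull)
                              else colMeans(hull),
                   V = if (is.null(p$V_m3)) NA_real_ else p$V_m3,
                   AGB = if (is.null(p$AGB_Mg)) NA_real_ else p$AGB_Mg,
                   agb_sd = if (is.null(p$agb_sd_Mg)) NA_real_
                            else p$agb_sd_Mg),
              class = "crown")
  })
  crown_set(crowns)
}
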