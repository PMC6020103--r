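#' Convert stem volume to above-ground biomass
#'
#' `AGB [Mg] = V [m^3] * density [kg m^-3] / 1000`.
#'
#' @param V stem-plus-crown volume, m^3.
#' @param density wood density (oven-dry mass per green volume), kg m^-3.
#' @return AGB in megagrams (Mg).
#' @export
volume_to_agb <- function(V, density) {
  stopifnot(all(V >= 0), all(density >= 0))
  V * density / 1000
}

#' Convert AGB to carbon mass
#'
#' Multiplies by the standard biomass carbon fraction 0.471.
#'
#' @param agb AGB (Mg, or Mg per hectare).
#' @return Carbon mass on the same scale (Mg C).
#' @export
agb_to_carbon <- function(agb) {
  stopifnot(all(agb >= 0))
  0.471 * agb
}

#' Attribute a crown set with volume and AGB
#'
#' Applies the fitted allometry to every crown and converts to AGB with
#' a fixed mean wood density.
#'
#' @param crowns a [crown_set()].
#' @param model an `allometric_model`.
#' @param density mean wood density, kg m^-3.
#' @param agb_sd optional per-crown AGB standard deviations (e.g. from
#'   [run_monte_carlo()]), matched by crown id.
#' @return The crown set with `V`, `AGB` (and `agb_sd`) filled in.
#' @export
attribute_agb <- function(crowns, model, density, agb_sd = NULL) {
  for (i in seq_along(crowns$crowns)) {
    cr <- crowns$crowns[[i]]
    pred <- predict_volume(model, cr$H, cr$Ar)
    cr$V <- pred$V
    cr$AGB <- volume_to_agb(pred$V, density)
    if (!is.null(agb_sd)) {
      m <- match(cr$id, agb_sd$crown_id)
      if (!is.na(m)) cr$agb_sd <- agb_sd$agb_sd[m]
    }
    crowns$crowns[[i]] <- cr
  }
  crowns
}

#' Rasterize a crown set to per-hectare density layers
#'
#' Each crown is assigned to the grid cell containing its hull centroid.
#' With the default 100 m cell (1 ha), cell values are directly per-
#' hectare densities. Layers: `agb_density` (Mg ha^-1), `tree_density`
#' (trees ha^-1), `agb_sd_abs` (Mg ha^-1, per-crown sds aggregated in
#' quadrature, assuming independent crown errors), `agb_sd_rel`
#' (fraction of `agb_density`; 0 where empty).
#'
#' @param crowns a [crown_set()] whose crowns carry `AGB` (see
#'   [attribute_agb()]).
#' @param extent `c(xmin, ymin, xmax, ymax)` or NULL (snapped hull of the
#'   centroids). Crowns outside the extent are dropped with a warning.
#' @param cell cell size, m (default 100).
#' @return An `agb_raster`: list with `origin`, `cell`, `nx`, `ny` and a
#'   `layers` list of matrices (row 1 = southernmost).
#' @export
rasterize_crowns <- function(crowns, extent = NULL, cell = 100) {
  tab <- as.data.frame(crowns)
  if (!nrow(tab)) stop("rasterize_crowns: empty crown set")
  if (anyNA(tab$AGB_Mg)) stop("rasterize_crowns: crowns lack AGB")
  if (is.null(extent)) {
    extent <- c(floor(min(tab$x) / cell) * cell,
                floor(min(tab$y) / cell) * cell,
                ceiling((max(tab$x) + 1e-9) / cell) * cell,
                ceiling((max(tab$y) + 1e-9) / cell) * cell)
  }
  inside <- tab$x >= extent[1] & tab$x < extent[3] &
    tab$y >= extent[2] & tab$y < extent[4]
  if (any(!inside)) {
    warning(sum(!inside), " crown(s) outside extent dropped")
    tab <- tab[inside, , drop = FALSE]
  }
  nx <- as.integer(round((extent[3] - extent[1]) / cell))
  ny <- as.integer(round((extent[4] - extent[2]) / cell))
  ix <- pmin(nx, floor((tab$x - extent[1]) / cell) + 1L)
  iy <- pmin(ny, floor((tab$y - extent[2]) / cell) + 1L)
  cell_ha <- cell^2 / 1e4
  idx <- (ix - 1L) * ny + iy
  lay <- function(v, f) {
    m <- matrix(0, nrow = ny, ncol = nx)
    agg <- tapply(v, idx, f)
    m[as.integer(names(agg))] <- agg
    m
  }
  agb <- lay(tab$AGB_Mg, sum) / cell_ha
  cnt <- lay(rep(1, nrow(tab)), sum) / cell_ha
  sdv <- if (all(is.na(tab$agb_sd_Mg))) matrix(0, ny, nx) else
    sqrt(lay(ifelse(is.na(tab$agb_sd_Mg), 0, tab$agb_sd_Mg)^2, sum)) /
      cell_ha
  rel <- ifelse(agb > 0, sdv / agb, 0)
  structure(list(origin = extent[1:2], cell = cell, nx = nx, ny = ny,
                 crs = NA_character_,
                 layers = list(agb_density = agb, tree_density = cnt,
                               agb_sd_abs = sdv, agb_sd_rel = rel)),
            class = "agb_raster")
}

#' @export
print.agb_raster <- function(x, ...) {
  occ <- x$layers$agb_density[x$layers$tree_density > 0]
  cat(sprintf("<agb_raster> %dx%d cells of %g m\n", x$nx, x$ny, x$cell))
  if (length(occ))
    cat(sprintf("  occupied cells: %d | median AGB %.1f Mg/ha | max %.1f\n",
                length(occ), stats::median(occ), max(occ)))
  invisible(x)
}

#' Write one raster layer as an Esri ASCII grid
#'
#' Plain-text `.asc` raster interchange format readable by all common
#' GIS software; nodata cells are written as -9999.
#'
#' @param raster an `agb_raster`.
#' @param layer layer name (see [rasterize_crowns()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_raster_asc <- function(raster, layer, path) {
  m <- raster$layers[[layer]]
  if (is.null(m)) stop("write_raster_asc: no layer '", layer, "'")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", raster$nx),
               sprintf("nrows %d", raster$ny),
               sprintf("xllcorner %.6f", raster$origin[1]),
               sprintf("yllcorner %.6f", raster$origin[2]),
               sprintf("cellsize %.6f", raster$cell),
               "NODATA_value -9999"), con)
  for (row in rev(seq_len(raster$ny)))   # asc rows run north to south
    writeLines(paste(m[row, ], collapse = " "), con)
  invisible(path)
}

#' Tree count, crown area and AGB share by height class
#'
#' Bins crowns into height classes and, when a forest mask is given,
#' into forest / non-forest strata by centroid-in-polygon. AGB shares
#' are fractions of the grand total, so they sum to 1 over all rows.
#'
#' @param crowns a [crown_set()] with `AGB` attributed.
#' @param forest_mask NULL, or a list of polygons (each an n x 2 matrix
#'   of xy vertices) delimiting forested areas.
#' @param bin_width height class width, m (default 5).
#' @return data.frame: `h_low`, `h_high`, `stratum`, `n_trees`,
#'   `sum_ar_m2`, `agb_mg`, `agb_share`.
#' @export
summarize_by_height_class <- function(crowns, forest_mask = NULL,
                                      bin_width = 5) {
  tab <- as.data.frame(crowns)
  if (!nrow(tab)) stop("summarize_by_height_class: empty crown set")
  bin <- floor(tab$H_m / bin_width)
  stratum <- rep("non-forest", nrow(tab))
  if (!is.null(forest_mask) && length(forest_mask)) {
    inf <- rep(FALSE, nrow(tab))
    for (poly in forest_mask)
      inf <- inf | point_in_polygon(tab$x, tab$y, poly)
    stratum[inf] <- "forest"
  }
  total_agb <- sum(tab$AGB_Mg)
  out <- do.call(rbind, lapply(split(seq_len(nrow(tab)),
                                     list(bin, stratum), drop = TRUE),
                               function(idx) {
    data.frame(h_low = bin[idx[1]] * bin_width,
               h_high = (bin[idx[1]] + 1) * bin_width,
               stratum = stratum[idx[1]],
               n_trees = length(idx),
               sum_ar_m2 = sum(tab$Ar_m2[idx]),
               agb_mg = sum(tab$AGB_Mg[idx]),
               agb_share = if (total_agb > 0)
                 sum(tab$AGB_Mg[idx]) / total_agb else 0)
  }))
  out <- out[order(out$h_low, out$stratum), ]
  rownames(out) <- NULL
  out
}
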