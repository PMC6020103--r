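#' Construct a LiDAR point cloud
#'
#' A `point_cloud` is a plain `data.frame` with columns `x`, `y`, `z`
#' (metres, projected CRS; `z` is elevation or, after
#' [normalize_heights()], height above ground) and `number_of_returns`
#' (how many returns the emitting pulse produced). `return_number` is
#' optional. Empty clouds are valid.
#'
#' @param data data.frame with at least `x`, `y`, `z`; if
#'   `number_of_returns` is absent it can be passed separately.
#' @param number_of_returns optional integer vector recycled to the rows of
#'   `data`.
#' @param crs CRS identifier carried as an opaque string (no reprojection
#'   is ever performed).
#' @param normalized logical flag: `z` is height above ground.
#' @return A `point_cloud` object (a classed data.frame).
#' @examples
#' pc <- point_cloud(data.frame(x = 1:3, y = 0, z = c(2, 5, 9),
#'                              number_of_returns = c(1L, 2L, 2L)))
#' n_points(pc)
#' @export
point_cloud <- function(data, number_of_returns = NULL,
                        crs = NA_character_, normalized = FALSE) {
  data <- as.data.frame(data)
  if (!is.null(number_of_returns))
    data$number_of_returns <- number_of_returns
  required <- c("x", "y", "z")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols))
    stop("point_cloud: missing columns: ", paste(missing_cols, collapse = ", "))
  if (!"number_of_returns" %in% names(data))
    data$number_of_returns <- NA_integer_
  if (nrow(data)) {
    if (!all(is.finite(data$x)) || !all(is.finite(data$y)) ||
        !all(is.finite(data$z)))
      stop("point_cloud: coordinates must be finite")
    nr <- data$number_of_returns
    if (any(!is.na(nr) & nr < 1))
      stop("point_cloud: number_of_returns must be >= 1")
    if ("return_number" %in% names(data)) {
      rn <- data$return_number
      bad <- !is.na(rn) & !is.na(nr) & (rn < 1 | rn > nr)
      if (any(bad))
        stop("point_cloud: return_number must lie in [1, number_of_returns]")
    }
  }
  structure(data,
            class = c("point_cloud", "data.frame"),
            crs = crs, normalized = isTRUE(normalized))
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud> %d points | crs: %s | normalized: %s\n",
              nrow(x), attr(x, "crs"), attr(x, "normalized")))
  if (nrow(x)) {
    cat(sprintf("  x: [%.2f, %.2f]  y: [%.2f, %.2f]  z: [%.2f, %.2f]\n",
                min(x$x), max(x$x), min(x$y), max(x$y), min(x$z), max(x$z)))
  }
  invisible(x)
}

#' Number of points in a cloud
#' @param cloud a [point_cloud()].
#' @return Integer count.
#' @export
n_points <- function(cloud) nrow(cloud)

#' Is a cloud height-normalized?
#' @param cloud a [point_cloud()].
#' @return Logical flag set by [normalize_heights()] or at construction.
#' @export
is_normalized <- function(cloud) isTRUE(attr(cloud, "normalized"))

# keep class + attributes through row subsetting
subset_cloud <- function(cloud, keep) {
  out <- as.data.frame(cloud)[keep, , drop = FALSE]
  rownames(out) <- NULL
  point_cloud(out, crs = attr(cloud, "crs"),
              normalized = isTRUE(attr(cloud, "normalized")))
}

#' Normalize point heights to height-above-ground
#'
#' Simple grid-minimum normalizer: within each `cell` x `cell` metre tile
#' the minimum `z` is taken as the local ground elevation and subtracted
#' from every point in the tile. Adequate for synthetic scenes and gently
#' varying terrain; operational ALS archives are usually delivered already
#' ground-normalized, in which case this step is skipped.
#'
#' @param cloud a [point_cloud()].
#' @param cell tile size in metres (default 1).
#' @return A normalized `point_cloud` (flag set); empty in, empty out.
#' @export
normalize_heights <- function(cloud, cell = 1.0) {
  stopifnot(cell > 0)
  if (!nrow(cloud)) {
    attr(cloud, "normalized") <- TRUE
    return(cloud)
  }
  ix <- floor(cloud$x / cell)
  iy <- floor(cloud$y / cell)
  key <- paste(ix, iy)
  zmin <- stats::ave(cloud$z, key, FUN = min)
  out <- as.data.frame(cloud)
  out$z <- cloud$z - zmin
  point_cloud(out, crs = attr(cloud, "crs"), normalized = TRUE)
}

#' Remove ground and low returns
#'
#' Retains points strictly above `z_min`; points with `z <= z_min` are
#' dropped. The 1 m default removes ground and low clutter before crown
#' clustering.
#'
#' @param cloud a height-normalized [point_cloud()].
#' @param z_min height cutoff in metres (default 1).
#' @return Filtered `point_cloud`.
#' @export
filter_low_points <- function(cloud, z_min = 1.0) {
  if (!nrow(cloud)) return(cloud)
  subset_cloud(cloud, cloud$z > z_min)
}

#' Remove single-return points
#'
#' Retains points whose emitting pulse produced more than one return.
#' Hard surfaces (roofs, roads) typically backscatter a single return
#' while vegetation produces several, so this filter removes the majority
#' of buildings before clustering.
#'
#' @param cloud a [point_cloud()] with `number_of_returns` populated.
#' @param field which LAS metafield carries the per-pulse return count.
#'   Datasets occasionally confuse "Number of Returns" with "Return
#'   Number"; the toggle lets the filter run on either.
#' @return Filtered `point_cloud`.
#' @export
filter_single_return_points <- function(cloud,
                                        field = c("number_of_returns",
                                                  "return_number")) {
  field <- match.arg(field)
  if (!nrow(cloud)) return(cloud)
  v <- cloud[[field]]
  if (is.null(v) || anyNA(v))
    stop("filter_single_return_points: field '", field,
         "' is missing or incomplete")
  subset_cloud(cloud, v > 1)
}
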