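#' Maximum crown height
#'
#' `H` is the maximum point height of the crown's member points. ALS
#' pulses often miss the very apex of a tree, so `H` from sparse data is
#' a slight underestimate of true tree height.
#'
#' @param points data.frame with a `z` column (heights above ground, m).
#' @return Maximum height in metres.
#' @export
crown_height <- function(points) {
  if (!nrow(points)) stop("crown_height: empty point set")
  max(points$z)
}

#' Projected crown area
#'
#' Area of the 2D convex hull of the xy projection of *all* crown points.
#' Degenerate sets (fewer than three distinct points, or collinear) have
#' area 0; the downstream minimum-polygon-area cleaning rule removes them.
#'
#' @param points data.frame with `x`, `y` columns (m).
#' @return Area in square metres.
#' @export
crown_area <- function(points) {
  if (!nrow(points)) stop("crown_area: empty point set")
  polygon_area(convex_hull_xy(points$x, points$y))
}

#' Equivalent crown radius
#'
#' Radius of the circle with the crown's projected area:
#' `r = sqrt(Ar / pi)`. Collapsing area to a radius puts crown extent on
#' the same scale as the height-to-radius threshold regressions.
#'
#' @param Ar projected crown area (m^2), non-negative.
#' @return Radius in metres.
#' @export
crown_radius <- function(Ar) {
  if (any(Ar < 0)) stop("crown_radius: negative area")
  sqrt(Ar / pi)
}

#' Build a crown record from member points
#'
#' Computes the 2D convex hull, `H`, `Ar`, `r` and the hull centroid for
#' one detected crown.
#'
#' @param points data.frame with `x`, `y`, `z`.
#' @param id crown identifier.
#' @return A `crown` object (list with `id`, `points`, `n_points`, `H`,
#'   `Ar`, `r`, `hull`, `centroid`).
#' @export
make_crown <- function(points, id = NA_integer_) {
  if (!nrow(points)) stop("make_crown: empty point set")
  hull <- convex_hull_xy(points$x, points$y)
  Ar <- polygon_area(hull)
  centroid <- if (nrow(hull) >= 3) polygon_centroid(hull) else
    c(mean(points$x), mean(points$y))
  structure(list(id = id,
                 points = as.data.frame(points),
                 n_points = nrow(points),
                 H = max(points$z),
                 Ar = Ar,
                 r = sqrt(Ar / pi),
                 hull = hull,
                 centroid = centroid,
                 V = NA_real_, AGB = NA_real_, agb_sd = NA_real_),
            class = "crown")
}

#' @export
print.crown <- function(x, ...) {
  cat(sprintf("<crown %s> n=%d H=%.2f m Ar=%.1f m2 r=%.2f m\n",
              x$id, x$n_points, x$H, x$Ar, x$r))
  invisible(x)
}

#' Bundle crowns into a crown set
#'
#' @param crowns list of [make_crown()] objects.
#' @param params the [segmentation_params()] provenance (optional).
#' @return A `crown_set`.
#' @export
crown_set <- function(crowns = list(), params = NULL) {
  ids <- vapply(crowns, function(c) c$id, numeric(1))
  if (anyNA(ids) || any(duplicated(ids)))
    for (i in seq_along(crowns)) crowns[[i]]$id <- i
  structure(list(crowns = crowns, params = params), class = "crown_set")
}

#' @export
length.crown_set <- function(x) length(x$crowns)

#' @export
print.crown_set <- function(x, ...) {
  cat(sprintf("<crown_set> %d crowns\n", length(x$crowns)))
  invisible(x)
}

#' Crown metrics table
#'
#' One row per crown: id, centroid, `H`, `Ar`, `r`, point count, and
#' volume/AGB columns when attributed.
#'
#' @param x a `crown_set`.
#' @param ... unused.
#' @return data.frame of per-crown metrics.
#' @export
as.data.frame.crown_set <- function(x, ...) {
  if (!length(x$crowns))
    return(data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                      H_m = numeric(0), Ar_m2 = numeric(0), r_m = numeric(0),
                      n_points = integer(0), V_m3 = numeric(0),
                      AGB_Mg = numeric(0), agb_sd_Mg = numeric(0)))
  do.call(rbind, lapply(x$crowns, function(cr) {
    data.frame(id = cr$id, x = cr$centroid[1], y = cr$centroid[2],
               H_m = cr$H, Ar_m2 = cr$Ar, r_m = cr$r,
               n_points = cr$n_points, V_m3 = cr$V, AGB_Mg = cr$AGB,
               agb_sd_Mg = cr$agb_sd)
  }))
}
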