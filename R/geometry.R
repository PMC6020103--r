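# Small computational-geometry kernel used by crown metrics and cleaning.
# Hulls are counter-clockwise, open (first vertex not repeated).

convex_hull_xy <- function(x, y) {
  pts <- unique(cbind(x, y))
  if (nrow(pts) < 3) return(pts)
  idx <- grDevices::chull(pts[, 1], pts[, 2])
  pts[rev(idx), , drop = FALSE]   # chull is clockwise; reverse to ccw
}

# shoelace; vertices ccw, open ring
polygon_area <- function(poly) {
  n <- nrow(poly)
  if (is.null(n) || n < 3) return(0)
  x <- poly[, 1]; y <- poly[, 2]
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

polygon_centroid <- function(poly) {
  n <- nrow(poly)
  if (n < 3) return(colMeans(poly))
  x <- poly[, 1]; y <- poly[, 2]
  j <- c(2:n, 1)
  cross <- x * y[j] - x[j] * y
  a <- sum(cross) / 2
  if (abs(a) < 1e-12) return(colMeans(poly))
  c(sum((x + x[j]) * cross) / (6 * a),
    sum((y + y[j]) * cross) / (6 * a))
}

# Sutherland-Hodgman clip of convex `subject` by convex `clip` (both ccw)
convex_poly_intersection <- function(subject, clip) {
  if (nrow(subject) < 3 || nrow(clip) < 3) return(subject[0, , drop = FALSE])
  out <- subject
  nc <- nrow(clip)
  for (i in seq_len(nc)) {
    if (nrow(out) == 0) break
    a <- clip[i, ]; b <- clip[if (i == nc) 1 else i + 1, ]
    ex <- b[1] - a[1]; ey <- b[2] - a[2]
    side <- ex * (out[, 2] - a[2]) - ey * (out[, 1] - a[1])  # >=0 inside (ccw)
    n <- nrow(out)
    nxt <- c(2:n, 1)
    newpts <- list(); k <- 0
    for (j in seq_len(n)) {
      cur_in <- side[j] >= -1e-12
      nj <- nxt[j]
      nxt_in <- side[nj] >= -1e-12
      if (cur_in) { k <- k + 1; newpts[[k]] <- out[j, ] }
      if (cur_in != nxt_in) {
        t <- side[j] / (side[j] - side[nj])
        k <- k + 1
        newpts[[k]] <- out[j, ] + t * (out[nj, ] - out[j, ])
      }
    }
    out <- if (k) do.call(rbind, newpts) else out[0, , drop = FALSE]
  }
  out
}

# intersection-over-union of two convex hulls
hull_iou <- function(h1, h2) {
  a1 <- polygon_area(h1); a2 <- polygon_area(h2)
  if (a1 <= 0 || a2 <= 0) return(0)
  inter <- polygon_area(convex_poly_intersection(h1, h2))
  inter / (a1 + a2 - inter)
}

# ray-casting point-in-polygon (general polygon, open ring)
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  if (is.null(n) || n < 3) return(rep(FALSE, length(px)))
  inside <- rep(FALSE, length(px))
  xs <- poly[, 1]; ys <- poly[, 2]
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((ys[i] > py) != (ys[j] > py)) &
      (px < (xs[j] - xs[i]) * (py - ys[i]) / (ys[j] - ys[i]) + xs[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}
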