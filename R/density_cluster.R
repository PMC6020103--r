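#' Density-based clustering of a filtered point cloud
#'
#' First stage of the individual tree detection: DBSCAN in 3D Euclidean
#' space acts as a low-pass filter that groups returns into discrete tree
#' crowns and merged canopies while discarding sparse clutter (building
#' edges, aerials, cranes) as noise. A point is a core point when at
#' least `min_samples` points (itself included) lie within `eps`;
#' clusters are the density-connected components of core points plus
#' their border points.
#'
#' The `eps = 3.5` m / `min_samples = 20` defaults suit ~2 pulses per
#' square metre ALS: the eps footprint (~38 m^2) is small enough to keep
#' individual street trees distinct while bridging within-crown gaps.
#'
#' @param cloud a filtered [point_cloud()] (multi-return, `z > 1` m).
#' @param eps neighbourhood radius in metres.
#' @param min_samples minimum neighbourhood size for a core point.
#' @return list with `clusters` (list of [make_crown()] objects, each
#'   with at least `min_samples` points) and `noise` (a `point_cloud` of
#'   unclustered points).
#' @export
cluster_density <- function(cloud, eps = 3.5, min_samples = 20) {
  n <- nrow(cloud)
  if (!n) return(list(clusters = list(), noise = cloud))
  xyz <- cbind(cloud$x, cloud$y, cloud$z)

  # grid spatial index: cell size = eps, so all eps-neighbours of a point
  # lie in its own or the 26 adjacent cells; +1 shift keeps neighbour keys
  # collision-free at the grid edge
  mins <- c(min(xyz[, 1]), min(xyz[, 2]), min(xyz[, 3]))
  cx <- floor((xyz[, 1] - mins[1]) / eps) + 1L
  cy <- floor((xyz[, 2] - mins[2]) / eps) + 1L
  cz <- floor((xyz[, 3] - mins[3]) / eps) + 1L
  sx <- max(cx) + 2L; sy <- max(cy) + 2L
  key <- cx + sx * (cy + sy * cz)
  cell_of <- match(key, unique(key))
  members <- split(seq_len(n), cell_of)
  ukey <- key[!duplicated(key)]
  ucx <- cx[!duplicated(key)]; ucy <- cy[!duplicated(key)]
  ucz <- cz[!duplicated(key)]

  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  ncell <- length(ukey)
  cand <- vector("list", ncell)   # candidate point ids per cell, lazily built
  cell_candidates <- function(ci) {
    if (!is.null(cand[[ci]])) return(cand[[ci]])
    nk <- (ucx[ci] + offs[, 1]) +
      sx * ((ucy[ci] + offs[, 2]) + sy * (ucz[ci] + offs[, 3]))
    hit <- match(nk, ukey)
    ids <- unlist(members[hit[!is.na(hit)]], use.names = FALSE)
    cand[[ci]] <<- ids
    ids
  }
  eps2 <- eps^2
  region_query <- function(i) {
    ids <- cell_candidates(cell_of[i])
    d2 <- (xyz[ids, 1] - xyz[i, 1])^2 + (xyz[ids, 2] - xyz[i, 2])^2 +
      (xyz[ids, 3] - xyz[i, 3])^2
    ids[d2 <= eps2]
  }

  labels <- integer(n)          # 0 = unvisited, -1 = noise, >0 cluster id
  visited <- logical(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (visited[i]) next
    visited[i] <- TRUE
    nb <- region_query(i)
    if (length(nb) < min_samples) {
      labels[i] <- -1L
      next
    }
    cid <- cid + 1L
    labels[i] <- cid
    queue <- nb
    qpos <- 1L
    queued <- logical(n); queued[queue] <- TRUE
    while (qpos <= length(queue)) {
      q <- queue[qpos]; qpos <- qpos + 1L
      if (labels[q] == -1L) labels[q] <- cid      # border point claimed
      if (visited[q]) next
      visited[q] <- TRUE
      labels[q] <- cid
      nb2 <- region_query(q)
      if (length(nb2) >= min_samples) {
        fresh <- nb2[!queued[nb2]]
        if (length(fresh)) {
          queue <- c(queue, fresh)
          queued[fresh] <- TRUE
        }
      }
    }
  }

  # a cluster can end up below min_samples when its border points were
  # claimed first by an adjacent cluster; such fragments are dissolved
  # into noise so every returned cluster honours |P| >= min_samples
  sizes <- tabulate(labels[labels > 0L], nbins = cid)
  for (k in which(sizes < min_samples)) labels[labels == k] <- -1L
  kept <- which(sizes >= min_samples)
  clusters <- lapply(seq_along(kept), function(i) {
    make_crown(as.data.frame(cloud)[labels == kept[i], , drop = FALSE],
               id = i)
  })
  list(clusters = clusters,
       noise = subset_cloud(cloud, labels == -1L))
}
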