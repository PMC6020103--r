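#' Segmentation parameters
#'
#' Bundles the knobs of the two-stage individual tree detection. The
#' density stage uses `eps` / `min_samples`; the splitting stage needs
#' two height-to-radius threshold models fitted from TLS crowns (see
#' [fit_threshold_model()]): `split_model` (upper 95% prediction-bound
#' line; a crown wider than this bound for its height is a merged canopy)
#' and `bt_model` (mean regression line; its prediction is the radius
#' threshold used when carving a canopy into subclusters).
#'
#' @param eps density-stage neighbourhood radius (m).
#' @param min_samples density-stage minimum neighbourhood size.
#' @param split_model `threshold_model` of kind `"split_95pi"`.
#' @param bt_model `threshold_model` of kind `"bt_mean"`.
#' @param min_subcluster_points subclusters smaller than this are
#'   discarded as noise during splitting.
#' @param max_iterations cap on splitting rounds; hitting it flags the
#'   affected crowns as non-converged rather than looping forever.
#' @param min_polygon_area crowns with hull area below this (m^2) are
#'   removed in cleaning; they tend to coincide with building edges.
#' @param max_crown_height crowns taller than this (m) are removed as
#'   implausible (cranes, aerials).
#' @param duplicate_iou hull intersection-over-union at or above which two
#'   crowns are treated as duplicates (usually vertically offset copies);
#'   the one with more points is kept.
#' @param duplicate_containment fraction of the smaller hull covered by
#'   the larger at or above which the pair is also treated as duplicate.
#'   Vertically offset duplicates are typically a lower slice of a large
#'   crown: their hull sits inside the main hull but is much smaller, so
#'   IoU alone cannot catch them.
#' @return A `segmentation_params` list.
#' @export
segmentation_params <- function(eps = 3.5, min_samples = 20,
                                split_model = NULL, bt_model = NULL,
                                min_subcluster_points = 5,
                                max_iterations = 20,
                                min_polygon_area = 10,
                                max_crown_height = 45,
                                duplicate_iou = 0.9,
                                duplicate_containment = 0.75) {
  stopifnot(eps > 0, min_samples >= 1, min_polygon_area >= 0,
            duplicate_iou > 0, duplicate_iou <= 1, max_iterations >= 1)
  stopifnot(duplicate_containment > 0, duplicate_containment <= 1)
  structure(list(eps = eps, min_samples = min_samples,
                 split_model = split_model, bt_model = bt_model,
                 min_subcluster_points = min_subcluster_points,
                 max_iterations = max_iterations,
                 min_polygon_area = min_polygon_area,
                 max_crown_height = max_crown_height,
                 duplicate_iou = duplicate_iou,
                 duplicate_containment = duplicate_containment),
            class = "segmentation_params")
}

#' Does a cluster need splitting?
#'
#' A cluster is a merged canopy when its equivalent radius exceeds the
#' upper 95% prediction bound for a single crown of its height:
#' `beta + alpha * H < r` (strict). Equality does not trigger a split.
#'
#' @param cluster a [make_crown()] object with `H` and `r` computed.
#' @param split_model `threshold_model` with `alpha`, `beta`.
#' @return logical.
#' @export
needs_split <- function(cluster, split_model) {
  (split_model$beta + split_model$alpha * cluster$H) < cluster$r
}

# Radius-threshold clustering on xy, two-run protocol. Run 1 finds the
# cluster count using the radius threshold alone: the count k is
# increased from 1 until a k-partition exists in which every
# subcluster's equivalent radius (from its convex-hull area) is within
# `threshold` -- a canopy of m crowns of the expected radius first
# satisfies the bound at k = m. Each candidate partition is built by
# deterministic farthest-point seeding followed by Lloyd iterations.
# Run 2 keeps the count fixed at run 1's result and polishes the
# assignment (the final Lloyd pass at the accepted k). If no k up to
# the cap satisfies the bound, the best partition found is returned.
threshold_cluster_xy <- function(xy, threshold, max_lloyd = 25) {
  n <- nrow(xy)
  if (n == 0) return(integer(0))

  eq_radius <- function(idx) {
    sqrt(polygon_area(convex_hull_xy(xy[idx, 1], xy[idx, 2])) / pi)
  }
  assign_nearest <- function(cent) {
    d2 <- outer(xy[, 1], cent[, 1], "-")^2 + outer(xy[, 2], cent[, 2], "-")^2
    max.col(-d2, ties.method = "first")
  }
  cluster_k <- function(k) {
    # farthest-point seeding from the centroid outwards
    cx <- mean(xy[, 1]); cy <- mean(xy[, 2])
    seeds <- integer(k)
    d2 <- (xy[, 1] - cx)^2 + (xy[, 2] - cy)^2
    seeds[1] <- which.max(d2)
    if (k > 1) {
      dmin <- (xy[, 1] - xy[seeds[1], 1])^2 + (xy[, 2] - xy[seeds[1], 2])^2
      for (j in 2:k) {
        seeds[j] <- which.max(dmin)
        dmin <- pmin(dmin, (xy[, 1] - xy[seeds[j], 1])^2 +
                       (xy[, 2] - xy[seeds[j], 2])^2)
      }
    }
    cent <- xy[seeds, , drop = FALSE]
    lab <- assign_nearest(cent)
    for (it in seq_len(max_lloyd)) {
      for (j in seq_len(k)) {
        sel <- lab == j
        if (any(sel)) cent[j, ] <- c(mean(xy[sel, 1]), mean(xy[sel, 2]))
      }
      newlab <- assign_nearest(cent)
      if (all(newlab == lab)) break
      lab <- newlab
    }
    match(lab, sort(unique(lab)))
  }

  whole_r <- eq_radius(seq_len(n))
  if (whole_r <= threshold) return(rep(1L, n))
  kmax <- max(2L, min(n, ceiling(3 * (whole_r / threshold)^2) + 3L))
  best_lab <- rep(1L, n)
  best_excess <- whole_r - threshold
  for (k in 2:kmax) {
    lab <- cluster_k(k)
    radii <- vapply(split(seq_len(n), lab), eq_radius, numeric(1))
    excess <- max(radii) - threshold
    if (excess <= 0) return(lab)
    if (excess < best_excess) {
      best_excess <- excess
      best_lab <- lab
    }
  }
  best_lab
}

#' Split a merged canopy into individual crowns
#'
#' Iterative loop: for a cluster violating the single-crown bound, the
#' radius threshold `B_t = beta + alpha * H` is computed from the mean
#' height-to-radius model, the cluster's points are re-clustered in xy by
#' the two-run radius-threshold procedure, per-subcluster metrics are
#' recomputed, and any subcluster that still violates the bound is split
#' again. Subclusters smaller than `min_subcluster_points` are discarded.
#' The loop stops when no subcluster violates the bound or after
#' `max_iterations` rounds (remaining clusters are returned carrying a
#' `warn_nonconverged` flag).
#'
#' Splitting operates on xy only: `B_t` is a crown *radius*, a horizontal
#' extent; `H` is recomputed per subcluster from its member points.
#'
#' @param cluster a [make_crown()] object.
#' @param bt_model mean-line `threshold_model` (kind `"bt_mean"`).
#' @param split_model bound-line `threshold_model` (kind `"split_95pi"`).
#' @param params [segmentation_params()].
#' @return list of crowns (the input unchanged, as a singleton, when no
#'   split is needed).
#' @export
split_canopy <- function(cluster, bt_model, split_model, params) {
  if (!needs_split(cluster, split_model)) return(list(cluster))
  done <- list()
  active <- list(cluster)
  iter <- 0
  while (length(active) && iter < params$max_iterations) {
    iter <- iter + 1
    nxt <- list()
    for (cl in active) {
      bt <- bt_model$beta + bt_model$alpha * cl$H
      lab <- threshold_cluster_xy(cbind(cl$points$x, cl$points$y), bt)
      parts <- split(seq_len(nrow(cl$points)), lab)
      if (length(parts) <= 1) {
        # cannot be divided further although the bound is still violated
        cl$warn_nonconverged <- TRUE
        done[[length(done) + 1]] <- cl
        next
      }
      for (idx in parts) {
        if (length(idx) < params$min_subcluster_points) next
        sub <- make_crown(cl$points[idx, , drop = FALSE])
        if (needs_split(sub, split_model)) {
          nxt[[length(nxt) + 1]] <- sub
        } else {
          done[[length(done) + 1]] <- sub
        }
      }
    }
    active <- nxt
  }
  for (cl in active) {            # max_iterations reached
    cl$warn_nonconverged <- TRUE
    done[[length(done) + 1]] <- cl
  }
  done
}

#' Segment individual trees from an ALS point cloud
#'
#' Full individual tree detection workflow on a height-normalized cloud:
#' single-return points are removed (buildings and other hard surfaces),
#' points at `z <= 1` m are removed (ground and low clutter), the
#' remainder is density-clustered into crowns and canopies, canopies
#' wider than the single-crown prediction bound are split, and the crown
#' set is cleaned (minimum polygon area, implausible heights, duplicate
#' removal).
#'
#' @param cloud a height-normalized [point_cloud()].
#' @param params [segmentation_params()] with both threshold models set.
#' @return A [crown_set()] with parameter provenance attached.
#' @export
segment_trees <- function(cloud, params) {
  if (is.null(params$split_model) || is.null(params$bt_model))
    stop("segment_trees: params must carry split_model and bt_model")
  filt <- filter_single_return_points(cloud)
  filt <- filter_low_points(filt, z_min = 1.0)
  dc <- cluster_density(filt, eps = params$eps,
                        min_samples = params$min_samples)
  crowns <- list()
  for (cl in dc$clusters) {
    for (cr in split_canopy(cl, params$bt_model, params$split_model, params))
      crowns[[length(crowns) + 1]] <- cr
  }
  for (i in seq_along(crowns)) crowns[[i]]$id <- i
  clean_crowns(crown_set(crowns, params = params), params)
}

#' Clean a crown set
#'
#' Removes crowns with hull area below `min_polygon_area` (these tend to
#' coincide with building edges), crowns taller than `max_crown_height`
#' (cranes, aerials and other false positives), and duplicate crowns:
#' among pairs whose hull intersection-over-union is at least
#' `duplicate_iou`, *or* whose smaller hull is covered by the larger one
#' to at least `duplicate_containment` (the vertically-offset-duplicate
#' signature), the crown with more points is kept (ties go to the taller
#' crown).
#'
#' @param crowns a [crown_set()].
#' @param params [segmentation_params()].
#' @return Cleaned [crown_set()].
#' @export
clean_crowns <- function(crowns, params) {
  keep <- vapply(crowns$crowns, function(cr) {
    cr$Ar >= params$min_polygon_area && cr$H <= params$max_crown_height
  }, logical(1))
  cl <- crowns$crowns[keep]
  if (length(cl) > 1) {
    drop <- rep(FALSE, length(cl))
    # only test pairs with overlapping bounding boxes
    bb <- t(vapply(cl, function(cr)
      c(range(cr$hull[, 1]), range(cr$hull[, 2])), numeric(4)))
    for (i in seq_along(cl)) {
      if (drop[i]) next
      for (j in seq_along(cl)) {
        if (j <= i || drop[j]) next
        if (bb[i, 2] < bb[j, 1] || bb[j, 2] < bb[i, 1] ||
            bb[i, 4] < bb[j, 3] || bb[j, 4] < bb[i, 3]) next
        a_i <- polygon_area(cl[[i]]$hull)
        a_j <- polygon_area(cl[[j]]$hull)
        inter <- polygon_area(convex_poly_intersection(cl[[i]]$hull,
                                                       cl[[j]]$hull))
        iou <- if (a_i > 0 && a_j > 0) inter / (a_i + a_j - inter) else 0
        contain <- if (min(a_i, a_j) > 0) inter / min(a_i, a_j) else 0
        if (iou >= params$duplicate_iou ||
            contain >= params$duplicate_containment) {
          loser <- if (cl[[i]]$n_points != cl[[j]]$n_points) {
            if (cl[[i]]$n_points < cl[[j]]$n_points) i else j
          } else {
            if (cl[[i]]$H < cl[[j]]$H) i else j
          }
          drop[loser] <- TRUE
          if (loser == i) break
        }
      }
    }
    cl <- cl[!drop]
  }
  for (i in seq_along(cl)) cl[[i]]$id <- i
  crown_set(cl, params = params)
}
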