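#' Allometric parameters for the synthetic tree population
#'
#' The generator draws tree heights uniformly over `h_range` and couples
#' crown radius and volume to height through the same model families the
#' estimation side fits: a linear height-to-radius law with Gaussian
#' scatter, `r = beta + alpha*H + N(0, radius_sd)`, and a volume law
#' `V = k_ar*Ar + k_exp*(a*b^H)` with multiplicative lognormal noise of
#' coefficient of variation `noise_cv`. Defaults give a population that
#' spans street-tree to mature-park-tree structure (heights 5-35 m,
#' crown areas up to several hundred m^2, volumes up to ~35 m^3); they
#' are synthetic calibration choices, not measurements.
#'
#' @param alpha,beta radius-law slope (m/m) and intercept (m).
#' @param radius_sd Gaussian scatter of crown radius about the law (m).
#' @param k_ar,k_exp,a,b volume-law coefficients; `k_exp` defaults to 1
#'   so the exponential scale `a` is the identified quantity.
#' @param noise_cv coefficient of variation of multiplicative volume
#'   noise.
#' @param h_range height range (m), drawn uniformly.
#' @param crown_base_frac crown base height as a fraction of `H`.
#' @return list of generator parameters.
#' @export
tree_population_params <- function(alpha = 0.25, beta = 0.5,
                                   radius_sd = 0.75,
                                   k_ar = 0.04, k_exp = 1,
                                   a = 0.05, b = 1.2,
                                   noise_cv = 0.10,
                                   h_range = c(5, 35),
                                   crown_base_frac = 0.25) {
  stopifnot(alpha > 0 || beta > 0, radius_sd >= 0, noise_cv >= 0,
            length(h_range) == 2, h_range[1] > 0,
            h_range[2] >= h_range[1],
            crown_base_frac >= 0, crown_base_frac < 1,
            a > 0, b > 0)
  list(alpha = alpha, beta = beta, radius_sd = radius_sd,
       k_ar = k_ar, k_exp = k_exp, a = a, b = b, noise_cv = noise_cv,
       h_range = h_range, crown_base_frac = crown_base_frac)
}

# species/density lookup bundled as a synthetic fixture
synthetic_density_table <- function() {
  path <- system.file("extdata", "wood_density_synthetic.csv",
                      package = "urbancanopy")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Generate a synthetic tree population with known truth
#'
#' @param n number of trees.
#' @param params [tree_population_params()].
#' @param seed RNG seed; identical seeds give identical populations.
#' @return data.frame of tree specs: `id`, `x`, `y` (0 until placed),
#'   `H`, `crown_radius`, `crown_base`, `shape`, `species`,
#'   `wood_density`, `Ar_true`, `V_true`, `AGB_true`.
#' @export
generate_tree_population <- function(n, params = tree_population_params(),
                                     seed = 1) {
  stopifnot(n >= 0)
  dens <- synthetic_density_table()
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  if (n == 0)
    return(data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                      H = numeric(0), crown_radius = numeric(0),
                      crown_base = numeric(0), shape = character(0),
                      species = character(0), wood_density = numeric(0),
                      Ar_true = numeric(0), V_true = numeric(0),
                      AGB_true = numeric(0)))
  H <- stats::runif(n, params$h_range[1], params$h_range[2])
  r <- params$beta + params$alpha * H +
    stats::rnorm(n, 0, params$radius_sd)
  r <- pmax(r, 0.5)
  Ar <- pi * r^2
  V <- params$k_ar * Ar + params$k_exp * params$a * params$b^H
  if (params$noise_cv > 0)
    V <- V * exp(stats::rnorm(n, 0, params$noise_cv))
  sp <- dens$species[sample.int(nrow(dens), n, replace = TRUE)]
  rho <- dens$density_kg_m3[match(sp, dens$species)]
  data.frame(id = seq_len(n), x = 0, y = 0,
             H = H, crown_radius = r,
             crown_base = params$crown_base_frac * H,
             shape = "ellipsoid",
             species = sp, wood_density = rho,
             Ar_true = Ar, V_true = V,
             AGB_true = V * rho / 1000)
}

#' Place trees so crowns cannot merge
#'
#' Dart-throwing placement enforcing, for every pair, a stem spacing of
#' at least `max(min_spacing, r_i + r_j + 2*eps)`: crowns neither touch
#' nor come within the density-clustering radius of each other, the
#' geometric condition "well separated" presupposes.
#'
#' @param trees population from [generate_tree_population()].
#' @param min_spacing floor on pairwise stem spacing (m).
#' @param eps density-stage radius the spacing must clear (m).
#' @param seed RNG seed.
#' @return The population with `x`, `y` filled in; the bounding extent
#'   (with a crown-radius margin) is attached as attribute `extent`.
#' @export
place_trees_separated <- function(trees, min_spacing = 12, eps = 3.5,
                                  seed = 1) {
  n <- nrow(trees)
  if (!n) return(trees)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed + 1000L)
  # size the arena for the required packing
  need <- max(min_spacing, 2 * max(trees$crown_radius) + 2 * eps)
  side <- ceiling(sqrt(n) * need * 1.8)
  xs <- numeric(n); ys <- numeric(n)
  placed <- 0
  tries <- 0
  while (placed < n) {
    tries <- tries + 1
    if (tries > 20000 * n) stop("place_trees_separated: packing failed")
    px <- stats::runif(1, 0, side); py <- stats::runif(1, 0, side)
    ok <- TRUE
    if (placed > 0) {
      req <- pmax(min_spacing,
                  trees$crown_radius[seq_len(placed)] +
                    trees$crown_radius[placed + 1] + 2 * eps)
      d <- sqrt((xs[seq_len(placed)] - px)^2 + (ys[seq_len(placed)] - py)^2)
      ok <- all(d >= req)
    }
    if (ok) {
      placed <- placed + 1
      xs[placed] <- px; ys[placed] <- py
    }
  }
  trees$x <- xs; trees$y <- ys
  margin <- max(trees$crown_radius) + 2
  attr(trees, "extent") <- c(min(xs) - margin, min(ys) - margin,
                             max(xs) + margin, max(ys) + margin)
  trees
}

#' Scene specification
#'
#' @param trees placed tree population (with `x`, `y`).
#' @param extent `c(xmin, ymin, xmax, ymax)`; taken from the placement
#'   attribute when NULL.
#' @param buildings NULL or data.frame `xmin, xmax, ymin, ymax, height`.
#' @param pulse_density outgoing pulses per m^2 (default 2).
#' @param veg_multireturn_prob probability a vegetation pulse yields
#'   more than one return.
#' @param edge_noise_prob fraction of building points mislabelled as
#'   multi-return (emulating hard-surface edge artefacts).
#' @param seed RNG seed for the rendering.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(trees, extent = NULL, buildings = NULL,
                       pulse_density = 2, veg_multireturn_prob = 1.0,
                       edge_noise_prob = 0.02, seed = 1) {
  stopifnot(pulse_density > 0,
            veg_multireturn_prob >= 0, veg_multireturn_prob <= 1,
            edge_noise_prob >= 0, edge_noise_prob <= 1)
  if (is.null(extent)) extent <- attr(trees, "extent")
  if (is.null(extent)) {
    if (nrow(trees)) {
      m <- max(trees$crown_radius) + 2
      extent <- c(min(trees$x) - m, min(trees$y) - m,
                  max(trees$x) + m, max(trees$y) + m)
    } else extent <- c(0, 0, 100, 100)
  }
  structure(list(trees = trees, extent = extent, buildings = buildings,
                 pulse_density = pulse_density,
                 veg_multireturn_prob = veg_multireturn_prob,
                 edge_noise_prob = edge_noise_prob, seed = seed),
            class = "scene_spec")
}

# sample one tree's returns: first returns on the upper crown envelope,
# second returns inside the crown volume (surface-biased capture; the
# apex is hit only in the zero-measure centre, so max z < H as in real
# ALS)
sample_tree_points <- function(tr, pulse_density, multi_prob) {
  zc <- (tr$crown_base + tr$H) / 2
  c_semi <- (tr$H - tr$crown_base) / 2
  npulse <- stats::rpois(1, pulse_density * pi * tr$crown_radius^2)
  if (npulse == 0)
    return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      number_of_returns = integer(0)))
  rho <- tr$crown_radius * sqrt(stats::runif(npulse))
  th <- stats::runif(npulse, 0, 2 * pi)
  px <- tr$x + rho * cos(th); py <- tr$y + rho * sin(th)
  rel <- pmin(rho / tr$crown_radius, 1)
  top <- if (tr$shape == "cone") {
    tr$crown_base + (tr$H - tr$crown_base) * (1 - rel)
  } else {
    zc + c_semi * sqrt(pmax(0, 1 - rel^2))
  }
  multi <- stats::runif(npulse) < multi_prob
  nr <- ifelse(multi, 2L, 1L)
  first <- data.frame(x = px, y = py, z = top, number_of_returns = nr)
  if (any(multi)) {
    bot <- if (tr$shape == "cone") rep(tr$crown_base, npulse) else
      zc - c_semi * sqrt(pmax(0, 1 - rel^2))
    zin <- stats::runif(sum(multi), bot[multi], top[multi])
    second <- data.frame(x = px[multi], y = py[multi], z = zin,
                         number_of_returns = 2L)
    first <- rbind(first, second)
  }
  first
}

#' Render a synthetic ALS capture of a scene
#'
#' Emulates a low pulse-density airborne capture: tree crowns are
#' sampled on/within parametric crown envelopes (vegetation pulses
#' produce multiple returns with `veg_multireturn_prob`), building roofs
#' emit single-return points except for an `edge_noise_prob` fraction,
#' and open ground returns sit at `z ~ 0`. Per-point truth labels
#' (`ground`, `building`, or the tree id) are returned alongside.
#'
#' @param spec a [scene_spec()].
#' @return list with `cloud` (a [point_cloud()], normalized), `truth`
#'   (list: `labels` per point, `trees` = per-tree truth table with
#'   `H`, `Ar_true`, `V_true`, `AGB_true`), and bookkeeping counts
#'   `n_ground`, `n_building`, `n_veg`.
#' @export
render_scene <- function(spec) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(spec$seed)
  ext <- spec$extent
  parts <- list(); labels <- list()

  area <- (ext[3] - ext[1]) * (ext[4] - ext[2])
  ng <- stats::rpois(1, spec$pulse_density * area)
  if (ng > 0) {
    parts[[length(parts) + 1]] <- data.frame(
      x = stats::runif(ng, ext[1], ext[3]),
      y = stats::runif(ng, ext[2], ext[4]),
      z = abs(stats::rnorm(ng, 0, 0.03)),
      number_of_returns = 1L)
    labels[[length(labels) + 1]] <- rep("ground", ng)
  }
  n_ground <- ng

  n_building <- 0
  if (!is.null(spec$buildings) && nrow(spec$buildings)) {
    for (i in seq_len(nrow(spec$buildings))) {
      b <- spec$buildings[i, ]
      nb <- stats::rpois(1, spec$pulse_density *
                           (b$xmax - b$xmin) * (b$ymax - b$ymin))
      if (nb == 0) next
      nr <- ifelse(stats::runif(nb) < spec$edge_noise_prob, 2L, 1L)
      parts[[length(parts) + 1]] <- data.frame(
        x = stats::runif(nb, b$xmin, b$xmax),
        y = stats::runif(nb, b$ymin, b$ymax),
        z = b$height + abs(stats::rnorm(nb, 0, 0.05)),
        number_of_returns = nr)
      labels[[length(labels) + 1]] <- rep("building", nb)
      n_building <- n_building + nb
    }
  }

  n_veg <- 0
  if (nrow(spec$trees)) {
    for (i in seq_len(nrow(spec$trees))) {
      tp <- sample_tree_points(spec$trees[i, ], spec$pulse_density,
                               spec$veg_multireturn_prob)
      if (!nrow(tp)) next
      parts[[length(parts) + 1]] <- tp
      labels[[length(labels) + 1]] <- rep(as.character(spec$trees$id[i]),
                                          nrow(tp))
      n_veg <- n_veg + nrow(tp)
    }
  }

  df <- if (length(parts)) do.call(rbind, parts) else
    data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
               number_of_returns = integer(0))
  cloud <- point_cloud(df, normalized = TRUE)
  list(cloud = cloud,
       truth = list(labels = unlist(labels), trees = spec$trees),
       n_ground = n_ground, n_building = n_building, n_veg = n_veg)
}

#' Synthesize a QSM tree table from a population
#'
#' Emulates the TLS side: each tree receives 10 stochastic
#' reconstruction volumes drawn from `Gaussian(V_true, recon_cv *
#' V_true)`; `Ar` is the exact crown disc area, `H` is copied, and
#' `dbh` is a monotone power function of volume
#' (`dbh = 0.12 * V^0.4`, a plausible urban-tree taper).
#'
#' @param trees population from [generate_tree_population()].
#' @param recon_cv reconstruction coefficient of variation (default
#'   0.05, i.e. a 95% CI of ~3.6% of volume — leaf-off-quality TLS).
#' @param seed RNG seed.
#' @return A [qsm_table()].
#' @export
make_qsm_table <- function(trees, recon_cv = 0.05, seed = 1) {
  stopifnot(recon_cv >= 0)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed + 2000L)
  n <- nrow(trees)
  vols <- matrix(NA_real_, nrow = n, ncol = 10)
  for (j in 1:10)
    vols[, j] <- if (recon_cv > 0)
      pmax(1e-6, stats::rnorm(n, trees$V_true, recon_cv * trees$V_true))
    else trees$V_true
  df <- data.frame(id = trees$id, site = "synthetic",
                   dbh_m = 0.12 * trees$V_true^0.4,
                   h_m = trees$H, ar_m2 = pi * trees$crown_radius^2)
  colnames(vols) <- paste0("vol_", 1:10)
  df <- cbind(df, as.data.frame(vols))
  df$species <- trees$species
  df$wood_density <- trees$wood_density
  qsm_table(df)
}

#' Score detected crowns against scene truth
#'
#' Greedy one-to-one matching of detected crown centroids to true stem
#' positions: candidate pairs within `max_dist` are matched closest
#' first, each stem and each detection used at most once.
#'
#' @param truth truth table (the `trees` element of [render_scene()]'s
#'   truth, or any data.frame with `x`, `y`, `H`, `Ar_true`).
#' @param detected a [crown_set()].
#' @param max_dist matching radius (m), default 2.
#' @return list: `precision`, `recall`, `f1`, `area_ratio` (sum detected
#'   Ar / sum true Ar), `height_bias` (mean detected H - true H over
#'   matches), `n_matched`, `undefined` flag (TRUE when no detections;
#'   precision reported as 0).
#' @export
match_crowns <- function(truth, detected, max_dist = 2) {
  nt <- nrow(truth)
  tab <- as.data.frame(detected)
  nd <- nrow(tab)
  if (nd == 0)
    return(list(precision = 0, recall = 0, f1 = 0,
                area_ratio = 0, height_bias = NA_real_,
                n_matched = 0L, undefined = TRUE))
  dx <- outer(tab$x, truth$x, "-")
  dy <- outer(tab$y, truth$y, "-")
  d <- sqrt(dx^2 + dy^2)
  cand <- which(d <= max_dist, arr.ind = TRUE)
  matched_d <- logical(nd); matched_t <- logical(nt)
  pairs <- list()
  if (nrow(cand)) {
    ord <- order(d[cand])
    for (k in ord) {
      i <- cand[k, 1]; j <- cand[k, 2]
      if (matched_d[i] || matched_t[j]) next
      matched_d[i] <- TRUE; matched_t[j] <- TRUE
      pairs[[length(pairs) + 1]] <- c(i, j)
    }
  }
  nm <- length(pairs)
  hb <- if (nm) {
    mean(vapply(pairs, function(p) tab$H_m[p[1]] - truth$H[p[2]],
                numeric(1)))
  } else NA_real_
  precision <- nm / nd
  recall <- if (nt) nm / nt else NA_real_
  f1 <- if (nm) 2 * precision * recall / (precision + recall) else 0
  list(precision = precision, recall = recall, f1 = f1,
       area_ratio = sum(tab$Ar_m2) / sum(truth$Ar_true),
       height_bias = hb, n_matched = nm, undefined = FALSE)
}
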