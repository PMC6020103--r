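split_m <- threshold_model(alpha = 0.5, beta = 1.0, kind = "split_95pi")

test_that("split criterion is the strict upper prediction bound", {
  mk <- function(r) structure(list(H = 10, r = r), class = "crown")
  expect_false(needs_split(mk(5.9), split_m))   # bound 6.0 not exceeded
  expect_true(needs_split(mk(6.1), split_m))
  expect_false(needs_split(mk(6.0), split_m))   # equality does not split
})

test_that("split_canopy is a no-op for single-crown clusters", {
  pc <- blob_cloud(100, 0, 0, sd = 0.8, seed = 4)
  cl <- make_crown(as.data.frame(pc), id = 1)
  bt_m <- threshold_model(0.3, 0.7, "bt_mean")
  out <- split_canopy(cl, bt_m, split_m, segmentation_params())
  expect_length(out, 1)
  expect_identical(out[[1]]$points, cl$points)
})

test_that("a merged pair splits into two crowns near the true stems", {
  models <- fit_study_models()
  p <- tree_population_params(radius_sd = 0)
  tr <- generate_tree_population(2, p, seed = 101)
  tr$H <- c(20, 20); tr$crown_radius <- c(5.5, 5.5); tr$crown_base <- c(5, 5)
  tr$x <- c(50, 58); tr$y <- c(50, 50)
  sc <- render_scene(scene_spec(tr, extent = c(0, 0, 110, 110), seed = 101))
  params <- segmentation_params(split_model = models$split,
                                bt_model = models$bt)
  cs <- segment_trees(sc$cloud, params)
  expect_equal(length(cs), 2)
  tab <- as.data.frame(cs)
  expect_true(all(abs(sort(tab$x) - c(50, 58)) < 2))
  expect_true(all(abs(tab$y - 50) < 2))
})

test_that("three touching crowns split into three accepted subclusters", {
  models <- fit_study_models()
  p <- tree_population_params(radius_sd = 0)
  tr <- generate_tree_population(3, p, seed = 202)
  tr$H <- rep(20, 3); tr$crown_radius <- rep(5.5, 3); tr$crown_base <- rep(5, 3)
  tr$x <- c(42, 50, 58); tr$y <- rep(50, 3)
  sc <- render_scene(scene_spec(tr, extent = c(0, 0, 110, 110), seed = 202))
  params <- segmentation_params(split_model = models$split,
                                bt_model = models$bt)
  cs <- segment_trees(sc$cloud, params)
  expect_equal(length(cs), 3)
  for (cr in cs$crowns)
    expect_true(!needs_split(cr, models$split) ||
                  isTRUE(cr$warn_nonconverged))
})

test_that("crown cleaning enforces area, height and duplicate rules", {
  mk <- function(cx, n, r, h, zoff = 0) {
    th <- seq(0, 2 * pi, length.out = n)
    make_crown(data.frame(x = cx + r * cos(th), y = r * sin(th),
                          z = h + zoff))
  }
  params <- segmentation_params()
  # area rule: 9 vs 15 m2 at the 10 m2 threshold
  small <- mk(0, 30, sqrt(9 / pi), 12)
  big <- mk(20, 30, sqrt(15 / pi), 12)
  out <- clean_crowns(crown_set(list(small, big)), params)
  expect_equal(length(out), 1)
  expect_equal(out$crowns[[1]]$Ar, big$Ar, tolerance = 1e-6)
  # height rule
  tall <- mk(40, 30, 3, 80)
  out2 <- clean_crowns(crown_set(list(big, tall)), params)
  expect_equal(length(out2), 1)
  expect_lt(out2$crowns[[1]]$H, 45)
  # vertically offset duplicates: same footprint, high IoU
  dup_lo <- mk(0, 40, 3, 8)
  dup_hi <- mk(0, 25, 3, 16)
  out3 <- clean_crowns(crown_set(list(dup_lo, dup_hi)), params)
  expect_equal(length(out3), 1)
  expect_equal(out3$crowns[[1]]$n_points, 40)  # more points wins
})

test_that("contained lower slices are removed as duplicates", {
  th <- seq(0, 2 * pi, length.out = 60)
  main <- make_crown(data.frame(x = 8 * cos(th), y = 8 * sin(th), z = 25))
  slice <- make_crown(data.frame(x = 4 * cos(th[1:45]),
                                 y = 4 * sin(th[1:45]), z = 12))
  out <- clean_crowns(crown_set(list(main, slice)), segmentation_params())
  expect_equal(length(out), 1)
  expect_equal(out$crowns[[1]]$n_points, 60)
})

test_that("segmentation partitions the filtered cloud", {
  models <- fit_study_models()
  pop <- place_trees_separated(generate_tree_population(12, seed = 21),
                               seed = 21)
  sc <- render_scene(scene_spec(pop, seed = 21))
  params <- segmentation_params(split_model = models$split,
                                bt_model = models$bt)
  cs <- segment_trees(sc$cloud, params)
  # crown point sets are pairwise disjoint
  keys <- unlist(lapply(cs$crowns, function(cr)
    paste(cr$points$x, cr$points$y, cr$points$z)))
  expect_equal(anyDuplicated(keys), 0)
  # all crown points come from the filtered cloud
  filt <- filter_low_points(filter_single_return_points(sc$cloud))
  allkeys <- paste(filt$x, filt$y, filt$z)
  expect_true(all(keys %in% allkeys))
})

test_that("segmentation is deterministic", {
  models <- fit_study_models()
  pop <- place_trees_separated(generate_tree_population(10, seed = 31),
                               seed = 31)
  sc <- render_scene(scene_spec(pop, seed = 31))
  params <- segmentation_params(split_model = models$split,
                                bt_model = models$bt)
  t1 <- as.data.frame(segment_trees(sc$cloud, params))
  t2 <- as.data.frame(segment_trees(sc$cloud, params))
  expect_identical(t1, t2)
})

test_that("raising the minimum polygon area never adds crowns", {
  models <- fit_study_models()
  pop <- place_trees_separated(generate_tree_population(15, seed = 41),
                               seed = 41)
  sc <- render_scene(scene_spec(pop, seed = 41))
  n_prev <- Inf
  for (a in c(0, 10, 40, 120)) {
    params <- segmentation_params(split_model = models$split,
                                  bt_model = models$bt,
                                  min_polygon_area = a)
    n <- length(segment_trees(sc$cloud, params))
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("buildings are removed by the return-number filter", {
  models <- fit_study_models()
  tr <- generate_tree_population(1, seed = 51)
  tr$H <- 18; tr$crown_radius <- 4; tr$crown_base <- 5
  tr$x <- 30; tr$y <- 30
  bld <- data.frame(xmin = 60, xmax = 90, ymin = 20, ymax = 45, height = 12)
  sc <- render_scene(scene_spec(tr, extent = c(0, 0, 100, 60),
                                buildings = bld, edge_noise_prob = 0,
                                seed = 51))
  params <- segmentation_params(split_model = models$split,
                                bt_model = models$bt)
  cs <- segment_trees(sc$cloud, params)
  expect_equal(length(cs), 1)
  tab <- as.data.frame(cs)
  expect_lt(abs(tab$x - 30), 2)
})

test_that("an empty cloud segments to an empty crown set", {
  models <- fit_study_models()
  pc <- point_cloud(data.frame(x = numeric(0), y = numeric(0),
                               z = numeric(0),
                               number_of_returns = integer(0)))
  params <- segmentation_params(split_model = models$split,
                                bt_model = models$bt)
  expect_equal(length(segment_trees(pc, params)), 0)
})
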