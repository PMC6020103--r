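make_table <- function(H, Ar, V) {
  df <- data.frame(id = seq_along(H), site = "t", dbh_m = 0.3,
                   h_m = H, ar_m2 = Ar)
  for (j in 1:10) df[[paste0("vol_", j)]] <- V
  df$species <- "x"
  qsm_table(df)
}

test_that("QSM tables derive mean volume and CI on load", {
  q <- make_table(c(10, 20, 30), c(50, 100, 150), c(2, 8, 20))
  expect_equal(q$V, c(2, 8, 20))
  expect_equal(q$v_ci95, c(0, 0, 0))
  expect_error(make_table(c(10, 20), c(50, 100), c(-1, 5)), "non-positive")
  f <- tempfile(fileext = ".csv")
  write.csv(as.data.frame(q), f, row.names = FALSE)
  expect_equal(read_qsm_table(f)$V, q$V)
})

test_that("reconstruction stability QC applies the t-based 95% CI rule", {
  expect_true(qc_volume_stability(rep(10, 10)))
  # construct volumes whose CI half-width is a chosen fraction of mean
  base <- scale(rnorm(10))[, 1]            # exactly mean 0, sd 1
  ci_frac <- function(f, m = 10) {
    sd_needed <- f * m * sqrt(10) / qt(0.975, 9)
    m + base * sd_needed
  }
  expect_false(qc_volume_stability(ci_frac(0.15)))  # 15% > 10% tolerance
  expect_true(qc_volume_stability(ci_frac(0.08)))   # 8% passes
  expect_error(qc_volume_stability(c(5)), "at least 2")
})

test_that("slice-wise 4-NN density QC discriminates grid spacings", {
  grid <- function(sp) {
    g <- expand.grid(x = seq(0, 1, by = sp), y = seq(0, 1, by = sp),
                     z = seq(0, 3, by = sp))
    g
  }
  expect_true(qc_point_density(grid(0.05), max_dist = 0.06)$pass)
  expect_false(qc_point_density(grid(0.2), max_dist = 0.05)$pass)
  # single-slice cloud: only the uppermost slice exists, so no slice is
  # evaluated and the check passes vacuously
  one <- data.frame(x = runif(50), y = runif(50), z = runif(50, 0, 0.5))
  res <- qc_point_density(one)
  expect_true(res$pass)
  expect_false(any(res$per_slice$evaluated))
})

test_that("exponential height curve recovers exact and flat laws", {
  H <- 5:30
  em <- fit_exponential_height(H, 2 * 1.2^H)
  expect_equal(em$a, 2, tolerance = 1e-6)
  expect_equal(em$b, 1.2, tolerance = 1e-6)
  em_flat <- fit_exponential_height(H, rep(7, length(H)))
  expect_equal(em_flat$b, 1, tolerance = 1e-6)
  expect_error(fit_exponential_height(c(1, 2), c(1, 2)), ">= 3")
  expect_error(fit_exponential_height(H, -(1:26)), "positive")
})

test_that("joint allometry fit recovers a noiseless generating law", {
  set.seed(13)
  H <- runif(60, 5, 35)
  Ar <- pi * (0.5 + 0.25 * H + rnorm(60, 0, 0.75))^2
  V <- 0.05 * Ar + 0.08 * 1.15^H        # k_Ar=0.05, a=0.08, b=1.15
  q <- make_table(H, Ar, V)
  m <- fit_volume_allometry(q, method = "joint")
  expect_equal(m$k_Ar, 0.05, tolerance = 1e-6)
  expect_equal(m$k_exp * m$exp_model$a, 0.08, tolerance = 1e-6)
  expect_equal(m$exp_model$b, 1.15, tolerance = 1e-6)
  expect_equal(m$r2, 1.0, tolerance = 1e-9)
  # noiseless predictions have zero residual on held-out trees
  Hn <- runif(20, 5, 35)
  Arn <- pi * (0.5 + 0.25 * Hn)^2
  pred <- predict_volume(m, Hn, Arn)
  expect_equal(pred$V, 0.05 * Arn + 0.08 * 1.15^Hn, tolerance = 1e-6)
})

test_that("area-only volume laws drive the exponential weight to zero", {
  set.seed(14)
  H <- runif(80, 5, 35)
  Ar <- runif(80, 20, 400)              # independent of H
  q <- make_table(H, Ar, 0.05 * Ar)
  m <- fit_volume_allometry(q, method = "two_stage")
  expect_equal(m$k_Ar, 0.05, tolerance = 1e-3)
  expect_lt(abs(m$k_exp * m$exp_model$a *
                  m$exp_model$b^mean(H)), 0.05 * mean(Ar) * 0.05)
})

test_that("allometry recovery holds under 10% noise across seeds", {
  # relative weighting matches the multiplicative volume noise
  errs_kar <- errs_b <- numeric(20)
  for (s in 1:20) {
    pop <- generate_tree_population(99, seed = 400 + s)
    q <- make_qsm_table(pop, recon_cv = 0.05, seed = 400 + s)
    m <- fit_volume_allometry(q, method = "joint", weighting = "relative")
    errs_kar[s] <- abs(m$k_Ar - 0.04) / 0.04
    errs_b[s] <- abs(m$exp_model$b - 1.2) / 1.2
  }
  expect_lt(median(errs_kar), 0.05)
  expect_lt(median(errs_b), 0.05)
})

test_that("threshold models fit the mean line and the shifted bound line", {
  H <- seq(5, 35, length.out = 200)
  r <- 1 + 0.3 * H
  q <- make_table(H, pi * r^2, 1 + 0.1 * H)
  bt <- fit_threshold_model(q, "bt_mean")
  expect_equal(bt$alpha, 0.3, tolerance = 1e-9)
  expect_equal(bt$beta, 1.0, tolerance = 1e-9)
  # homoskedastic noise: the bound line sits ~1.96 sd above the mean line
  set.seed(15)
  rn <- pmax(0.2, 1 + 0.3 * H + rnorm(length(H), 0, 0.5))
  qn <- make_table(H, pi * rn^2, 1 + 0.1 * H)
  mean_m <- fit_threshold_model(qn, "bt_mean")
  bound_m <- fit_threshold_model(qn, "split_95pi")
  hm <- mean(H)
  shift <- (bound_m$beta + bound_m$alpha * hm) -
    (mean_m$beta + mean_m$alpha * hm)
  expect_equal(shift, 1.96 * 0.5, tolerance = 0.15)
  # the bound line dominates the mean line at every training height
  expect_true(all(bound_m$beta + bound_m$alpha * H >=
                    mean_m$beta + mean_m$alpha * H - 1e-9))
  expect_error(fit_threshold_model(make_table(c(5, 10), c(10, 20),
                                              c(1, 2))), ">= 3")
})

test_that("volume prediction evaluates the model and clips at zero", {
  m <- structure(list(k_Ar = 0.05, k_exp = 1,
                      exp_model = structure(list(a = 0.1, b = 1.15),
                                            class = "exponential_height_model"),
                      residual_sd = 0.5, r2 = 1, rmse = 0.4, n = 10,
                      method = "joint"),
                 class = "allometric_model")
  expect_equal(predict_volume(m, 0, 0)$V, 0.1)   # k_exp * a at H = 0
  expect_equal(predict_volume(m, 20, 100)$V, 5 + 0.1 * 1.15^20)
  expect_equal(predict_volume(m, 20, 100)$pred_sd, 0.5)
  m$k_Ar <- -1
  p <- predict_volume(m, 0, 100)
  expect_equal(p$V, 0)
  expect_equal(attr(p, "n_clipped"), 1)
})

test_that("models survive a JSON round trip", {
  q <- make_table(seq(5, 30, by = 1), pi * (1 + 0.3 * seq(5, 30, 1))^2,
                  2 * 1.1^seq(5, 30, 1))
  m <- fit_volume_allometry(q, method = "joint")
  f <- tempfile(fileext = ".json")
  write_model_json(m, f)
  m2 <- read_model_json(f)
  expect_equal(m2$k_Ar, m$k_Ar, tolerance = 1e-12)
  expect_equal(m2$exp_model$b, m$exp_model$b, tolerance = 1e-12)
  tm <- fit_threshold_model(q, "split_95pi")
  write_model_json(tm, f)
  tm2 <- read_model_json(f)
  expect_equal(tm2$alpha, tm$alpha, tolerance = 1e-12)
  expect_identical(tm2$kind, "split_95pi")
})
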