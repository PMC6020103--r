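# a small crown set with known metrics, built from disc point samples
disc_crown <- function(id, cx, cy, r, h, n, seed) {
  set.seed(seed)
  th <- runif(n, 0, 2 * pi)
  rho <- r * sqrt(runif(n))
  make_crown(data.frame(x = cx + rho * cos(th), y = cy + rho * sin(th),
                        z = runif(n, 0.6 * h, h)), id = id)
}

toy_model <- function(residual_sd = 0) {
  structure(list(k_Ar = 0.04, k_exp = 1,
                 exp_model = structure(list(a = 0.05, b = 1.2),
                                       class = "exponential_height_model"),
                 residual_sd = residual_sd, r2 = 1, rmse = 0, n = 99,
                 method = "joint"),
            class = "allometric_model")
}

test_that("crown metric uncertainty is seeded and degenerate-safe", {
  cr <- disc_crown(1, 0, 0, 5, 20, 300, 1)
  cr$points$z <- 15                       # all points at one height
  cfg <- mc_config(seed = 42)
  u1 <- crown_metric_uncertainty(cr, cfg)
  u2 <- crown_metric_uncertainty(cr, cfg)
  expect_equal(u1$sd_H, 0)
  expect_identical(u1, u2)
  expect_gt(u1$sd_Ar, 0)
  tiny <- disc_crown(2, 0, 0, 1, 5, 3, 2)
  expect_error(crown_metric_uncertainty(tiny, cfg), "too few")
})

test_that("denser crowns have relatively tighter area estimates", {
  rel <- sapply(1:10, function(s) {
    c100 <- disc_crown(1, 0, 0, 5, 20, 100, s)
    c1000 <- disc_crown(2, 0, 0, 5, 20, 1000, s)
    cfg <- mc_config(seed = s)
    u100 <- crown_metric_uncertainty(c100, cfg)
    u1000 <- crown_metric_uncertainty(c1000, cfg)
    (u1000$sd_Ar / c1000$Ar) < (u100$sd_Ar / c100$Ar)
  })
  expect_gte(median(rel), 1)   # holds in the majority of seeds
})

test_that("the wood-density PDF reproduces the empirical distribution", {
  expect_error(build_density_pdf(numeric(0)), "empty")
  expect_error(build_density_pdf(c(500, -3)), "> 0")
  single <- build_density_pdf(537)
  set.seed(1)
  expect_true(all(draw_density(single, 100) == 537))
  two <- build_density_pdf(c(400, 600))
  set.seed(2)
  d <- draw_density(two, 1e4)
  expect_lt(abs(mean(d == 400) - 0.5), 3 * sqrt(0.25 / 1e4))
  tab <- read.csv(system.file("extdata", "wood_density_synthetic.csv",
                              package = "urbancanopy"))
  pdf <- build_density_pdf(tab)
  set.seed(3)
  d2 <- draw_density(pdf, 1e5)
  se <- sd(tab$density_kg_m3) / sqrt(1e5)
  expect_lt(abs(mean(d2) - mean(tab$density_kg_m3)), 3 * se)
})

test_that("degenerate PDFs reproduce the deterministic AGB exactly", {
  crowns <- crown_set(list(disc_crown(1, 0, 0, 5, 20, 200, 1),
                           disc_crown(2, 30, 0, 4, 15, 150, 2)))
  model <- toy_model()
  pdfs <- list(als = data.frame(crown_id = c(1, 2), sd_H = 0, sd_Ar = 0),
               qsm = 0,
               density = build_density_pdf(537))
  res <- run_monte_carlo(crowns, model, pdfs, mc_config(n_sims = 50))
  tab <- as.data.frame(crowns)
  det <- volume_to_agb(predict_volume(model, tab$H_m, tab$Ar_m2)$V, 537)
  expect_equal(res$per_crown$agb_mean, det)
  expect_equal(res$per_crown$agb_sd, c(0, 0))
  # freezing every component gives the same result without any PDF draws
  frozen <- run_monte_carlo(crowns, model, list(fixed_density = 537),
                            mc_config(n_sims = 5, components = character(0)))
  expect_equal(frozen$per_crown$agb_mean, det)
})

test_that("a fixed seed makes Monte Carlo results bit-identical", {
  crowns <- crown_set(list(disc_crown(1, 0, 0, 5, 20, 200, 1)))
  model <- toy_model()
  pdfs <- list(als = data.frame(crown_id = 1, sd_H = 0.5, sd_Ar = 8),
               qsm = 0.05,
               density = build_density_pdf(c(420, 537, 560)))
  r1 <- run_monte_carlo(crowns, model, pdfs, mc_config(seed = 7))
  r2 <- run_monte_carlo(crowns, model, pdfs, mc_config(seed = 7))
  expect_identical(r1$total_agb, r2$total_agb)
  r3 <- run_monte_carlo(crowns, model, pdfs, mc_config(seed = 8))
  expect_false(identical(r1$total_agb, r3$total_agb))
})

test_that("density-only uncertainty propagates its CV linearly into AGB", {
  crowns <- crown_set(lapply(1:5, function(i)
    disc_crown(i, 40 * i, 0, 5, 20, 200, i)))
  model <- toy_model()
  set.seed(99)
  dens <- rnorm(5000, 537, 0.15 * 537)    # density CV = 15%
  dens <- dens[dens > 100]
  pdfs <- list(density = build_density_pdf(dens))
  cfg <- mc_config(n_sims = 1000, seed = 5, components = "density")
  res <- run_monte_carlo(crowns, model, pdfs, cfg)
  # same density draw scales every crown? no: one draw per crown, so the
  # total is an average over 5 crowns; per-crown CV is the clean check
  cv_pc <- res$per_crown$agb_sd / res$per_crown$agb_mean
  cv_true <- sd(dens) / mean(dens)
  se <- cv_true * sqrt(2 / (cfg$n_sims - 1))
  for (cv in cv_pc) expect_lt(abs(cv - cv_true), 3 * se)
})

test_that("missing PDFs for active components raise errors", {
  crowns <- crown_set(list(disc_crown(1, 0, 0, 5, 20, 100, 1)))
  model <- toy_model()
  expect_error(run_monte_carlo(crowns, model, list(),
                               mc_config(components = "density")),
               "density")
  expect_error(run_monte_carlo(crowns, model, list(),
                               mc_config(components = "als")), "als")
})

test_that("variance decomposition recovers known component shares", {
  cr <- disc_crown(1, 0, 0, 5, 20, 200, 3)
  crowns <- crown_set(list(cr))
  model <- toy_model()
  tab <- as.data.frame(crowns)
  v0 <- predict_volume(model, tab$H_m, tab$Ar_m2)$V
  rho0 <- 537
  # AGB = V * rho / 1000 is linear in each input, so component variances
  # are known in closed form from the input spreads; choose a 1:3 ratio
  set.seed(123)
  dens <- rnorm(20000, rho0, 0.10 * rho0)   # mild CV: no truncation
  v_d <- (v0 * sd(dens) / 1000)^2
  sd_q <- sqrt(v_d / 3) * 1000 / rho0       # var(qsm) = var(density)/3
  pdfs <- list(qsm = data.frame(crown_id = 1, sd = sd_q),
               density = build_density_pdf(dens))
  cfg <- mc_config(n_sims = 1000, seed = 17,
                   components = c("qsm", "density"))
  shares <- variance_decomposition(crowns, model, pdfs, cfg)
  expect_lt(abs(shares[["qsm"]] - 0.25), 0.06)
  expect_lt(abs(shares[["density"]] - 0.75), 0.06)
  # single active component takes the whole share
  cfg1 <- mc_config(n_sims = 200, seed = 1, components = "qsm")
  s1 <- variance_decomposition(crowns, model, pdfs, cfg1)
  expect_equal(as.numeric(s1), 1)
  # a zero-variance component contributes nothing
  pdfs0 <- list(qsm = data.frame(crown_id = 1, sd = 0),
                density = build_density_pdf(dens))
  s0 <- variance_decomposition(crowns, model, pdfs0, cfg)
  expect_equal(unname(s0[["qsm"]]), 0)
})

test_that("total variance dominates each single-component variance", {
  crowns <- crown_set(lapply(1:3, function(i)
    disc_crown(i, 40 * i, 0, 4 + i, 12 + 3 * i, 150, i)))
  model <- toy_model()
  pdfs <- list(als = crown_uncertainty_pdfs(crowns, mc_config(seed = 2)),
               qsm = 0.1,
               density = build_density_pdf(c(420, 537, 560, 590, 510)))
  cfg <- mc_config(n_sims = 400, seed = 31)
  v_all <- var(run_monte_carlo(crowns, model, pdfs, cfg)$total_agb)
  for (comp in c("qsm", "als", "density")) {
    cfg1 <- cfg; cfg1$components <- comp
    v1 <- var(run_monte_carlo(crowns, model, pdfs, cfg1)$total_agb)
    expect_gt(v_all, 0.8 * v1)   # subadditivity within MC tolerance
  }
})
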