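#' Monte Carlo configuration
#'
#' @param n_sims number of Monte Carlo model runs (default 100).
#' @param subsample_iterations iterations used when estimating crown
#'   measurement uncertainty by point subsampling (default 100).
#' @param subsample_fraction fraction of a crown's points *retained* per
#'   subsample iteration (default 0.75).
#' @param seed integer seed controlling every random draw.
#' @param components uncertainty components to perturb: any of `"qsm"`
#'   (volume), `"als"` (crown `H`/`Ar` measurement), `"density"` (wood
#'   density). Inactive components are frozen at their point values.
#' @return An `mc_config` list.
#' @export
mc_config <- function(n_sims = 100, subsample_iterations = 100,
                      subsample_fraction = 0.75, seed = 1,
                      components = c("qsm", "als", "density")) {
  stopifnot(n_sims >= 1, subsample_fraction > 0, subsample_fraction <= 1,
            subsample_iterations >= 2)
  if (length(components))
    components <- match.arg(components, several.ok = TRUE)
  else
    components <- character(0)   # everything frozen: deterministic run
  structure(list(n_sims = as.integer(n_sims),
                 subsample_iterations = as.integer(subsample_iterations),
                 subsample_fraction = subsample_fraction,
                 seed = as.integer(seed),
                 components = components),
            class = "mc_config")
}

#' Crown measurement uncertainty by point subsampling
#'
#' Repeats `subsample_iterations` times: retain a uniformly random
#' `subsample_fraction` of the crown's points and recompute `H` and
#' `Ar`. The standard deviations across iterations characterise the
#' sensitivity of the crown metrics to the particular returns the ALS
#' happened to record.
#'
#' @param crown a [make_crown()] object (member points required).
#' @param config an [mc_config()]; its `seed` makes the result
#'   deterministic.
#' @return list with `crown_id`, `sd_H` (m), `sd_Ar` (m^2)
#'   (class `crown_metric_pdf`).
#' @export
crown_metric_uncertainty <- function(crown, config = mc_config()) {
  n <- crown$n_points
  f <- config$subsample_fraction
  if (n < ceiling(1 / (1 - f)))
    stop("crown_metric_uncertainty: too few points to subsample")
  k <- max(3L, as.integer(round(f * n)))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(config$seed + (if (is.na(crown$id)) 0L else as.integer(crown$id)))
  hs <- numeric(config$subsample_iterations)
  as <- numeric(config$subsample_iterations)
  for (i in seq_len(config$subsample_iterations)) {
    idx <- sample.int(n, k)
    hs[i] <- max(crown$points$z[idx])
    as[i] <- polygon_area(convex_hull_xy(crown$points$x[idx],
                                         crown$points$y[idx]))
  }
  structure(list(crown_id = crown$id,
                 sd_H = stats::sd(hs), sd_Ar = stats::sd(as)),
            class = "crown_metric_pdf")
}

#' Measurement PDFs for every crown in a set
#'
#' Applies [crown_metric_uncertainty()] per crown. Crowns with too few
#' points to subsample receive the mean *relative* sd of the crowns that
#' could be sampled, scaled to their own `H` and `Ar`.
#'
#' @param crowns a [crown_set()] whose crowns retain member points.
#' @param config an [mc_config()].
#' @return data.frame `crown_id`, `sd_H`, `sd_Ar`.
#' @export
crown_uncertainty_pdfs <- function(crowns, config = mc_config()) {
  res <- lapply(crowns$crowns, function(cr) {
    tryCatch(crown_metric_uncertainty(cr, config), error = function(e) NULL)
  })
  ok <- !vapply(res, is.null, logical(1))
  if (!any(ok)) stop("crown_uncertainty_pdfs: no crown could be subsampled")
  tab <- data.frame(
    crown_id = vapply(crowns$crowns, function(c) c$id, numeric(1)),
    sd_H = NA_real_, sd_Ar = NA_real_)
  tab$sd_H[ok] <- vapply(res[ok], function(r) r$sd_H, numeric(1))
  tab$sd_Ar[ok] <- vapply(res[ok], function(r) r$sd_Ar, numeric(1))
  if (any(!ok)) {
    H <- vapply(crowns$crowns, function(c) c$H, numeric(1))
    Ar <- vapply(crowns$crowns, function(c) c$Ar, numeric(1))
    rel_h <- mean(tab$sd_H[ok] / H[ok])
    rel_a <- mean(tab$sd_Ar[ok] / pmax(Ar[ok], 1e-9))
    tab$sd_H[!ok] <- rel_h * H[!ok]
    tab$sd_Ar[!ok] <- rel_a * Ar[!ok]
  }
  tab
}

#' Empirical wood-density distribution
#'
#' Non-parametric PDF of wood density: Monte Carlo draws are uniform
#' with replacement over the per-tree mapped density values, so the
#' propagated distribution is exactly the empirical one.
#'
#' @param densities numeric vector of wood densities (kg m^-3), or a
#'   data.frame with a `density` (or `density_kg_m3`) column.
#' @return A `density_pdf` (list with `samples`).
#' @export
build_density_pdf <- function(densities) {
  if (is.data.frame(densities)) {
    col <- intersect(c("density", "density_kg_m3", "wood_density"),
                     names(densities))[1]
    if (is.na(col)) stop("build_density_pdf: no density column found")
    densities <- densities[[col]]
  }
  densities <- densities[!is.na(densities)]
  if (!length(densities)) stop("build_density_pdf: empty density table")
  if (any(densities <= 0)) stop("build_density_pdf: densities must be > 0")
  structure(list(samples = as.numeric(densities)), class = "density_pdf")
}

#' Draw from a density PDF
#' @param pdf a [build_density_pdf()] object.
#' @param n number of draws.
#' @return numeric vector of densities (kg m^-3).
#' @export
draw_density <- function(pdf, n = 1) {
  pdf$samples[sample.int(length(pdf$samples), n, replace = TRUE)]
}

# deterministic AGB for a crown table given a model and fixed density
deterministic_agb <- function(tab, model, density) {
  pred <- predict_volume(model, tab$H_m, tab$Ar_m2)
  volume_to_agb(pred$V, density)
}

#' Monte Carlo propagation of AGB uncertainty
#'
#' Runs the volume allometry + wood-density conversion `n_sims` times.
#' Per simulation and crown, the active components draw: `als` — `H` and
#' `Ar` from Gaussians with the subsampling standard deviations
#' (truncated at zero); `qsm` — predicted volume from a Gaussian with
#' the per-crown volume sd; `density` — a wood density resampled from
#' the empirical PDF (one draw per crown per simulation). Inactive
#' components stay frozen at their point values, so with all components
#' frozen the result equals the deterministic estimate exactly.
#'
#' @param crowns a [crown_set()].
#' @param model an `allometric_model`.
#' @param pdfs list with elements (required per active component):
#'   `als` — data.frame from [crown_uncertainty_pdfs()];
#'   `qsm` — either a single relative sd applied to predicted volume or
#'   a data.frame `crown_id`, `sd` (m^3); `density` — a
#'   [build_density_pdf()] object. `fixed_density` (kg m^-3) gives the
#'   frozen density when the density component is inactive (defaults to
#'   the mean of `pdfs$density$samples`, or 537 if neither is present).
#' @param config an [mc_config()].
#' @return An `mc_result`: `per_crown` (mean, sd, 2.5/97.5 percentiles of
#'   AGB in Mg), `total_agb` (vector of per-simulation Borough totals),
#'   `summary`.
#' @export
run_monte_carlo <- function(crowns, model, pdfs, config = mc_config()) {
  tab <- as.data.frame(crowns)
  ncr <- nrow(tab)
  if (!ncr) stop("run_monte_carlo: empty crown set")
  active <- config$components
  if ("als" %in% active && is.null(pdfs$als))
    stop("run_monte_carlo: 'als' active but pdfs$als missing")
  if ("qsm" %in% active && is.null(pdfs$qsm))
    stop("run_monte_carlo: 'qsm' active but pdfs$qsm missing")
  if ("density" %in% active && is.null(pdfs$density))
    stop("run_monte_carlo: 'density' active but pdfs$density missing")

  fixed_density <- pdfs$fixed_density
  if (is.null(fixed_density))
    fixed_density <- if (!is.null(pdfs$density))
      mean(pdfs$density$samples) else 537

  if ("als" %in% active) {
    m <- match(tab$id, pdfs$als$crown_id)
    sd_H <- pdfs$als$sd_H[m]; sd_Ar <- pdfs$als$sd_Ar[m]
    if (anyNA(sd_H) || anyNA(sd_Ar))
      stop("run_monte_carlo: pdfs$als does not cover all crowns")
  }
  qsm_sd <- NULL
  if ("qsm" %in% active) {
    base_v <- predict_volume(model, tab$H_m, tab$Ar_m2)$V
    qsm_sd <- if (is.data.frame(pdfs$qsm)) {
      s <- pdfs$qsm$sd[match(tab$id, pdfs$qsm$crown_id)]
      if (anyNA(s)) stop("run_monte_carlo: pdfs$qsm does not cover crowns")
      s
    } else {
      as.numeric(pdfs$qsm) * base_v
    }
  }

  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(config$seed)

  agb <- matrix(NA_real_, nrow = config$n_sims, ncol = ncr)
  for (s in seq_len(config$n_sims)) {
    H <- tab$H_m; Ar <- tab$Ar_m2
    if ("als" %in% active) {
      H <- pmax(0, stats::rnorm(ncr, H, sd_H))
      Ar <- pmax(0, stats::rnorm(ncr, Ar, sd_Ar))
    }
    V <- predict_volume(model, H, Ar)$V
    if ("qsm" %in% active)
      V <- pmax(0, stats::rnorm(ncr, V, qsm_sd))
    rho <- if ("density" %in% active)
      draw_density(pdfs$density, ncr) else rep(fixed_density, ncr)
    agb[s, ] <- volume_to_agb(V, rho)
  }

  per_crown <- data.frame(
    crown_id = tab$id,
    agb_mean = colMeans(agb),
    agb_sd = apply(agb, 2, stats::sd),
    q025 = apply(agb, 2, stats::quantile, probs = 0.025, names = FALSE),
    q975 = apply(agb, 2, stats::quantile, probs = 0.975, names = FALSE))
  total <- rowSums(agb)
  structure(list(per_crown = per_crown,
                 total_agb = total,
                 summary = c(mean = mean(total), sd = stats::sd(total),
                             q025 = stats::quantile(total, 0.025,
                                                    names = FALSE),
                             q975 = stats::quantile(total, 0.975,
                                                    names = FALSE)),
                 components = active, n_sims = config$n_sims),
            class = "mc_result")
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf(
    "<mc_result> %d sims, components: %s\n  total AGB %.2f Mg (sd %.2f, 95%% [%.2f, %.2f])\n",
    x$n_sims, paste(x$components, collapse = "+"),
    x$summary["mean"], x$summary["sd"], x$summary["q025"], x$summary["q975"]))
  invisible(x)
}

#' Variance decomposition by component freezing
#'
#' Runs the Monte Carlo once per component with the other components
#' frozen; each component's share is its total-AGB variance divided by
#' the sum of the single-component variances (so shares sum to 1).
#' The interaction residual — all-active variance minus the sum of the
#' single-component variances — is attached as attribute `interaction`.
#'
#' @param crowns,model,pdfs,config see [run_monte_carlo()].
#' @return named numeric vector of shares per component.
#' @export
variance_decomposition <- function(crowns, model, pdfs,
                                   config = mc_config()) {
  comps <- config$components
  if (length(comps) < 1) stop("variance_decomposition: no active components")
  vars <- vapply(seq_along(comps), function(i) {
    cfg <- config
    cfg$components <- comps[i]
    cfg$seed <- config$seed + i
    stats::var(run_monte_carlo(crowns, model, pdfs, cfg)$total_agb)
  }, numeric(1))
  names(vars) <- comps
  shares <- if (sum(vars) > 0) vars / sum(vars) else
    rep(0, length(vars))
  names(shares) <- comps
  all_cfg <- config
  all_cfg$seed <- config$seed
  v_all <- stats::var(run_monte_carlo(crowns, model, pdfs,
                                      all_cfg)$total_agb)
  attr(shares, "interaction") <- v_all - sum(vars)
  shares
}
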