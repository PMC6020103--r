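#' QSM tree tables
#'
#' A QSM tree table holds one row per TLS-measured tree: `id`, `site`,
#' `dbh_m`, `h_m`, `ar_m2`, up to ten reconstruction volumes
#' `vol_1..vol_10` (m^3, one per stochastic QSM reconstruction of the
#' same tree point cloud), `species` and optionally `wood_density`
#' (kg m^-3). `V` (mean reconstruction volume) and `v_ci95` (95%
#' confidence half-width as a fraction of `V`) are derived on load.
#'
#' @param df data.frame in the schema above.
#' @return A validated `qsm_table` data.frame with `V` and `v_ci95`.
#' @export
qsm_table <- function(df) {
  df <- as.data.frame(df)
  volcols <- grep("^vol_[0-9]+$", names(df), value = TRUE)
  if (!length(volcols)) stop("qsm_table: no vol_* columns")
  need <- c("id", "h_m", "ar_m2")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("qsm_table: missing columns: ", paste(miss, collapse = ", "))
  vols <- as.matrix(df[, volcols, drop = FALSE])
  df$V <- rowMeans(vols, na.rm = TRUE)
  nrec <- rowSums(!is.na(vols))
  sdv <- apply(vols, 1, stats::sd, na.rm = TRUE)
  ci <- ifelse(nrec >= 2,
               stats::qt(0.975, nrec - 1) * sdv / sqrt(nrec), NA_real_)
  df$v_ci95 <- ci / df$V
  if (any(df$V <= 0, na.rm = TRUE))
    stop("qsm_table: non-positive mean volumes")
  if (any(df$h_m <= 0 | df$ar_m2 <= 0, na.rm = TRUE))
    stop("qsm_table: non-positive H or Ar")
  class(df) <- c("qsm_table", "data.frame")
  df
}

#' Read a QSM tree table from CSV
#'
#' @param path CSV with columns `id, site, dbh_m, h_m, ar_m2,
#'   vol_1..vol_10, species[, wood_density]`.
#' @return A [qsm_table()].
#' @export
read_qsm_table <- function(path) {
  qsm_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' QSM reconstruction-stability quality check
#'
#' A tree passes when the 95% confidence half-width (t-based) of its
#' reconstruction volumes is at most `max_rel_ci` of the mean volume.
#' Trees whose stochastic reconstructions disagree more than that are
#' excluded from allometry fitting.
#'
#' @param volumes numeric vector of reconstruction volumes (>= 2 values).
#' @param max_rel_ci tolerated CI half-width as a fraction of the mean.
#' @return logical.
#' @export
qc_volume_stability <- function(volumes, max_rel_ci = 0.10) {
  volumes <- volumes[!is.na(volumes)]
  if (length(volumes) < 2)
    stop("qc_volume_stability: need at least 2 reconstruction volumes")
  m <- mean(volumes)
  half <- stats::qt(0.975, length(volumes) - 1) *
    stats::sd(volumes) / sqrt(length(volumes))
  half <= max_rel_ci * m
}

#' Filter a QSM table on reconstruction stability
#'
#' @param trees a [qsm_table()].
#' @param max_rel_ci see [qc_volume_stability()].
#' @return The rows that pass, as a `qsm_table`.
#' @export
qc_filter_qsm <- function(trees, max_rel_ci = 0.10) {
  volcols <- grep("^vol_[0-9]+$", names(trees), value = TRUE)
  keep <- apply(as.matrix(trees[, volcols, drop = FALSE]), 1, function(v)
    qc_volume_stability(v, max_rel_ci))
  out <- trees[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Slice-wise point-density quality check for a TLS tree cloud
#'
#' For each 1 m height slice of the cloud (the uppermost slice is
#' excluded: tree tops are intrinsically sparse), the mean Euclidean
#' distance between each point and its four nearest neighbours is
#' computed. The cloud passes when every evaluated slice has a mean 4-NN
#' distance of at most `max_dist`. Slices with fewer than 5 points are
#' skipped.
#'
#' @param cloud data.frame with `x`, `y`, `z` (a single tree's points).
#' @param slice_height slice thickness (m).
#' @param max_dist pass threshold (m), default 0.05 (5 cm).
#' @return list with `pass` (logical) and `per_slice` data.frame
#'   (`z_low`, `n`, `mean_nn4`, `evaluated`).
#' @export
qc_point_density <- function(cloud, slice_height = 1.0, max_dist = 0.05) {
  z0 <- min(cloud$z)
  bin <- floor((cloud$z - z0) / slice_height)
  top <- max(bin)
  bins <- sort(unique(bin))
  rows <- lapply(bins, function(b) {
    sel <- bin == b
    n <- sum(sel)
    evaluated <- (b != top) && n >= 5
    mean_nn4 <- NA_real_
    if (evaluated) {
      d <- as.matrix(stats::dist(cloud[sel, c("x", "y", "z")]))
      diag(d) <- Inf
      nn4 <- apply(d, 1, function(r) mean(sort(r)[1:4]))
      mean_nn4 <- mean(nn4)
    }
    data.frame(z_low = z0 + b * slice_height, n = n,
               mean_nn4 = mean_nn4, evaluated = evaluated)
  })
  per_slice <- do.call(rbind, rows)
  ev <- per_slice$evaluated
  list(pass = !any(ev) || all(per_slice$mean_nn4[ev] <= max_dist),
       per_slice = per_slice)
}

#' Fit an exponential height-to-volume curve
#'
#' Least-squares fit of `V = a * b^H`: a log-linear regression supplies
#' starting values, refined by nonlinear least squares. This is the
#' exponential height term used as one of the two predictors in the
#' volume allometry.
#'
#' @param H tree heights (m).
#' @param V tree volumes (m^3), positive.
#' @return list with `a`, `b` (class `exponential_height_model`).
#' @export
fit_exponential_height <- function(H, V) {
  if (length(H) < 3) stop("fit_exponential_height: need >= 3 trees")
  if (any(V <= 0)) stop("fit_exponential_height: volumes must be positive")
  if (diff(range(H)) < 1e-9)
    stop("fit_exponential_height: degenerate height range")
  lin <- stats::lm(log(V) ~ H)
  a0 <- exp(stats::coef(lin)[[1]])
  b0 <- exp(stats::coef(lin)[[2]])
  # scaleOffset makes the convergence test well-defined on exact
  # (zero-residual) data
  fit <- tryCatch(
    stats::nls(V ~ a * b^H, start = list(a = a0, b = b0),
               control = stats::nls.control(maxiter = 200,
                                            scaleOffset = 1,
                                            warnOnly = TRUE)),
    error = function(e) NULL)
  if (is.null(fit)) {
    a <- a0; b <- b0
  } else {
    cf <- stats::coef(fit)
    a <- cf[["a"]]; b <- cf[["b"]]
  }
  structure(list(a = a, b = b), class = "exponential_height_model")
}

#' Fit the two-predictor volume allometry
#'
#' Models stem-plus-crown volume as a linear combination of projected
#' crown area and an exponential function of height, with the intercept
#' forced through the origin so small trees cannot receive negative
#' volumes:
#' `V = k_Ar * Ar + k_exp * a * b^H`.
#'
#' Two fitting routes are provided. `"two_stage"` (default) first fits
#' the exponential `a * b^H` against `V` alone, then regresses `V` on
#' `Ar` and the fitted exponential (OLS through the origin); `k_exp`
#' rescales the stage-one exponential. `"joint"` co-estimates `k_Ar`,
#' `a` and `b` by nonlinear least squares with `k_exp` fixed at 1 (the
#' product `k_exp * a` is the only identified quantity, so the joint
#' route folds it into `a`); it recovers a generating law of this exact
#' form from noiseless data to machine precision.
#'
#' The reported r-squared is computed against the *uncentred* total sum
#' of squares, the appropriate baseline for a through-origin fit.
#'
#' @param trees a [qsm_table()] (use [qc_filter_qsm()] first).
#' @param method `"two_stage"` or `"joint"`.
#' @param weighting `"ols"` (unweighted, as in a plain multiple linear
#'   regression) or `"relative"` (iteratively reweighted least squares
#'   with weights `1/fitted^2`). QSM reconstruction scatter and
#'   allometric residuals grow roughly in proportion to tree volume, so
#'   relative weighting is the likelihood-consistent choice for
#'   multiplicative errors and markedly improves coefficient recovery;
#'   `"ols"` remains the default for comparability with standard MLR
#'   practice.
#' @return An `allometric_model`: `k_Ar`, `k_exp`, `exp_model` (`a`,`b`),
#'   `r2`, `rmse`, `residual_sd`, `n`, `method`.
#' @export
fit_volume_allometry <- function(trees, method = c("two_stage", "joint"),
                                 weighting = c("ols", "relative")) {
  method <- match.arg(method)
  weighting <- match.arg(weighting)
  if (nrow(trees) < 4) stop("fit_volume_allometry: need >= 4 trees")
  H <- trees$h_m; Ar <- trees$ar_m2; V <- trees$V
  em <- fit_exponential_height(H, V)

  if (method == "two_stage") {
    g <- em$a * em$b^H
    X <- cbind(Ar = Ar, g = g)
    fit <- if (weighting == "relative")
      stats::lm.wfit(X, V, w = 1 / pmax(V, 1e-6)^2)
    else stats::lm.fit(X, V)
    k_ar <- fit$coefficients[["Ar"]]
    k_exp <- fit$coefficients[["g"]]
    fitted <- X %*% fit$coefficients
    a <- em$a; b <- em$b
  } else {
    # seed the joint fit from the two-stage solution
    g0 <- em$a * em$b^H
    ts <- stats::lm.fit(cbind(Ar, g0), V)$coefficients
    start <- list(kar = max(ts[[1]], 1e-6),
                  a = max(ts[[2]] * em$a, 1e-8), b = max(em$b, 1.0001))
    nl <- tryCatch(
      stats::nls(V ~ kar * Ar + a * b^H, start = start,
                 algorithm = "port",
                 lower = c(kar = 0, a = 1e-12, b = 1e-6),
                 control = stats::nls.control(maxiter = 500,
                                              tol = 1e-10,
                                              warnOnly = TRUE)),
      error = function(e)
        stop("fit_volume_allometry: joint fit failed: ",
             conditionMessage(e)))
    cf <- stats::coef(nl)
    k_ar <- cf[["kar"]]; a <- cf[["a"]]; b <- cf[["b"]]
    if (weighting == "relative") {
      # IRLS: refit with weights 1/fitted^2 until coefficients settle
      for (it in 1:5) {
        w <- 1 / pmax(k_ar * Ar + a * b^H, 1e-3)^2
        nl2 <- tryCatch(
          stats::nls(V ~ kar * Ar + a * b^H,
                     start = list(kar = k_ar, a = a, b = b),
                     weights = w, algorithm = "port",
                     lower = c(kar = 0, a = 1e-12, b = 1e-6),
                     control = stats::nls.control(maxiter = 200,
                                                  warnOnly = TRUE)),
          error = function(e) NULL)
        if (is.null(nl2)) break
        cf2 <- stats::coef(nl2)
        moved <- max(abs(cf2 - c(k_ar, a, b)) /
                       pmax(abs(c(k_ar, a, b)), 1e-9))
        k_ar <- cf2[["kar"]]; a <- cf2[["a"]]; b <- cf2[["b"]]
        if (moved < 1e-8) break
      }
    }
    k_exp <- 1
    fitted <- k_ar * Ar + a * b^H
  }

  resid <- V - as.vector(fitted)
  n <- length(V)
  p <- if (method == "two_stage") 2 else 3
  rss <- sum(resid^2)
  structure(list(k_Ar = k_ar, k_exp = k_exp,
                 exp_model = structure(list(a = a, b = b),
                                       class = "exponential_height_model"),
                 r2 = max(0, min(1, 1 - rss / sum(V^2))),
                 rmse = sqrt(rss / n),
                 residual_sd = sqrt(rss / max(1, n - p)),
                 n = n, method = method),
            class = "allometric_model")
}

#' @export
print.allometric_model <- function(x, ...) {
  cat(sprintf(
    "<allometric_model> V = %.4g*Ar + %.4g*(%.4g*%.4g^H)  [%s, n=%d]\n",
    x$k_Ar, x$k_exp, x$exp_model$a, x$exp_model$b, x$method, x$n))
  cat(sprintf("  r2 = %.4f (uncentred), RMSE = %.3g m3\n", x$r2, x$rmse))
  invisible(x)
}

#' Construct a height-to-radius threshold model directly
#'
#' @param alpha slope (m radius per m height).
#' @param beta intercept (m).
#' @param kind `"bt_mean"` (mean line, radius threshold for splitting) or
#'   `"split_95pi"` (upper prediction-bound line, split trigger).
#' @param n training count, if known.
#' @return A `threshold_model`.
#' @export
threshold_model <- function(alpha, beta, kind = c("bt_mean", "split_95pi"),
                            n = NA_integer_) {
  kind <- match.arg(kind)
  structure(list(alpha = alpha, beta = beta, kind = kind, n = n),
            class = "threshold_model")
}

#' @export
print.threshold_model <- function(x, ...) {
  cat(sprintf("<threshold_model %s> r = %.4f + %.4f * H (n=%s)\n",
              x$kind, x$beta, x$alpha, x$n))
  invisible(x)
}

#' Fit a height-to-radius threshold model from TLS crowns
#'
#' Both models regress equivalent crown radius `r = sqrt(Ar/pi)` on
#' maximum height `H` over the TLS (QSM) trees. `kind = "bt_mean"`
#' returns the OLS line itself — its prediction is the expected single-
#' crown radius at a given height and drives the radius threshold used
#' when carving canopies. `kind = "split_95pi"` evaluates the upper 95%
#' prediction bound at every training height and fits a straight line
#' through those bound points (the exact bound is slightly curved in
#' `H`); a crown wider than this line for its height is taken to be a
#' merged canopy. Using the prediction bound rather than the mean avoids
#' splitting legitimately large crowns.
#'
#' @param trees a [qsm_table()].
#' @param kind `"bt_mean"` or `"split_95pi"`.
#' @param level prediction-interval level for the bound line.
#' @return A [threshold_model()].
#' @export
fit_threshold_model <- function(trees, kind = c("bt_mean", "split_95pi"),
                                level = 0.95) {
  kind <- match.arg(kind)
  if (nrow(trees) < 3) stop("fit_threshold_model: need >= 3 trees")
  dat <- data.frame(H = trees$h_m, r = sqrt(trees$ar_m2 / pi))
  fit <- stats::lm(r ~ H, data = dat)
  if (kind == "bt_mean") {
    cf <- stats::coef(fit)
    return(threshold_model(alpha = cf[["H"]], beta = cf[["(Intercept)"]],
                           kind = "bt_mean", n = nrow(dat)))
  }
  upr <- stats::predict(fit, newdata = dat, interval = "prediction",
                        level = level)[, "upr"]
  line <- stats::lm(upr ~ H, data = data.frame(H = dat$H, upr = upr))
  cf <- stats::coef(line)
  threshold_model(alpha = cf[["H"]], beta = cf[["(Intercept)"]],
                  kind = "split_95pi", n = nrow(dat))
}

#' Predict tree volume from crown metrics
#'
#' Evaluates the fitted allometry `V = k_Ar*Ar + k_exp*a*b^H`. Negative
#' predictions (possible for extreme inputs despite the through-origin
#' fit) are clipped to zero; the number of clipped values is attached as
#' attribute `n_clipped`.
#'
#' @param model an `allometric_model`.
#' @param H maximum crown height(s), m.
#' @param Ar projected crown area(s), m^2.
#' @return data.frame with `V` (m^3) and `pred_sd` (residual standard
#'   deviation of the fit, m^3), with attribute `n_clipped`.
#' @export
predict_volume <- function(model, H, Ar) {
  stopifnot(length(H) == length(Ar))
  v <- model$k_Ar * Ar + model$k_exp * model$exp_model$a *
    model$exp_model$b^H
  ncl <- sum(v < 0)
  v <- pmax(v, 0)
  out <- data.frame(V = v, pred_sd = rep(model$residual_sd, length(v)))
  attr(out, "n_clipped") <- ncl
  out
}

#' Serialize fitted models to JSON
#'
#' @param model an `allometric_model` or `threshold_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  obj <- unclass(model)
  obj$.class <- class(model)
  if (!is.null(obj$exp_model)) obj$exp_model <- unclass(obj$exp_model)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a model serialized by [write_model_json()]
#' @param path JSON path.
#' @return The restored model object.
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- obj$.class
  obj$.class <- NULL
  if (!is.null(obj$exp_model))
    obj$exp_model <- structure(as.list(obj$exp_model),
                               class = "exponential_height_model")
  structure(obj, class = cls)
}
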