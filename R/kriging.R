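#' Ordinary kriging with a local neighbourhood
#'
#' Best linear unbiased prediction under an unknown constant mean: for each
#' target location the kriging system is solved on the `neighborhood` nearest
#' samples, with weights constrained to sum to 1. The covariance used is
#' `C(h) = c * rho(h)` for `h > 0` and `C(0) = c0 + c`, so a prediction at a
#' sampled location reproduces the observed value exactly.
#'
#' @param model A `variogram_model` (from [fit_variogram_ml()] or
#'   [variogram_model()]).
#' @param samples Data frame with `x`, `y`, `value`.
#' @param targets Data frame with `x`, `y` of prediction locations.
#' @param neighborhood Number of nearest samples used per prediction (default
#'   64, capped at the number of samples).
#' @return A tibble: `x`, `y`, `estimate`, `kriging_variance`.
#' @export
ordinary_kriging <- function(model, samples, targets, neighborhood = 64) {
  stopifnot(inherits(model, "variogram_model"))
  check_columns(samples, c("x", "y", "value"), "sample table")
  check_columns(targets, c("x", "y"), "target table")
  ok <- krige_engine(model, samples, as.matrix(targets[, c("x", "y")]),
                     neighborhood)
  tibble::tibble(x = targets$x, y = targets$y,
                 estimate = ok$estimate, kriging_variance = ok$variance)
}

# internal: vectorized OK solver. exclude_self drops a sample at zero distance
# from its own neighbourhood (leave-one-out mode). Returns estimates,
# variances, and the weight-sum diagnostic.
krige_engine <- function(model, samples, target_xy, neighborhood,
                         exclude_self = FALSE) {
  sxy <- as.matrix(samples[, c("x", "y")])
  z <- samples$value
  n <- nrow(sxy)
  k <- min(neighborhood, n - as.integer(exclude_self))
  if (k < 1) fb_abort("not enough samples for the requested neighbourhood",
                      "too_few_samples")
  c0 <- model$nugget
  c1 <- model$psill
  sill <- c0 + c1
  # between distinct measurements the nugget does not correlate, so
  # sample-sample covariance at h = 0 keeps only the partial sill; the
  # diagonal carries the full sill. Target-sample covariance at h = 0 uses
  # the full sill so predictions honour the data exactly.
  cov_fun <- function(h) c1 * matern_correlation(h, model$range, model$nu)
  m <- nrow(target_xy)
  est <- numeric(m)
  kv <- numeric(m)
  wsum <- numeric(m)
  for (i in seq_len(m)) {
    dx <- sxy[, 1] - target_xy[i, 1]
    dy <- sxy[, 2] - target_xy[i, 2]
    d <- sqrt(dx * dx + dy * dy)
    if (exclude_self) d[which.min(d)] <- Inf
    nb <- order(d)[seq_len(k)]
    Dn <- as.matrix(dist(sxy[nb, , drop = FALSE]))
    C <- cov_fun(Dn)
    diag(C) <- sill
    A <- rbind(cbind(C, 1), c(rep(1, k), 0))
    b0 <- cov_fun(d[nb])
    b0[d[nb] == 0] <- sill
    b <- c(b0, 1)
    sol <- tryCatch(solve(A, b), error = function(e) {
      fb_abort(paste0(
        "singular kriging system at target ", i,
        "; add a nugget or jitter duplicate coordinates"), "singular_system")
    })
    w <- sol[seq_len(k)]
    est[i] <- sum(w * z[nb])
    v <- sill - sum(w * b[seq_len(k)]) - sol[k + 1]
    kv[i] <- max(v, 0)
    wsum[i] <- sum(w)
  }
  list(estimate = est, variance = kv, weight_sum = wsum)
}

#' Leave-one-out cross-validation of a kriging model
#'
#' Each site is predicted from all remaining sites with the fixed fitted
#' model. The standardized squared prediction error (SSPE) is
#' `theta_i = (z_i - zhat_{-i})^2 / sigma2_{k,-i}`; under a well-specified
#' model theta is approximately chi-squared with 1 df, so its mean should be
#' near 1 and its median near 0.455. The squared correlation of observed vs
#' predicted values is reported as the LOO r-squared.
#'
#' @inheritParams ordinary_kriging
#' @return An object of class `kriging_cv`: list with `sites` (per-site
#'   tibble: `x`, `y`, `observed`, `predicted`, `kriging_variance`, `sspe`)
#'   and summary fields `mean_sspe`, `median_sspe`, `r_squared`, `n`.
#' @export
loo_cross_validation <- function(model, samples, neighborhood = 64) {
  stopifnot(inherits(model, "variogram_model"))
  check_columns(samples, c("x", "y", "value"), "sample table")
  if (nrow(samples) < 3) fb_abort("need >= 3 samples for LOO", "too_few_samples")
  ok <- krige_engine(model, samples, as.matrix(samples[, c("x", "y")]),
                     neighborhood, exclude_self = TRUE)
  sspe <- (samples$value - ok$estimate)^2 / ok$variance
  sspe[ok$variance == 0 & (samples$value - ok$estimate)^2 == 0] <- 0
  sites <- tibble::tibble(
    x = samples$x, y = samples$y, observed = samples$value,
    predicted = ok$estimate, kriging_variance = ok$variance, sspe = sspe
  )
  structure(
    list(
      sites = sites,
      mean_sspe = mean(sspe),
      median_sspe = median(sspe),
      r_squared = suppressWarnings(cor(samples$value, ok$estimate)^2),
      n = nrow(samples)
    ),
    class = "kriging_cv"
  )
}

#' @export
print.kriging_cv <- function(x, ...) {
  cat("Leave-one-out kriging cross-validation (n =", x$n, ")\n")
  cat(sprintf("  mean SSPE %.3f (ideal 1), median SSPE %.3f (ideal 0.455)\n",
              x$mean_sspe, x$median_sspe))
  cat(sprintf("  LOO r^2 (observed vs predicted): %.3f\n", x$r_squared))
  invisible(x)
}

#' @method glance kriging_cv
#' @export
glance.kriging_cv <- function(x, ...) {
  tibble::tibble(mean_sspe = x$mean_sspe, median_sspe = x$median_sspe,
                 r_squared = x$r_squared, n = x$n)
}

#' @method tidy kriging_cv
#' @export
tidy.kriging_cv <- function(x, ...) x$sites

#' Krige onto a regular grid
#'
#' Predicts every node of a regular grid covering `bbox` (default: the sample
#' bounding box) at `resolution_km` spacing. An optional `mask` function
#' `(x, y) -> logical` excludes nodes outside the territory.
#'
#' @inheritParams ordinary_kriging
#' @param bbox Numeric vector `c(xmin, xmax, ymin, ymax)`; defaults to the
#'   sample bounding box.
#' @param resolution_km Node spacing (km).
#' @param mask Optional vectorized predicate keeping nodes where `TRUE`.
#' @return A tibble of class `kriging_grid`: `x`, `y`, `estimate`,
#'   `kriging_variance`, with the resolution stored as an attribute.
#' @export
krige_grid <- function(model, samples, bbox = NULL, resolution_km = 16,
                       neighborhood = 64, mask = NULL) {
  check_columns(samples, c("x", "y", "value"), "sample table")
  if (is.null(bbox)) {
    bbox <- c(min(samples$x), max(samples$x), min(samples$y), max(samples$y))
  }
  stopifnot(length(bbox) == 4, bbox[1] <= bbox[2], bbox[3] <= bbox[4])
  gx <- seq(bbox[1], bbox[2], by = resolution_km)
  gy <- seq(bbox[3], bbox[4], by = resolution_km)
  nodes <- tidyr::expand_grid(x = gx, y = gy)
  if (!is.null(mask)) nodes <- dplyr::filter(nodes, mask(.data$x, .data$y))
  out <- ordinary_kriging(model, samples, nodes, neighborhood)
  attr(out, "resolution_km") <- resolution_km
  class(out) <- c("kriging_grid", class(out))
  out
}

#' Map a kriged grid
#'
#' @param object A [krige_grid()] result.
#' @param what `"estimate"` or `"kriging_variance"`.
#' @param ... Unused.
#' @return A ggplot tile map.
#' @method autoplot kriging_grid
#' @export
autoplot.kriging_grid <- function(object, what = c("estimate",
                                                   "kriging_variance"), ...) {
  what <- match.arg(what)
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$x, y = .data$y,
                               fill = .data[[what]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = what) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (km)", y = "y (km)") +
    ggplot2::theme_minimal()
}
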