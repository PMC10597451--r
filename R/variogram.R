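#' Matern correlation function
#'
#' `rho(h) = 2^(1-nu)/Gamma(nu) * (h/a)^nu * K_nu(h/a)` with `rho(0) = 1`.
#' The half-integer smoothness values used as the default candidate grid have
#' closed forms (no Bessel evaluation): `nu = 0.5` is the exponential model
#' `exp(-h/a)`, `nu = 1.5` is `(1 + x) exp(-x)` and `nu = 2.5` is
#' `(1 + x + x^2/3) exp(-x)` with `x = h/a`.
#'
#' @param h Distances (km), `>= 0`.
#' @param range Matern distance parameter `a` (km), `> 0`.
#' @param nu Smoothness, `> 0`.
#' @return Correlations in `[0, 1]`.
#' @export
matern_correlation <- function(h, range, nu) {
  stopifnot(range > 0, nu > 0, all(h >= 0))
  x <- h / range
  if (isTRUE(all.equal(nu, 0.5))) {
    exp(-x)
  } else if (isTRUE(all.equal(nu, 1.5))) {
    (1 + x) * exp(-x)
  } else if (isTRUE(all.equal(nu, 2.5))) {
    (1 + x + x^2 / 3) * exp(-x)
  } else {
    out <- rep(1, length(x))
    pos <- x > 0
    xp <- x[pos]
    out[pos] <- 2^(1 - nu) / gamma(nu) * xp^nu * besselK(xp, nu)
    # besselK underflows to 0 at large arguments, which is the right limit
    out[pos][!is.finite(out[pos])] <- 0
    out
  }
}

#' Matern semivariance
#'
#' `gamma(h) = c0 + c * (1 - rho(h))` for `h > 0`, with `gamma(0) = 0` by
#' convention (the nugget `c0` is the limit from above).
#'
#' @param h Distances (km).
#' @param nugget Nugget semivariance `c0 >= 0`.
#' @param psill Partial sill `c >= 0`.
#' @param range,nu Matern parameters, see [matern_correlation()].
#' @return Semivariances.
#' @export
matern_semivariance <- function(h, nugget, psill, range, nu = 0.5) {
  stopifnot(nugget >= 0, psill >= 0)
  g <- nugget + psill * (1 - matern_correlation(h, range, nu))
  g[h == 0] <- 0
  g
}

#' Empirical (experimental) variogram
#'
#' Matheron's estimator: pairs are binned by separation distance and
#' `gamma_hat(h) = sum (z_i - z_j)^2 / (2 N(h))` within each bin. Diagnostic
#' only — model fitting uses maximum likelihood, not least squares on bins.
#'
#' @param samples Data frame with columns `x`, `y` (projected km) and `value`.
#' @param lag_width Bin width (km).
#' @param max_dist Maximum pair separation retained; defaults to one third of
#'   the bounding-box diagonal.
#' @return A tibble of class `empirical_variogram`: `lag` (bin centre, km),
#'   `gamma`, `n_pairs`; zero-pair bins are dropped.
#' @export
empirical_variogram <- function(samples, lag_width = 10, max_dist = NULL) {
  check_columns(samples, c("x", "y", "value"), "sample table")
  if (nrow(samples) < 2) fb_abort("need >= 2 samples", "too_few_samples")
  stopifnot(lag_width > 0)
  d <- dist(cbind(samples$x, samples$y))
  if (is.null(max_dist)) {
    max_dist <- sqrt(diff(range(samples$x))^2 + diff(range(samples$y))^2) / 3
  }
  dv <- as.numeric(d)
  sq <- as.numeric(dist(samples$value))^2
  keep <- dv <= max_dist & dv > 0
  if (!any(keep)) fb_abort("no sample pairs within max_dist", "no_pairs")
  bin <- floor(dv[keep] / lag_width)
  gam <- tapply(sq[keep], bin, function(s) sum(s) / (2 * length(s)))
  np <- tapply(sq[keep], bin, length)
  out <- tibble::tibble(
    lag = (as.numeric(names(gam)) + 0.5) * lag_width,
    gamma = as.numeric(gam),
    n_pairs = as.integer(np)
  )
  class(out) <- c("empirical_variogram", class(out))
  out
}

# internal: profile negative log-likelihood of a constant-mean Gaussian field.
# Sigma = sigma2 * (R(a) + eta*I); the mean and sigma2 are profiled out, so the
# optimizer only sees (log a, log eta). Returns +Inf on a failed factorization.
profile_nll <- function(par, D, z, nu) {
  a <- exp(par[1])
  eta <- exp(par[2])
  n <- length(z)
  V <- matern_correlation(D, a, nu)
  diag(V) <- 1 + eta
  L <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(L)) return(1e10)
  logdet <- 2 * sum(log(diag(L)))
  one <- rep(1, n)
  Vi_z <- backsolve(L, forwardsolve(t(L), z))
  Vi_1 <- backsolve(L, forwardsolve(t(L), one))
  mu <- sum(Vi_z) / sum(Vi_1)
  r <- z - mu
  Q <- sum(r * (Vi_z - mu * Vi_1))
  if (Q <= 0) return(1e10)
  0.5 * (n * log(2 * pi) + n * log(Q / n) + logdet + n)
}

#' Fit a Matern variogram model by maximum likelihood
#'
#' Maximizes the Gaussian likelihood of a constant-mean spatial process with
#' covariance `C(h) = c * rho_Matern(h; a, nu) + c0 * 1{h = 0}`. The mean and
#' the overall variance are profiled out analytically, so the optimizer works
#' on `(log a, log(c0/c))` only; the smoothness `nu` is selected over a
#' discrete candidate grid (the likelihood is notoriously flat in continuous
#' `nu`), keeping fits reproducible. Among candidates the model with the
#' smallest negative log-likelihood is returned.
#'
#' @param samples Data frame with columns `x`, `y`, `value`.
#' @param nu_candidates Candidate smoothness values (default `c(0.5, 1.5,
#'   2.5)`).
#' @param init Optional named list `list(range =, nugget_ratio =)` overriding
#'   the data-driven initialization.
#' @return An object of class `variogram_model`: `nugget`, `psill`, `range`,
#'   `nu`, `effective_range` (95% practical range, `NA` for a pure-nugget
#'   fit), `neg_loglik`, `mean`, `n`, `pure_nugget` flag, `convergence`.
#' @export
fit_variogram_ml <- function(samples, nu_candidates = c(0.5, 1.5, 2.5),
                             init = NULL) {
  check_columns(samples, c("x", "y", "value"), "sample table")
  z <- samples$value
  n <- length(z)
  if (n < 3) fb_abort("need >= 3 samples for a likelihood fit",
                      "too_few_samples")
  D <- as.matrix(dist(cbind(samples$x, samples$y)))
  mean_dist <- mean(D[upper.tri(D)])
  a0 <- init$range %||% (mean_dist / 4)
  eta0 <- init$nugget_ratio %||% 0.5
  best <- NULL
  for (nu in nu_candidates) {
    opt <- optim(
      c(log(a0), log(eta0)), profile_nll,
      D = D, z = z, nu = nu, method = "Nelder-Mead",
      control = list(maxit = 500, reltol = 1e-8)
    )
    if (opt$value >= 1e10) next
    if (is.null(best) || opt$value < best$value) {
      best <- list(value = opt$value, par = opt$par, nu = nu,
                   convergence = opt$convergence)
    }
  }
  if (is.null(best)) {
    fb_abort("variogram likelihood optimization failed to converge",
             "no_convergence")
  }
  a <- exp(best$par[1])
  eta <- exp(best$par[2])
  # recover the profiled variance and mean at the optimum
  V <- matern_correlation(D, a, best$nu)
  diag(V) <- 1 + eta
  L <- chol(V)
  one <- rep(1, n)
  Vi_z <- backsolve(L, forwardsolve(t(L), z))
  Vi_1 <- backsolve(L, forwardsolve(t(L), one))
  mu <- sum(Vi_z) / sum(Vi_1)
  r <- z - mu
  sigma2 <- sum(r * (Vi_z - mu * Vi_1)) / n
  psill <- sigma2
  nugget <- eta * sigma2
  pure_nugget <- psill < 0.05 * (psill + nugget)
  model <- structure(
    list(
      nugget = nugget, psill = psill, range = a, nu = best$nu,
      effective_range = NA_real_, neg_loglik = best$value, mean = mu,
      n = n, pure_nugget = pure_nugget, convergence = best$convergence
    ),
    class = "variogram_model"
  )
  model$effective_range <- effective_range(model)
  model
}

#' Build a variogram model from known parameters
#'
#' Useful for kriging with planted or externally fitted parameters.
#'
#' @inheritParams matern_semivariance
#' @param mean Constant process mean (used only as metadata).
#' @return A `variogram_model` object.
#' @export
variogram_model <- function(nugget, psill, range, nu = 0.5, mean = 0) {
  stopifnot(nugget >= 0, psill >= 0, range > 0, nu > 0)
  model <- structure(
    list(nugget = nugget, psill = psill, range = range, nu = nu,
         effective_range = NA_real_, neg_loglik = NA_real_, mean = mean,
         n = NA_integer_, pure_nugget = psill == 0, convergence = 0L),
    class = "variogram_model"
  )
  model$effective_range <- effective_range(model)
  model
}

#' Practical (95%) autocorrelation range
#'
#' The smallest distance at which the semivariance reaches 95% of the partial
#' sill above the nugget, i.e. where the Matern correlation drops to 0.05,
#' found numerically. For the exponential model (`nu = 0.5`) this is
#' `-log(0.05) * a`, about `3 a`. Undefined (`NA`) for a pure-nugget model.
#'
#' @param model A `variogram_model`.
#' @return Distance in km, or `NA` for a pure-nugget model.
#' @export
effective_range <- function(model) {
  stopifnot(inherits(model, "variogram_model"))
  if (model$psill <= 0 || isTRUE(model$pure_nugget)) return(NA_real_)
  f <- function(h) matern_correlation(h, model$range, model$nu) - 0.05
  upper <- model$range
  while (f(upper) > 0 && upper < 1e8 * model$range) upper <- upper * 2
  uniroot(f, lower = 1e-12 * model$range, upper = upper,
          tol = 1e-10 * model$range)$root
}

#' @export
print.variogram_model <- function(x, ...) {
  cat("Matern variogram model (ML fit)\n")
  cat(sprintf("  nugget %.4g, partial sill %.4g, range %.4g km, nu %.2g\n",
              x$nugget, x$psill, x$range, x$nu))
  cat(sprintf("  effective (95%%) range: %s km\n",
              ifelse(is.na(x$effective_range), "undefined (pure nugget)",
                     sprintf("%.1f", x$effective_range))))
  if (!is.na(x$neg_loglik)) {
    cat(sprintf("  neg. log-likelihood %.2f (n = %d)\n", x$neg_loglik, x$n))
  }
  invisible(x)
}

#' @method glance variogram_model
#' @export
glance.variogram_model <- function(x, ...) {
  tibble::tibble(
    nugget = x$nugget, psill = x$psill, range_km = x$range, nu = x$nu,
    effective_range_km = x$effective_range, neg_loglik = x$neg_loglik,
    n = x$n, pure_nugget = x$pure_nugget
  )
}

#' Plot an empirical variogram with an optional fitted model curve
#'
#' @param object An [empirical_variogram()] tibble.
#' @param model Optional `variogram_model` overlay.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot empirical_variogram
#' @export
autoplot.empirical_variogram <- function(object, model = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$lag, y = .data$gamma)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_pairs), alpha = 0.7) +
    ggplot2::scale_size_area(name = "pairs") +
    ggplot2::labs(x = "separation distance h (km)",
                  y = expression(hat(gamma)(h))) +
    ggplot2::theme_minimal()
  if (!is.null(model)) {
    h <- seq(0, max(object$lag), length.out = 200)
    curve_df <- tibble::tibble(
      lag = h,
      gamma = matern_semivariance(h, model$nugget, model$psill,
                                  model$range, model$nu)
    )
    p <- p + ggplot2::geom_line(data = curve_df, colour = "firebrick")
  }
  p
}
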