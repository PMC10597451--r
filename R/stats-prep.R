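#' Shapiro-Wilk normality screen
#'
#' Thin wrapper around [stats::shapiro.test()] returning a tidy one-row
#' tibble; used to decide whether a response needs a Box-Cox transform before
#' downstream modelling.
#'
#' @param x Numeric vector, `3 <= length(x) <= 5000`, non-constant.
#' @return A tibble: `statistic` (W), `p_value`, `n`.
#' @export
shapiro_normality <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3 || n > 5000) {
    fb_abort("Shapiro-Wilk requires 3 <= n <= 5000", "bad_n")
  }
  if (sd(x) == 0) fb_abort("constant vector: normality test undefined",
                           "zero_variance")
  sw <- shapiro.test(x)
  tibble::tibble(statistic = unname(sw$statistic),
                 p_value = sw$p.value, n = n)
}

#' Box-Cox lambda by profile likelihood
#'
#' Maximizes the Box-Cox normal profile log-likelihood
#' `-(n/2) log(sigma2_hat(lambda)) + (lambda - 1) sum(log x)` over
#' `lambda` in `[lower, upper]` by golden-section search. The profile
#' criterion (rather than a seasonal-strength heuristic) targets an
#' approximately Gaussian residual distribution.
#'
#' @param x Positive numeric vector.
#' @param lower,upper Search interval for lambda (default `[-2, 2]`).
#' @return The maximizing lambda.
#' @export
boxcox_lambda <- function(x, lower = -2, upper = 2) {
  x <- x[!is.na(x)]
  if (any(x <= 0)) {
    fb_abort("Box-Cox requires strictly positive values; add a shift first",
             "nonpositive")
  }
  n <- length(x)
  if (n < 3) fb_abort("need >= 3 values", "bad_n")
  slx <- sum(log(x))
  prof <- function(lambda) {
    y <- boxcox_transform(x, lambda)
    s2 <- mean((y - mean(y))^2)
    -(n / 2) * log(s2) + (lambda - 1) * slx
  }
  optimize(prof, c(lower, upper), maximum = TRUE, tol = 1e-6)$maximum
}

#' Apply / invert a Box-Cox transform
#'
#' `(x^lambda - 1) / lambda` for `lambda != 0` and `log(x)` for `lambda = 0`
#' (the definitional limit), after an optional non-negative `shift`. The
#' transform is strictly increasing for every lambda, so ranks are preserved.
#'
#' @param x Values to transform (shifted values must be positive).
#' @param lambda Box-Cox exponent.
#' @param shift Additive offset applied before transforming (`>= 0`).
#' @return Transformed values.
#' @export
boxcox_transform <- function(x, lambda, shift = 0) {
  stopifnot(shift >= 0)
  xs <- x + shift
  if (any(!is.na(xs) & xs <= 0)) {
    fb_abort("Box-Cox domain violation: shifted values must be > 0",
             "nonpositive")
  }
  if (abs(lambda) < 1e-12) log(xs) else (xs^lambda - 1) / lambda
}

#' @rdname boxcox_transform
#' @param y Transformed values to invert.
#' @export
boxcox_inverse <- function(y, lambda, shift = 0) {
  if (abs(lambda) < 1e-12) exp(y) - shift
  else (lambda * y + 1)^(1 / lambda) - shift
}

#' Iterative Grubbs outlier filter
#'
#' One Grubbs step tests the single most extreme point:
#' `G = max|x_i - mean(x)| / sd(x)` against the two-sided critical value
#' `G_crit = ((n-1)/sqrt(n)) * sqrt(t^2 / (n - 2 + t^2))` with
#' `t = qt(1 - alpha/(2n), n - 2)`. While significant, the extreme point is
#' removed and the test repeated, up to `max_iter` removals (the cap prevents
#' pathological stripping of a heavy-tailed sample). Ties are broken by first
#' index, so removal order is deterministic.
#'
#' @param x Numeric vector, `n >= 3`.
#' @param alpha Two-sided significance level per iteration (default 0.05).
#' @param max_iter Maximum number of removals (default 5).
#' @return An object of class `grubbs_report`: list with `values` (cleaned
#'   vector), `removed_indices` (positions in the original `x`), and `trace`
#'   (tibble: `iteration`, `index`, `value`, `g`, `g_critical`, `removed`).
#' @export
grubbs_filter <- function(x, alpha = 0.05, max_iter = 5) {
  if (sum(!is.na(x)) < 3) fb_abort("Grubbs test requires n >= 3", "bad_n")
  idx <- seq_along(x)
  keep <- !is.na(x)
  work_x <- x[keep]
  work_i <- idx[keep]
  trace <- list()
  removed <- integer(0)
  for (iter in seq_len(max_iter)) {
    n <- length(work_x)
    if (n < 3) break
    m <- mean(work_x)
    s <- sd(work_x)
    if (s == 0) break
    dev <- abs(work_x - m)
    j <- which.max(dev)  # which.max takes the first index on ties
    g <- dev[j] / s
    gcrit <- grubbs_critical(n, alpha)
    sig <- g > gcrit
    trace[[iter]] <- tibble::tibble(
      iteration = iter, index = work_i[j], value = work_x[j],
      g = g, g_critical = gcrit, removed = sig
    )
    if (!sig) break
    removed <- c(removed, work_i[j])
    work_x <- work_x[-j]
    work_i <- work_i[-j]
  }
  structure(
    list(
      values = work_x,
      removed_indices = removed,
      trace = if (length(trace)) dplyr::bind_rows(trace) else
        tibble::tibble(iteration = integer(), index = integer(),
                       value = numeric(), g = numeric(),
                       g_critical = numeric(), removed = logical()),
      alpha = alpha
    ),
    class = "grubbs_report"
  )
}

#' Two-sided Grubbs critical value
#'
#' @param n Sample size (`>= 3`).
#' @param alpha Two-sided level.
#' @return The critical G.
#' @export
grubbs_critical <- function(n, alpha = 0.05) {
  stopifnot(n >= 3)
  t <- qt(1 - alpha / (2 * n), n - 2)
  (n - 1) / sqrt(n) * sqrt(t^2 / (n - 2 + t^2))
}

#' @export
print.grubbs_report <- function(x, ...) {
  cat("Grubbs outlier filter (alpha =", x$alpha, ")\n")
  cat("  removed", length(x$removed_indices), "value(s)")
  if (length(x$removed_indices)) {
    cat(" at index:", paste(x$removed_indices, collapse = ", "))
  }
  cat("\n")
  invisible(x)
}

#' @method tidy grubbs_report
#' @export
tidy.grubbs_report <- function(x, ...) x$trace

#' Condition a response for downstream modelling
#'
#' The shared preparation chain: Shapiro-Wilk normality screen; if rejected
#' (at `normality_alpha`), Box-Cox transform with profile-likelihood lambda
#' (a log transform when `force_log`); then iterative Grubbs outlier removal
#' on the transformed scale. Subsequent models run on the returned values;
#' the transform spec makes every result reproducible from raw data.
#'
#' @param x Raw response vector (positive if a transform is needed).
#' @param normality_alpha Shapiro rejection level (default 0.05).
#' @param grubbs_alpha,max_iter Passed to [grubbs_filter()].
#' @param force_log Use a log transform (lambda = 0) instead of estimating
#'   lambda.
#' @return An object of class `prepared_response`: `values` (cleaned,
#'   transformed), `keep` (logical index into `x` of retained observations),
#'   `transform` (list: `kind`, `lambda`, `shift`), `shapiro` (tibble),
#'   `outliers` (grubbs_report).
#' @export
prepare_response <- function(x, normality_alpha = 0.05, grubbs_alpha = 0.05,
                             max_iter = 5, force_log = FALSE) {
  sw <- shapiro_normality(x)
  if (sw$p_value < normality_alpha) {
    if (force_log) {
      transform <- list(kind = "log", lambda = 0, shift = 0)
    } else {
      transform <- list(kind = "boxcox", lambda = boxcox_lambda(x), shift = 0)
    }
  } else {
    transform <- list(kind = "identity", lambda = 1, shift = 0)
  }
  y <- if (transform$kind == "identity") x else
    boxcox_transform(x, transform$lambda, transform$shift)
  gr <- grubbs_filter(y, alpha = grubbs_alpha, max_iter = max_iter)
  keep <- !is.na(x)
  keep[gr$removed_indices] <- FALSE
  structure(
    list(values = y[keep], keep = keep, transform = transform,
         shapiro = sw, outliers = gr),
    class = "prepared_response"
  )
}

#' @export
print.prepared_response <- function(x, ...) {
  cat("Prepared response: transform =", x$transform$kind)
  if (x$transform$kind == "boxcox") {
    cat(sprintf(" (lambda = %.3f)", x$transform$lambda))
  }
  cat(";", length(x$outliers$removed_indices), "outlier(s) removed\n")
  invisible(x)
}
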