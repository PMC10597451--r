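#' Environmental driver analysis by (partial) redundancy analysis
#'
#' For a univariate standardized response, redundancy analysis reduces to
#' ordinary least squares: the explained fraction is `R^2 =
#' var(fitted)/var(y)` and the partitioned currency is the Ezekiel-adjusted
#' `R^2 = 1 - (1 - R^2)(n - 1)/(n - p - 1)`. Quantitative predictors are
#' standardized to zero mean and unit variance so coefficients are
#' comparable; categorical predictors enter as treatment-coded 0/1 dummies
#' with coefficients reported on that scale.
#'
#' @name variance_partitioning
NULL

# internal: run code under a temporary RNG state without disturbing the
# caller's stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# internal: standardized design matrix; numeric columns scaled, categorical
# columns treatment-dummied on the 0/1 scale
design_matrix <- function(data, cols) {
  if (length(cols) == 0) return(NULL)
  check_columns(data, cols, "predictor table")
  mats <- lapply(cols, function(cn) {
    v <- data[[cn]]
    if (is.numeric(v)) {
      if (sd(v) == 0) fb_abort(paste0("constant predictor: ", cn),
                               "zero_variance")
      m <- matrix((v - mean(v)) / sd(v), ncol = 1)
      colnames(m) <- cn
      m
    } else {
      f <- factor(v)
      if (nlevels(f) < 2) fb_abort(paste0("constant predictor: ", cn),
                                   "zero_variance")
      m <- stats::model.matrix(~f)[, -1, drop = FALSE]
      colnames(m) <- paste0(cn, "_", levels(f)[-1])
      m
    }
  })
  do.call(cbind, mats)
}

# internal: R^2 and rank of y on [1 X] via QR; X may be NULL (null model)
ols_r2 <- function(y, X) {
  n <- length(y)
  tss <- sum((y - mean(y))^2)
  if (is.null(X) || ncol(X) == 0) {
    return(list(r2 = 0, rank = 0L, fitted = rep(mean(y), n),
                residuals = y - mean(y)))
  }
  q <- qr(cbind(1, X))
  fitted <- qr.fitted(q, y)
  r2 <- 1 - sum((y - fitted)^2) / tss
  list(r2 = r2, rank = q$rank - 1L, fitted = fitted,
       residuals = y - fitted)
}

adj_r2 <- function(r2, n, p) 1 - (1 - r2) * (n - 1) / (n - p - 1)

#' Iterative VIF collinearity filter
#'
#' Repeatedly removes the quantitative predictor with the largest variance
#' inflation factor `VIF_j = 1/(1 - R^2_j)` (from regressing column j on the
#' other retained columns) until all VIFs are at or below `threshold`.
#' Categorical columns are exempt (dummies of one factor are structurally
#' correlated) and are passed through untouched. Exact duplicates are removed
#' before iteration and logged in the trace.
#'
#' @param data Site table.
#' @param cols Quantitative predictor columns to screen (default: all numeric
#'   columns of `data`).
#' @param threshold Maximum tolerated VIF (default 5).
#' @return A list: `retained` (column names), `removed`, `trace` (tibble:
#'   `step`, `column`, `vif`, `action`), `vif` (final per-column VIFs).
#' @export
vif_filter <- function(data, cols = NULL, threshold = 5) {
  if (is.null(cols)) cols <- names(data)[vapply(data, is.numeric, logical(1))]
  if (length(cols) < 2) fb_abort("need >= 2 quantitative columns",
                                 "too_few_columns")
  X <- design_matrix(data, cols)
  if (nrow(X) <= ncol(X)) fb_abort("need more rows than columns", "bad_n")
  trace <- list()
  step <- 0L
  # drop exact duplicates up front so the iterated regressions are sane
  dup <- duplicated(t(X))
  for (j in which(dup)) {
    step <- step + 1L
    trace[[step]] <- tibble::tibble(step = step, column = colnames(X)[j],
                                    vif = Inf, action = "duplicate")
  }
  keep <- colnames(X)[!dup]
  vifs <- NULL
  repeat {
    if (length(keep) < 2) break
    vifs <- vapply(keep, function(cn) {
      r2 <- ols_r2(X[, cn], X[, setdiff(keep, cn), drop = FALSE])$r2
      1 / (1 - min(r2, 1 - 1e-12))
    }, numeric(1))
    worst <- which.max(vifs)
    if (vifs[worst] <= threshold) break
    step <- step + 1L
    trace[[step]] <- tibble::tibble(step = step, column = keep[worst],
                                    vif = unname(vifs[worst]),
                                    action = "removed")
    keep <- keep[-worst]
  }
  list(
    retained = keep,
    removed = setdiff(cols, keep),
    trace = if (length(trace)) dplyr::bind_rows(trace) else
      tibble::tibble(step = integer(), column = character(),
                     vif = numeric(), action = character()),
    vif = vifs
  )
}

#' Exhaustive best-subset screen by BIC
#'
#' Enumerates every predictor subset up to `max_size`, fits the linear model,
#' and returns the subset minimizing BIC, together with the best model and
#' adjusted R-squared per size. Intended as the second selection step after
#' VIF filtering, so the candidate pool must already be small (<= 20
#' columns).
#'
#' @param data Site table.
#' @param response Response column name.
#' @param candidates Candidate predictor column names.
#' @param max_size Largest subset enumerated (default
#'   `min(8, length(candidates))`).
#' @return A list: `selected` (column names of the BIC-best subset, possibly
#'   empty), `by_size` (tibble: `size`, `bic`, `adj_r_squared`, `terms`),
#'   `null_bic`.
#' @export
best_subset_bic <- function(data, response, candidates,
                            max_size = min(8, length(candidates))) {
  if (length(candidates) > 20) {
    fb_abort("more than 20 candidates: pre-filter (e.g. vif_filter) first",
             "too_many_columns")
  }
  check_columns(data, c(response, candidates), "site table")
  y <- data[[response]]
  y <- (y - mean(y)) / sd(y)
  X <- design_matrix(data, candidates)
  n <- length(y)
  bic_of <- function(rss, p) n * log(rss / n) + (p + 1) * log(n)
  null_bic <- bic_of(sum((y - mean(y))^2), 0)
  best <- list(bic = null_bic, terms = character(0), size = 0L, adj = 0)
  by_size <- list(tibble::tibble(size = 0L, bic = null_bic,
                                 adj_r_squared = 0, terms = ""))
  # enumerate subsets of *input columns*; a categorical column enters with
  # all its dummies
  col_groups <- lapply(candidates, function(cn) {
    if (is.numeric(data[[cn]])) cn else
      colnames(X)[startsWith(colnames(X), paste0(cn, "_"))]
  })
  names(col_groups) <- candidates
  for (size in seq_len(min(max_size, length(candidates)))) {
    combos <- combn(candidates, size, simplify = FALSE)
    size_best <- NULL
    for (cb in combos) {
      sel_cols <- unlist(col_groups[cb], use.names = FALSE)
      fit <- ols_r2(y, X[, sel_cols, drop = FALSE])
      rss <- sum(fit$residuals^2)
      b <- bic_of(rss, fit$rank)
      a <- adj_r2(fit$r2, n, fit$rank)
      if (is.null(size_best) || b < size_best$bic) {
        size_best <- list(bic = b, terms = cb, adj = a)
      }
      if (b < best$bic) best <- list(bic = b, terms = cb, size = size, adj = a)
    }
    by_size[[size + 1]] <- tibble::tibble(
      size = size, bic = size_best$bic, adj_r_squared = size_best$adj,
      terms = paste(size_best$terms, collapse = "+"))
  }
  list(selected = best$terms, by_size = dplyr::bind_rows(by_size),
       null_bic = null_bic,
       worse_than_null = length(best$terms) > 0 && best$bic >= null_bic)
}

#' Fit a univariate redundancy analysis (standardized OLS)
#'
#' @param data Site table.
#' @param response Response column name (standardized internally).
#' @param predictors Predictor column names.
#' @return An object of class `rda_fit`: `r_squared`, `adj_r_squared`,
#'   `pseudo_f`, `df_model`, `df_resid`, `n`, `coefficients` (tibble: `term`,
#'   `estimate`), `dropped` (aliased columns removed), plus the internal
#'   response/design (for permutation machinery).
#' @export
rda_fit <- function(data, response, predictors) {
  check_columns(data, response, "site table")
  y <- data[[response]]
  if (any(is.na(y))) fb_abort("response contains missing values; prepare first",
                              "missing_values")
  y <- (y - mean(y)) / sd(y)
  X <- design_matrix(data, predictors)
  n <- length(y)
  if (!is.null(X) && n <= ncol(X) + 1) {
    fb_abort("need n > number of predictor columns + 1", "bad_n")
  }
  dropped <- character(0)
  if (!is.null(X)) {
    q <- qr(cbind(1, X))
    if (q$rank < ncol(X) + 1) {
      keep_idx <- q$pivot[seq_len(q$rank)]
      keep_idx <- setdiff(keep_idx, 1) - 1
      dropped <- setdiff(colnames(X), colnames(X)[keep_idx])
      X <- X[, keep_idx, drop = FALSE]
    }
  }
  fit <- ols_r2(y, X)
  p <- fit$rank
  r2 <- fit$r2
  ar2 <- adj_r2(r2, n, p)
  coefs <- if (is.null(X) || ncol(X) == 0) {
    tibble::tibble(term = character(), estimate = numeric())
  } else {
    beta <- qr.coef(qr(cbind(`(Intercept)` = 1, X)), y)
    tibble::tibble(term = colnames(X), estimate = unname(beta[-1]))
  }
  structure(
    list(
      r_squared = r2, adj_r_squared = ar2,
      pseudo_f = if (p > 0) (r2 / p) / ((1 - r2) / (n - p - 1)) else NA_real_,
      df_model = p, df_resid = n - p - 1, n = n,
      coefficients = coefs, dropped = dropped,
      response = response, predictors = predictors,
      y = y, X = X
    ),
    class = "rda_fit"
  )
}

#' @export
print.rda_fit <- function(x, ...) {
  cat("Univariate RDA (standardized least squares)\n")
  cat(sprintf("  %s ~ %d predictor column(s), n = %d\n",
              x$response, x$df_model, x$n))
  cat(sprintf("  R^2 = %.4f, adjusted R^2 = %.4f, pseudo-F = %.2f\n",
              x$r_squared, x$adj_r_squared, x$pseudo_f))
  if (length(x$dropped)) {
    cat("  dropped aliased column(s):", paste(x$dropped, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @method tidy rda_fit
#' @export
tidy.rda_fit <- function(x, ...) x$coefficients

#' @method glance rda_fit
#' @export
glance.rda_fit <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, adj_r_squared = x$adj_r_squared,
                 pseudo_f = x$pseudo_f, df_model = x$df_model,
                 df_resid = x$df_resid, n = x$n)
}

# internal permutation engine on matrices. Tests the contribution of X over
# the conditioning set Z by Freedman-Lane residual permutation: permuted
# responses are fitted_reduced + shuffled residuals_reduced.
permute_f <- function(y, X, Z, n_perm, seed) {
  n <- length(y)
  red <- ols_r2(y, Z)
  full_X <- if (is.null(Z)) X else cbind(Z, X)
  f_stat <- function(yy) {
    full <- ols_r2(yy, full_X)
    redr <- ols_r2(yy, Z)
    p_add <- full$rank - redr$rank
    if (p_add <= 0) return(c(NA_real_, 0))
    df_res <- n - 1 - full$rank
    c(((full$r2 - redr$r2) / p_add) / ((1 - full$r2) / df_res), p_add)
  }
  obs <- f_stat(y)
  perm_f <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      y_star <- red$fitted + sample(red$residuals)
      f_stat(y_star)[1]
    }, numeric(1))
  })
  list(pseudo_f = obs[1], p_added = obs[2],
       p_value = (1 + sum(perm_f >= obs[1], na.rm = TRUE)) / (1 + n_perm),
       n_perm = n_perm)
}

#' Permutation test of an RDA term
#'
#' Pseudo-F test of the variance explained by `predictors` beyond an optional
#' `condition` set, with significance assessed by Freedman-Lane permutation
#' of reduced-model residuals: `p = (1 + #\{F* >= F\}) / (1 + n_perm)`.
#'
#' @param data Site table.
#' @param response Response column name.
#' @param predictors Columns whose joint contribution is tested.
#' @param condition Optional conditioning columns (partialled out).
#' @param n_perm Number of permutations (default 999).
#' @param seed RNG seed for the permutation stream.
#' @return A one-row tibble: `pseudo_f`, `p_value`, `df`, `n_perm`.
#' @export
permutation_test <- function(data, response, predictors, condition = NULL,
                             n_perm = 999, seed = NULL) {
  if (n_perm < 1) fb_abort("n_perm must be >= 1", "bad_n_perm")
  y <- data[[response]]
  y <- (y - mean(y)) / sd(y)
  X <- design_matrix(data, predictors)
  Z <- design_matrix(data, condition)
  res <- permute_f(y, X, Z, n_perm, seed)
  tibble::tibble(pseudo_f = res$pseudo_f, p_value = res$p_value,
                 df = res$p_added, n_perm = n_perm)
}

#' Forward selection maximizing adjusted R-squared
#'
#' Greedy forward selection: at each step the candidate giving the largest
#' adjusted-R-squared gain is proposed, and enters only if (i) its marginal
#' permutation p-value (conditioned on the terms already selected) is below
#' `alpha` and (ii) the running adjusted R-squared does not exceed the
#' full-model adjusted R-squared ceiling. Deterministic under a fixed seed.
#'
#' @inheritParams permutation_test
#' @param candidates Candidate predictor columns.
#' @param alpha Entry threshold on the permutation p-value (default 0.05).
#' @param n_perm Permutations per entry test (default 999; raise towards
#'   10000 for publication-grade p-values).
#' @return A list of class `forward_selection`: `selected` (ordered columns),
#'   `steps` (tibble: `term`, `adj_r_squared`, `pseudo_f`, `p_value`),
#'   `ceiling` (full-model adjusted R^2), `fit` (final [rda_fit()]).
#' @export
forward_select <- function(data, response, candidates, alpha = 0.05,
                           n_perm = 999, seed = NULL) {
  full <- rda_fit(data, response, candidates)
  ceiling_ar2 <- full$adj_r_squared
  selected <- character(0)
  steps <- list()
  remaining <- candidates
  step_seed <- seed
  while (length(remaining) > 0) {
    ar2s <- vapply(remaining, function(cn) {
      rda_fit(data, response, c(selected, cn))$adj_r_squared
    }, numeric(1))
    cand <- remaining[which.max(ar2s)]
    new_ar2 <- max(ar2s)
    if (new_ar2 > ceiling_ar2 + 1e-12) break
    if (!is.null(step_seed)) step_seed <- step_seed + 1L
    pt <- permutation_test(data, response, cand,
                           condition = if (length(selected)) selected else NULL,
                           n_perm = n_perm, seed = step_seed)
    if (pt$p_value >= alpha) break
    selected <- c(selected, cand)
    steps[[length(steps) + 1]] <- tibble::tibble(
      term = cand, adj_r_squared = new_ar2,
      pseudo_f = pt$pseudo_f, p_value = pt$p_value)
    remaining <- setdiff(remaining, cand)
  }
  structure(
    list(
      selected = selected,
      steps = if (length(steps)) dplyr::bind_rows(steps) else
        tibble::tibble(term = character(), adj_r_squared = numeric(),
                       pseudo_f = numeric(), p_value = numeric()),
      ceiling = ceiling_ar2,
      fit = rda_fit(data, response, if (length(selected)) selected else
        character(0))
    ),
    class = "forward_selection"
  )
}

#' @export
print.forward_selection <- function(x, ...) {
  cat("Forward selection (adjusted R^2 criterion, ceiling =",
      sprintf("%.4f", x$ceiling), ")\n")
  if (nrow(x$steps) == 0) cat("  no term selected\n") else print(x$steps)
  invisible(x)
}

#' @method tidy forward_selection
#' @export
tidy.forward_selection <- function(x, ...) x$steps

#' Variance partitioning across predictor groups by partial RDA
#'
#' The unique (conditional) fraction of group g is `adjR2(y ~ all groups) -
#' adjR2(y ~ all groups except g)`; the jointly explained ("interactions")
#' fraction is the total adjusted R-squared minus the sum of unique
#' fractions, so the decomposition closes exactly. Small negative unique
#' fractions are reported as-is (standard in variance partitioning, a
#' consequence of the adjustment), never clipped. Each group's unique
#' fraction is tested by a conditioned permutation test.
#'
#' @param data Site table.
#' @param response Response column name.
#' @param groups Named list mapping group name -> character vector of
#'   predictor columns (>= 2 groups, none empty).
#' @param n_perm Permutations per group test (default 999).
#' @param seed RNG seed.
#' @return An object of class `varpart_result`: `fractions` (tibble: `group`,
#'   `adj_r_squared` unique fraction, `pseudo_f`, `p_value`), `shared`,
#'   `total` (full-model adjusted R^2), `n`.
#' @export
variance_partition <- function(data, response, groups, n_perm = 999,
                               seed = NULL) {
  if (length(groups) < 2) fb_abort("need >= 2 predictor groups", "too_few_groups")
  if (is.null(names(groups)) || any(names(groups) == "")) {
    fb_abort("groups must be a named list", "bad_groups")
  }
  if (any(lengths(groups) == 0)) fb_abort("empty predictor group", "empty_group")
  all_cols <- unlist(groups, use.names = FALSE)
  full <- rda_fit(data, response, all_cols)
  total <- full$adj_r_squared
  rows <- list()
  for (gi in seq_along(groups)) {
    g <- names(groups)[gi]
    others <- unlist(groups[setdiff(names(groups), g)], use.names = FALSE)
    reduced <- rda_fit(data, response, others)
    unique_g <- total - reduced$adj_r_squared
    pt <- permutation_test(data, response, groups[[g]], condition = others,
                           n_perm = n_perm,
                           seed = if (is.null(seed)) NULL else seed + gi)
    rows[[gi]] <- tibble::tibble(
      group = g, adj_r_squared = unique_g,
      pseudo_f = pt$pseudo_f, p_value = pt$p_value)
  }
  fractions <- dplyr::bind_rows(rows)
  structure(
    list(
      fractions = fractions,
      shared = total - sum(fractions$adj_r_squared),
      total = total,
      n = full$n,
      response = response
    ),
    class = "varpart_result"
  )
}

#' @export
print.varpart_result <- function(x, ...) {
  cat("Variance partitioning of", x$response,
      sprintf("(total adjusted R^2 = %.4f, n = %d)\n", x$total, x$n))
  df <- dplyr::bind_rows(
    x$fractions,
    tibble::tibble(group = "shared (interactions)",
                   adj_r_squared = x$shared,
                   pseudo_f = NA_real_, p_value = NA_real_)
  )
  print(df)
  invisible(x)
}

#' @method tidy varpart_result
#' @export
tidy.varpart_result <- function(x, ...) {
  dplyr::bind_rows(
    x$fractions,
    tibble::tibble(group = "shared", adj_r_squared = x$shared,
                   pseudo_f = NA_real_, p_value = NA_real_)
  )
}

#' @method glance varpart_result
#' @export
glance.varpart_result <- function(x, ...) {
  tibble::tibble(total_adj_r_squared = x$total, shared = x$shared, n = x$n)
}

#' Bar chart of variance-partitioning fractions
#'
#' @param object A [variance_partition()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot varpart_result
#' @export
autoplot.varpart_result <- function(object, ...) {
  df <- tidy(object)
  df$group <- factor(df$group, levels = df$group[order(df$adj_r_squared)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group,
                                   y = 100 * .data$adj_r_squared)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "explained variance (adjusted R², %)") +
    ggplot2::theme_minimal()
}
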