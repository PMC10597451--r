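#' Land-use contrasts by Kruskal-Wallis with Bonferroni post hoc
#'
#' Omnibus: the tie-corrected Kruskal-Wallis H (via [stats::kruskal.test()])
#' against a chi-squared null with `groups - 1` df. Post hoc: pairwise
#' mean-rank comparisons in the rank-LSD style — the difference of mean ranks
#' is referred to a t quantile with the pooled rank variance
#' `S^2 (N - 1 - H)/(N - k)` — with raw p-values multiplied by the number of
#' pairs (Bonferroni), capped at 1. Groups not separated by any significant
#' pair share a letter in the compact letter display.
#'
#' @param data Data frame of observations.
#' @param response Numeric response column name.
#' @param group Grouping column name (land-use class).
#' @param alpha Significance level for the letter display (default 0.05).
#' @return An object of class `kw_result`: `h` (tie-corrected statistic),
#'   `df`, `p_value`, `pairwise` (tibble: `group1`, `group2`,
#'   `mean_rank_diff`, `p_raw`, `p_adjusted`), `letters` (tibble: `group`,
#'   `n`, `median`, `mean_rank`, `letters`), `alpha`.
#' @export
kruskal_compare <- function(data, response, group, alpha = 0.05) {
  check_columns(data, c(response, group), "observation table")
  x <- data[[response]]
  g <- factor(data[[group]])
  ok <- !is.na(x) & !is.na(g)
  x <- x[ok]
  g <- droplevels(g[ok])
  counts <- table(g)
  if (nlevels(g) < 2) fb_abort("need >= 2 groups", "too_few_groups")
  if (any(counts < 2)) {
    fb_abort(paste0("group(s) with < 2 observations: ",
                    paste(names(counts)[counts < 2], collapse = ", ")),
             "too_few_obs")
  }
  kw <- kruskal.test(x, g)
  h <- unname(kw$statistic)
  k <- nlevels(g)
  n <- length(x)
  r <- rank(x)
  mean_ranks <- tapply(r, g, mean)
  # pooled rank variance; with no ties this is N(N+1)/12
  s2 <- var(r)
  pool <- s2 * (n - 1 - h) / (n - k)
  pairs <- combn(levels(g), 2, simplify = FALSE)
  n_pairs <- length(pairs)
  pw <- purrr::map_dfr(pairs, function(pr) {
    ni <- counts[[pr[1]]]
    nj <- counts[[pr[2]]]
    diff <- abs(mean_ranks[[pr[1]]] - mean_ranks[[pr[2]]])
    se <- sqrt(pool * (1 / ni + 1 / nj))
    tstat <- diff / se
    p_raw <- 2 * pt(tstat, n - k, lower.tail = FALSE)
    tibble::tibble(group1 = pr[1], group2 = pr[2], mean_rank_diff = diff,
                   p_raw = p_raw, p_adjusted = min(1, p_raw * n_pairs))
  })
  letters_df <- tibble::tibble(
    group = levels(g),
    n = as.integer(counts),
    median = as.numeric(tapply(x, g, median)),
    mean_rank = as.numeric(mean_ranks),
    letters = letter_display(levels(g), pw, alpha)
  )
  structure(
    list(h = h, df = k - 1L, p_value = kw$p.value, pairwise = pw,
         letters = letters_df, alpha = alpha, n = n,
         response = response, group = group),
    class = "kw_result"
  )
}

# internal: compact letter display by the insert-and-absorb algorithm.
# Each letter marks a maximal set of mutually non-significant groups.
letter_display <- function(groups, pairwise, alpha) {
  k <- length(groups)
  sig <- matrix(FALSE, k, k, dimnames = list(groups, groups))
  for (i in seq_len(nrow(pairwise))) {
    if (pairwise$p_adjusted[i] < alpha) {
      sig[pairwise$group1[i], pairwise$group2[i]] <- TRUE
      sig[pairwise$group2[i], pairwise$group1[i]] <- TRUE
    }
  }
  sets <- list(groups[1])
  for (gi in groups[-1]) {
    placed <- FALSE
    for (si in seq_along(sets)) {
      if (!any(sig[gi, sets[[si]]])) {
        sets[[si]] <- c(sets[[si]], gi)
        placed <- TRUE
      }
    }
    if (!placed) {
      # start a new letter seeded with every group compatible with gi
      compat <- groups[!sig[gi, groups] & groups != gi]
      compat <- compat[match(compat, groups) < match(gi, groups)]
      new_set <- c(compat[vapply(compat, function(cg)
        !any(sig[cg, compat[compat != cg]]), logical(1))], gi)
      sets[[length(sets) + 1]] <- new_set
    }
  }
  # absorb sets fully contained in another
  keep <- rep(TRUE, length(sets))
  for (i in seq_along(sets)) {
    for (j in seq_along(sets)) {
      if (i != j && keep[i] && keep[j] && all(sets[[i]] %in% sets[[j]])) {
        keep[i] <- FALSE
      }
    }
  }
  sets <- sets[keep]
  vapply(groups, function(gi) {
    paste0(letters[which(vapply(sets, function(s) gi %in% s, logical(1)))],
           collapse = "")
  }, character(1))
}

#' @export
print.kw_result <- function(x, ...) {
  cat("Kruskal-Wallis:", x$response, "by", x$group, "\n")
  cat(sprintf("  H = %.4f, df = %d, p = %.4g (n = %d)\n",
              x$h, x$df, x$p_value, x$n))
  cat("  groups (Bonferroni letters at alpha =", x$alpha, "):\n")
  print(x$letters)
  invisible(x)
}

#' @method tidy kw_result
#' @export
tidy.kw_result <- function(x, ...) x$pairwise

#' @method glance kw_result
#' @export
glance.kw_result <- function(x, ...) {
  tibble::tibble(h = x$h, df = x$df, p_value = x$p_value, n = x$n)
}

#' Boxplots with compact letter display
#'
#' @param object A [kruskal_compare()] result.
#' @param data The observation table the result was computed from.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot kw_result
#' @export
autoplot.kw_result <- function(object, data, ...) {
  lab <- object$letters
  ggplot2::ggplot(data,
                  ggplot2::aes(x = .data[[object$group]],
                               y = .data[[object$response]],
                               fill = .data[[object$group]])) +
    ggplot2::geom_boxplot(outlier.alpha = 0.3, show.legend = FALSE) +
    ggplot2::annotate("text", x = lab$group,
                      y = max(data[[object$response]], na.rm = TRUE) * 1.05,
                      label = lab$letters) +
    ggplot2::labs(x = NULL, y = object$response) +
    ggplot2::theme_minimal()
}

#' Per-group tail fractions of a response
#'
#' Share of values below `low` and above `high` in each group, in percent;
#' e.g. the share of soils with an F:B ratio above 5 per land use.
#'
#' @inheritParams kruskal_compare
#' @param low,high Ordered thresholds.
#' @return A tibble: `group`, `n`, `pct_below`, `pct_above`.
#' @export
threshold_fractions <- function(data, response, group, low = 1, high = 5) {
  check_columns(data, c(response, group), "observation table")
  stopifnot(low <= high)
  data |>
    dplyr::filter(!is.na(.data[[response]]), !is.na(.data[[group]])) |>
    dplyr::group_by(group = .data[[group]]) |>
    dplyr::summarise(
      n = dplyr::n(),
      pct_below = 100 * mean(.data[[response]] < low),
      pct_above = 100 * mean(.data[[response]] > high),
      .groups = "drop"
    )
}
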