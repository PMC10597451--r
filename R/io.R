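#' Read a site table
#'
#' Reads a site CSV (UTF-8, decimal point) into a typed tibble. Mandatory
#' columns are `site_id`, `x_km`, `y_km`; all others are optional. When
#' `fb_ratio` is absent but both densities are present it is computed on
#' load via [fb_ratio()]; when both are present their consistency is checked
#' to 1e-9 relative. Unit sanity warnings are emitted for implausible values
#' (pH outside [3, 10], negative densities).
#'
#' @param path CSV file path.
#' @return A tibble of site records.
#' @export
read_sites <- function(path) {
  sites <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                           lazy = FALSE)
  probs <- readr::problems(sites)
  if (nrow(probs) > 0) {
    fb_abort(paste0("malformed site CSV at line(s): ",
                    paste(unique(probs$row), collapse = ", ")), "bad_csv")
  }
  check_columns(sites, c("site_id", "x_km", "y_km"), "site CSV")
  # columns that must be numeric; a stray text cell makes readr fall back to
  # character, so locate the offending line(s) explicitly
  num_cols <- intersect(
    c("x_km", "y_km", "pH", "organic_C", "CN_ratio", "clay", "silt", "sand",
      "coarse_elements", "avail_P", "total_Ni", "total_Cu",
      "bacterial_density", "fungal_density", "fb_ratio"), names(sites))
  for (cn in num_cols) {
    if (!is.numeric(sites[[cn]])) {
      parsed <- suppressWarnings(as.numeric(sites[[cn]]))
      bad <- which(is.na(parsed) & !is.na(sites[[cn]]))
      fb_abort(paste0("malformed numeric value in column ", cn,
                      " at data line(s): ", paste(bad, collapse = ", ")),
               "bad_csv")
    }
  }
  has_dens <- all(c("bacterial_density", "fungal_density") %in% names(sites))
  if (!"fb_ratio" %in% names(sites) && has_dens) {
    sites$fb_ratio <- fb_ratio(sites$fungal_density, sites$bacterial_density)
  } else if ("fb_ratio" %in% names(sites) && has_dens) {
    expect <- fb_ratio(sites$fungal_density, sites$bacterial_density)
    rel <- abs(sites$fb_ratio - expect) / expect
    if (any(rel > 1e-9, na.rm = TRUE)) {
      fb_abort("fb_ratio column inconsistent with the density columns",
               "inconsistent_ratio")
    }
  }
  if ("pH" %in% names(sites) &&
      any(sites$pH < 3 | sites$pH > 10, na.rm = TRUE)) {
    warn("pH values outside [3, 10]: check units")
  }
  if (all(c("clay", "silt", "sand") %in% names(sites))) {
    tot <- sites$clay + sites$silt + sites$sand
    if (any(abs(tot - 1000) > 50, na.rm = TRUE)) {
      warn("clay + silt + sand deviates from 1000 g/kg for some sites")
    }
  }
  sites
}

#' @rdname read_sites
#' @param sites Site tibble.
#' @export
write_sites <- function(sites, path) {
  readr::write_csv(sites, path)
  invisible(path)
}

#' Extract spatial samples for one response
#'
#' @param sites Site tibble with `x_km`, `y_km`.
#' @param response Response column name.
#' @param values Optional replacement values (e.g. transformed), same length
#'   as `nrow(sites)`.
#' @return A tibble `site_id`, `x`, `y`, `value` with missing values dropped.
#' @export
spatial_samples <- function(sites, response, values = NULL) {
  check_columns(sites, c("site_id", "x_km", "y_km", response), "site table")
  v <- values %||% sites[[response]]
  out <- tibble::tibble(site_id = sites$site_id, x = sites$x_km,
                        y = sites$y_km, value = v)
  dplyr::filter(out, !is.na(.data$value))
}

#' Add standardized spatial descriptor columns
#'
#' The spatial predictor group: standardized coordinates and their
#' second-order polynomial terms (`spatial_x`, `spatial_y`, `spatial_x2`,
#' `spatial_y2`, `spatial_xy`). This trend-surface convention is a package
#' choice — flagged in reports — since coordinate descriptors can be
#' constructed in several ways.
#'
#' @param sites Site tibble with `x_km`, `y_km`.
#' @return `sites` with the five spatial columns appended.
#' @export
add_spatial_descriptors <- function(sites) {
  check_columns(sites, c("x_km", "y_km"), "site table")
  zx <- (sites$x_km - mean(sites$x_km)) / sd(sites$x_km)
  zy <- (sites$y_km - mean(sites$y_km)) / sd(sites$y_km)
  dplyr::mutate(sites, spatial_x = zx, spatial_y = zy,
                spatial_x2 = zx^2, spatial_y2 = zy^2, spatial_xy = zx * zy)
}

#' Default predictor grouping for driver analysis
#'
#' @param sites Site tibble (used to keep only columns that exist).
#' @return Named list: `soil`, `land_management`, `climate`, `spatial`.
#' @export
default_groups <- function(sites) {
  soil <- intersect(c("pH", "organic_C", "CN_ratio", "clay", "silt",
                      "coarse_elements", "avail_P", "total_Ni", "total_Cu"),
                    names(sites))
  groups <- list(
    soil = soil,
    land_management = intersect("landuse_coarse", names(sites)),
    climate = intersect("climate_class", names(sites)),
    spatial = c("spatial_x", "spatial_y", "spatial_x2", "spatial_y2",
                "spatial_xy")
  )
  groups[lengths(groups) > 0]
}

#' Run the full analysis chain on a site table
#'
#' For each response (F:B ratio and, when present, the bacterial and fungal
#' densities): response conditioning (normality screen, Box-Cox, Grubbs on
#' the transformed scale), geostatistics (ML Matern variogram,
#' leave-one-out cross-validation, optional kriged grid), VIF screening and
#' variance partitioning across soil / land-management / climate / spatial
#' groups, and land-use contrasts (Kruskal-Wallis with Bonferroni post hoc,
#' tail fractions). Sand is excluded from models (it is collinear with clay
#' + silt by construction).
#'
#' @param sites Site tibble (see [read_sites()]).
#' @param responses Response columns to analyse (defaults to those present
#'   among `fb_ratio`, `bacterial_density`, `fungal_density`).
#' @param groups Predictor grouping; default [default_groups()].
#' @param nu_candidates Smoothness grid for the variogram fit.
#' @param neighborhood Kriging neighbourhood size.
#' @param grid_resolution_km Grid spacing for the kriged map; `NULL` skips
#'   the map.
#' @param n_perm Permutations for the partition tests.
#' @param vif_threshold Collinearity threshold for the soil group.
#' @param seed RNG seed (mandatory; every stochastic step derives from it).
#' @return An object of class `run_report`: per-response list with elements
#'   `prepared`, `variogram`, `cv`, `grid`, `vif`, `varpart`, `kruskal`,
#'   `thresholds`, plus `seed`, `n_sites`, and the call configuration.
#' @export
run_pipeline <- function(sites,
                         responses = intersect(
                           c("fb_ratio", "bacterial_density",
                             "fungal_density"), names(sites)),
                         groups = NULL,
                         nu_candidates = c(0.5, 1.5, 2.5),
                         neighborhood = 64,
                         grid_resolution_km = NULL,
                         n_perm = 199,
                         vif_threshold = 5,
                         seed = 1) {
  check_columns(sites, c("site_id", "x_km", "y_km"), "site table")
  if (length(responses) == 0) fb_abort("no response columns found",
                                       "no_response")
  sites <- add_spatial_descriptors(sites)
  groups <- groups %||% default_groups(sites)
  results <- list()
  for (ri in seq_along(responses)) {
    resp <- responses[ri]
    prep <- prepare_response(sites[[resp]])
    kept <- dplyr::select(
      dplyr::filter(dplyr::mutate(sites, .keep_row = prep$keep),
                    .data$.keep_row),
      -".keep_row")
    kept[[paste0(resp, "_t")]] <- prep$values
    samples <- spatial_samples(kept, paste0(resp, "_t"))
    vg <- fit_variogram_ml(samples, nu_candidates = nu_candidates)
    cv <- loo_cross_validation(vg, samples, neighborhood)
    grid <- if (!is.null(grid_resolution_km)) {
      krige_grid(vg, samples, resolution_km = grid_resolution_km,
                 neighborhood = neighborhood)
    } else NULL
    g <- groups
    if ("soil" %in% names(g) && length(g$soil) >= 2) {
      vf <- vif_filter(kept, g$soil, threshold = vif_threshold)
      g$soil <- vf$retained
    } else vf <- NULL
    vp <- variance_partition(kept, paste0(resp, "_t"), g,
                             n_perm = n_perm, seed = seed + 100 * ri)
    kw <- if ("landuse_coarse" %in% names(kept)) {
      kruskal_compare(kept, paste0(resp, "_t"), "landuse_coarse")
    } else NULL
    th <- if (resp == "fb_ratio" && "landuse_coarse" %in% names(kept)) {
      threshold_fractions(kept, "fb_ratio", "landuse_coarse")
    } else NULL
    results[[resp]] <- list(prepared = prep, variogram = vg, cv = cv,
                            grid = grid, vif = vf, varpart = vp,
                            kruskal = kw, thresholds = th)
  }
  structure(
    list(results = results, responses = responses, seed = seed,
         n_sites = nrow(sites), neighborhood = neighborhood,
         nu_candidates = nu_candidates, n_perm = n_perm,
         spatial_descriptors = "standardized x, y and 2nd-order polynomial"),
    class = "run_report"
  )
}

#' @export
print.run_report <- function(x, ...) {
  cat("fbgeo run report (n =", x$n_sites, "sites, seed =", x$seed, ")\n")
  for (resp in x$responses) {
    r <- x$results[[resp]]
    cat("\n==", resp, "==\n")
    cat(sprintf("  transform: %s; outliers removed: %d\n",
                r$prepared$transform$kind,
                length(r$prepared$outliers$removed_indices)))
    cat(sprintf("  variogram: nu %.1f, effective range %.1f km\n",
                r$variogram$nu, r$variogram$effective_range))
    cat(sprintf("  LOO: mean SSPE %.3f, r^2 %.3f\n",
                r$cv$mean_sspe, r$cv$r_squared))
    cat(sprintf("  varpart: total adj R^2 %.3f (shared %.3f)\n",
                r$varpart$total, r$varpart$shared))
    if (!is.null(r$kruskal)) {
      cat(sprintf("  land use: H = %.2f, p = %.3g\n",
                  r$kruskal$h, r$kruskal$p_value))
    }
  }
  invisible(x)
}

#' Serialize a run report to JSON
#'
#' Writes the configuration, transform specs, outlier lists, variogram and
#' cross-validation parameters, and variance fractions — enough to
#' re-execute the run from raw data.
#'
#' @param report A [run_pipeline()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(report, path) {
  stopifnot(inherits(report, "run_report"))
  out <- list(
    seed = report$seed, n_sites = report$n_sites,
    neighborhood = report$neighborhood,
    nu_candidates = report$nu_candidates, n_perm = report$n_perm,
    spatial_descriptors = report$spatial_descriptors,
    responses = lapply(report$results, function(r) {
      list(
        transform = r$prepared$transform,
        outliers_removed = r$prepared$outliers$removed_indices,
        variogram = glance(r$variogram),
        cv = glance(r$cv),
        varpart = list(fractions = r$varpart$fractions,
                       shared = r$varpart$shared, total = r$varpart$total),
        kruskal = if (!is.null(r$kruskal)) glance(r$kruskal) else NULL
      )
    })
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
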