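#' Synthetic soil-monitoring-network generator
#'
#' Generates datasets shaped like a national soil monitoring survey — a
#' 16 x 16 km systematic grid of ~2,171 sites with land use, soil and climate
#' covariates, spatially autocorrelated log densities, and raw qPCR plates —
#' with every planted parameter returned as ground truth, so each pipeline
#' stage has a recovery test. The log10 F:B ratio is modelled directly as
#' intercept + land-use deviation + covariate effects + a ratio-specific
#' Matern field + noise; the bacterial log density has its own drivers and
#' shared + specific spatial components, and the fungal density is derived
#' so that the x100 ratio identity holds exactly. Because the ratio field is
#' independent of the density fields, the simulated F:B map has spatial
#' structure of its own, distinct from either density map.
#'
#' @name synthetic_data
NULL

#' Default configuration of the synthetic generator
#'
#' Covariate effect signs follow the planted conventions: on the F:B ratio pH
#' and organic carbon act negatively, C:N ratio and coarse elements
#' positively, silt negatively, available P positively; land-use levels are
#' ordered grassland < vineyard_orchard < crop < forest; among climates only
#' the Mediterranean class has a positive effect. Magnitudes are in log10
#' units per standard deviation of the covariate.
#'
#' @param n_sites Number of sites (default 2171).
#' @param grid_spacing_km Grid cell size (default 16).
#' @param field Ratio-specific Matern field: list `nugget`, `psill` (log10^2
#'   semivariance units), `effective_range_km`, `nu`.
#' @param fb_intercept Mean log10 F:B ratio (default `log10(2.72)` scale).
#' @param fb_effects Named coefficients on standardized covariates
#'   (log10 units).
#' @param landuse_effects Named direct land-use deviations (log10 units).
#' @param climate_effect Mediterranean climate deviation (log10 units).
#' @param noise_sd Residual SD of the log10 ratio.
#' @param bacterial Bacterial log10-density model: `intercept`, `effects`,
#'   `shared_field_sd`, `own_field_sd`, `noise_sd`.
#' @param plates qPCR plate design: `samples_per_plate`, `offset_sd`
#'   (cycles), `ct_sd` (cycles), `reps`, `standard_decades` (log10 copies per
#'   reaction of the dilution ladder), `reference_copies` (copies per
#'   reaction), `slope`, `intercept` (true curve).
#' @param conversion Copies-per-g per copies-per-reaction factor.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(
    n_sites = 2171,
    grid_spacing_km = 16,
    field = list(nugget = 0.002, psill = 0.008, effective_range_km = 84,
                 nu = 0.5),
    fb_intercept = 0.442,
    fb_effects = c(pH = -0.055, organic_C = -0.030, CN_ratio = 0.040,
                   coarse_elements = 0.035, silt = -0.018, avail_P = 0.030,
                   total_Ni = 0.012, total_Cu = -0.012),
    landuse_effects = c(grassland = -0.100, vineyard_orchard = -0.060,
                        crop = -0.030, forest = 0.090),
    climate_effect = 0.05,
    noise_sd = 0.19,
    bacterial = list(intercept = 10.2,
                     effects = c(organic_C = 0.22, CN_ratio = -0.12,
                                 pH = 0.15, clay = 0.05),
                     shared_field_sd = 0.18, own_field_sd = 0.10,
                     noise_sd = 0.12),
    plates = list(samples_per_plate = 30, offset_sd = 0.5, ct_sd = 0.15,
                  reps = 3, standard_decades = 2:7, reference_copies = 1e5,
                  slope = -3.3219, intercept = 38),
    conversion = 1e4) {
  cfg <- list(
    n_sites = n_sites, grid_spacing_km = grid_spacing_km, field = field,
    fb_intercept = fb_intercept, fb_effects = fb_effects,
    landuse_effects = landuse_effects, climate_effect = climate_effect,
    noise_sd = noise_sd, bacterial = bacterial, plates = plates,
    conversion = conversion
  )
  stopifnot(field$nugget >= 0, field$psill >= 0, noise_sd >= 0,
            n_sites >= 10)
  class(cfg) <- "synthetic_config"
  cfg
}

#' Matern distance parameter from a practical range
#'
#' Inverts the 95% practical-range relation numerically: returns `a` such
#' that the Matern correlation at `effective_range` equals 0.05 (for the
#' exponential case, `a = effective_range / 2.9957`).
#'
#' @param effective_range Practical range (km).
#' @param nu Smoothness.
#' @return The distance parameter `a` (km).
#' @export
matern_range_from_effective <- function(effective_range, nu = 0.5) {
  stopifnot(effective_range > 0)
  k <- uniroot(function(x) matern_correlation(x, 1, nu) - 0.05,
               lower = 1e-8, upper = 1e4, tol = 1e-12)$root
  effective_range / k
}

#' Draw Gaussian random fields with Matern covariance
#'
#' Exact simulation by Cholesky factorization of the covariance at the site
#' locations: `C = psill * rho(h) + nugget * I`. The factor is computed once
#' and reused across draws. A 1e-10 diagonal jitter is applied (with a
#' message) if the factorization fails numerically.
#'
#' @param locations Data frame with columns `x`, `y` (km).
#' @param nugget,psill Field variance components.
#' @param effective_range Practical (95%) range (km).
#' @param nu Matern smoothness.
#' @param n_draws Number of independent realizations.
#' @param seed RNG seed.
#' @return A numeric matrix, `nrow(locations)` x `n_draws`.
#' @export
simulate_field <- function(locations, nugget, psill, effective_range,
                           nu = 0.5, n_draws = 1, seed = NULL) {
  check_columns(locations, c("x", "y"), "location table")
  stopifnot(nugget >= 0, psill >= 0, effective_range > 0)
  n <- nrow(locations)
  if (nugget + psill == 0) return(matrix(0, n, n_draws))
  a <- matern_range_from_effective(effective_range, nu)
  C <- psill * matern_correlation(
    as.matrix(dist(cbind(locations$x, locations$y))), a, nu)
  diag(C) <- psill + nugget
  U <- tryCatch(chol(C), error = function(e) {
    message("covariance not numerically PSD; adding 1e-10 jitter")
    chol(C + diag(1e-10, n))
  })
  out <- with_seed(seed, {
    crossprod(U, matrix(rnorm(n * n_draws), n, n_draws))
  })
  dimnames(out) <- NULL
  out
}

# internal: clip to a plausible physical interval
clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Simulate a monitoring-network site table with known ground truth
#'
#' Sites sit at jittered centres of cells sampled from a ~950 x 950 km
#' square grid (the irregular territory is emulated by using a random subset
#' of cells). Covariate marginals are realistic for temperate mineral soils
#' (pH 4-8.5, C:N 8-25, ...) and depend on land use (forests more acidic,
#' higher C:N and organic C; vineyards richer in copper), which is what
#' creates the jointly explained ("interactions") variance fraction
#' downstream. Climate classes are assigned by geographic position with the
#' Mediterranean class in the south-east.
#'
#' @param cfg A [synthetic_config()].
#' @param seed Master RNG seed; a fixed seed makes the output byte-identical.
#' @return A list: `sites` (tibble, one row per site) and `truth` (list of
#'   every planted parameter and latent field).
#' @export
simulate_sites <- function(cfg = synthetic_config(), seed = 1) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_seed(seed, {
    sp <- cfg$grid_spacing_km
    n_cells <- ceiling(950 / sp)
    total_cells <- n_cells^2
    if (cfg$n_sites > total_cells) {
      fb_abort("n_sites exceeds the number of grid cells at this spacing",
               "bad_grid")
    }
    cells <- sort(sample.int(total_cells, cfg$n_sites))
    cx <- ((cells - 1) %% n_cells + 0.5) * sp
    cy <- ((cells - 1) %/% n_cells + 0.5) * sp
    x <- cx + runif(cfg$n_sites, -sp / 8, sp / 8)
    y <- cy + runif(cfg$n_sites, -sp / 8, sp / 8)
    xmax <- n_cells * sp
    n <- cfg$n_sites

    landuse <- sample(c("crop", "grassland", "forest", "vineyard_orchard"),
                      n, replace = TRUE, prob = c(0.45, 0.27, 0.23, 0.05))
    fine_map <- list(
      crop = c("crop_rotation", "crop_no_rotation", "fixed_fallow"),
      grassland = c("permanent_grassland", "temporary_grassland"),
      forest = c("deciduous_forest", "coniferous_forest"),
      vineyard_orchard = c("vineyard", "orchard")
    )
    landuse_fine <- vapply(landuse, function(lu)
      sample(fine_map[[lu]], 1), character(1))

    med <- x > 0.62 * xmax & y < 0.38 * xmax
    climate <- ifelse(med, "mediterranean",
               ifelse(x < 0.33 * xmax, "oceanic",
               ifelse(y > 0.60 * xmax, "semi_continental",
               ifelse(x > 0.70 * xmax, "continental", "intermediate"))))

    dev <- function(values) unname(values[landuse])
    pH <- clip(rnorm(n, 6.3, 1.0) +
                 dev(c(crop = 0.35, grassland = 0.1, forest = -0.8,
                       vineyard_orchard = 0.55)), 3.8, 8.5)
    organic_C <- exp(rnorm(n, log(20), 0.45) +
                       dev(c(crop = -0.22, grassland = 0.26, forest = 0.47,
                             vineyard_orchard = -0.36)))
    CN_ratio <- clip(rnorm(n, 10.5, 2.0) +
                       dev(c(crop = -0.5, grassland = 0.5, forest = 3.5,
                             vineyard_orchard = -0.5)), 8, 25)
    clay <- clip(rnorm(n, 250, 80), 30, 600)
    silt <- clip(rnorm(n, 350, 100), 50, 700)
    sand <- pmax(1000 - clay - silt, 20)
    coarse_elements <- clip(exp(rnorm(n, log(10), 0.7) +
                                  dev(c(crop = 0, grassland = 0, forest = 0.4,
                                        vineyard_orchard = 0.26))), 0.1, 80)
    avail_P <- exp(rnorm(n, log(50), 0.6) +
                     dev(c(crop = 0.34, grassland = 0, forest = -0.7,
                           vineyard_orchard = 0.26)))
    total_Ni <- exp(rnorm(n, log(25), 0.5))
    total_Cu <- exp(rnorm(n, log(12), 0.4) +
                      dev(c(crop = 0, grassland = 0, forest = 0,
                            vineyard_orchard = 1.1)))

    covs <- tibble::tibble(pH, organic_C, CN_ratio, clay, silt,
                           coarse_elements, avail_P, total_Ni, total_Cu)
    zcov <- vapply(covs, function(v) (v - mean(v)) / sd(v),
                   numeric(n))

    loc <- tibble::tibble(x = x, y = y)
    f_ratio <- simulate_field(loc, cfg$field$nugget, cfg$field$psill,
                              cfg$field$effective_range_km, cfg$field$nu)[, 1]
    b <- cfg$bacterial
    f_shared <- simulate_field(loc, 0, b$shared_field_sd^2,
                               cfg$field$effective_range_km,
                               cfg$field$nu)[, 1]
    f_bact <- simulate_field(loc, 0, b$own_field_sd^2,
                             cfg$field$effective_range_km, cfg$field$nu)[, 1]

    eff <- cfg$fb_effects
    r <- cfg$fb_intercept +
      unname(cfg$landuse_effects[landuse]) +
      as.numeric(zcov[, names(eff)] %*% eff) +
      cfg$climate_effect * (climate == "mediterranean") +
      f_ratio + rnorm(n, 0, cfg$noise_sd)

    beff <- b$effects
    log_bact <- b$intercept +
      as.numeric(zcov[, names(beff)] %*% beff) +
      f_shared + f_bact + rnorm(n, 0, b$noise_sd)
    log_fung <- log_bact + r - 2  # so that 100 * F / B = 10^r exactly

    sites <- dplyr::bind_cols(
      tibble::tibble(
        site_id = sprintf("site_%04d", seq_len(n)),
        x_km = x, y_km = y,
        landuse_coarse = landuse, landuse_fine = landuse_fine,
        climate_class = climate
      ),
      covs,
      tibble::tibble(
        sand = sand,
        bacterial_density = 10^log_bact,
        fungal_density = 10^log_fung,
        fb_ratio = 10^r
      )
    )
    truth <- list(
      config = cfg, seed = seed,
      log10_fb = r, log10_bacterial = log_bact,
      field_ratio = f_ratio, field_shared = f_shared, field_bacterial = f_bact,
      fb_effects = eff, landuse_effects = cfg$landuse_effects,
      climate_effect = cfg$climate_effect,
      effective_range_km = cfg$field$effective_range_km
    )
    list(sites = sites, truth = truth)
  })
}

#' Simulate raw qPCR plates for a set of samples
#'
#' Wells follow the assay layout: every plate carries triplicate reference
#' DNA, a 10-fold dilution standards ladder (`reps` wells per decade), and a
#' round-robin block of samples. `Ct = intercept + slope * log10(copies per
#' reaction) + plate offset + N(0, ct_sd)`; plate offsets are drawn
#' `N(0, offset_sd)` and returned as ground truth.
#'
#' @param true_copies Tibble with `sample_id` and `copies_per_g` (> 0).
#' @param cfg A [synthetic_config()] (the `plates` and `conversion` entries
#'   are used).
#' @param target `"16S"` or `"18S"`, recorded on the wells.
#' @param seed RNG seed.
#' @param noiseless If `TRUE`, plate offsets are still drawn but Ct noise is
#'   suppressed (for exact round-trip checks set `ct_sd = 0` instead to keep
#'   offsets).
#' @return A list: `wells` (tibble in the layout expected by
#'   [calibrate_plates()]) and `truth` (list: `plate_offsets`, `curve`,
#'   `conversion`).
#' @export
simulate_plates <- function(true_copies, cfg = synthetic_config(),
                            target = "16S", seed = 1, noiseless = FALSE) {
  check_columns(true_copies, c("sample_id", "copies_per_g"), "sample table")
  if (any(true_copies$copies_per_g <= 0, na.rm = TRUE)) {
    fb_abort("true copies must be > 0", "bad_density")
  }
  p <- cfg$plates
  ct_sd <- if (noiseless) 0 else p$ct_sd
  with_seed(seed, {
    n_samp <- nrow(true_copies)
    n_plates <- max(1L, ceiling(n_samp / p$samples_per_plate))
    offsets <- rnorm(n_plates, 0, p$offset_sd)
    plate_of <- rep(seq_len(n_plates), length.out = n_samp)
    ct_of <- function(copies_rxn, plate, nrep) {
      p$intercept + p$slope * log10(copies_rxn) + offsets[plate] +
        rnorm(nrep, 0, ct_sd)
    }
    wells <- list()
    for (pl in seq_len(n_plates)) {
      ref_ct <- ct_of(p$reference_copies, pl, p$reps)
      wells[[length(wells) + 1]] <- tibble::tibble(
        plate_id = paste0("P", pl), target = target, role = "reference",
        sample_id = paste0("ref_", target), replicate = seq_len(p$reps),
        ct = ref_ct, known_conc = NA_real_
      )
      for (dec in p$standard_decades) {
        conc <- 10^dec
        wells[[length(wells) + 1]] <- tibble::tibble(
          plate_id = paste0("P", pl), target = target, role = "standard",
          sample_id = sprintf("std_1e%d", dec), replicate = seq_len(p$reps),
          ct = ct_of(conc, pl, p$reps), known_conc = conc
        )
      }
      on_plate <- which(plate_of == pl)
      if (length(on_plate)) {
        # samples are run with the same replication as references
        copies_rxn <- rep(true_copies$copies_per_g[on_plate] /
                            cfg$conversion, each = p$reps)
        wells[[length(wells) + 1]] <- tibble::tibble(
          plate_id = paste0("P", pl), target = target, role = "sample",
          sample_id = rep(true_copies$sample_id[on_plate], each = p$reps),
          replicate = rep(seq_len(p$reps), times = length(on_plate)),
          ct = p$intercept + p$slope * log10(copies_rxn) + offsets[pl] +
            rnorm(length(copies_rxn), 0, ct_sd),
          known_conc = NA_real_
        )
      }
    }
    list(
      wells = dplyr::bind_rows(wells),
      truth = list(
        plate_offsets = setNames(offsets, paste0("P", seq_len(n_plates))),
        curve = list(slope = p$slope, intercept = p$intercept),
        conversion = cfg$conversion, ct_sd = ct_sd
      )
    )
  })
}
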