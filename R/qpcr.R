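#' qPCR master-curve calibration
#'
#' Multi-plate qPCR runs drift: the same template amplifies at slightly
#' different threshold cycles (Ct) on different plates. The master-curve
#' method removes this drift by (i) recentring every plate on a shared
#' reference DNA sample, (ii) pooling the recentred standards of all plates
#' into one calibration line, and (iii) quantifying every sample against that
#' single line. These functions implement each step on a long-format well
#' table with columns `plate_id`, `target` (`"16S"` or `"18S"`), `role`
#' (`"standard"`, `"reference"` or `"sample"`), `sample_id`, `replicate`,
#' `ct`, and `known_conc` (copies per reaction; standards only).
#'
#' @name qpcr_calibration
NULL

valid_targets <- c("16S", "18S")
valid_roles <- c("standard", "reference", "sample")

# internal: subset wells to one target, validating the basic well contract
filter_target <- function(wells, target) {
  check_columns(wells, c("plate_id", "target", "role", "sample_id", "ct"),
                "well table")
  target <- match.arg(target, valid_targets)
  bad_role <- setdiff(unique(wells$role), valid_roles)
  if (length(bad_role) > 0) {
    fb_abort(paste0("unknown well role(s): ", paste(bad_role, collapse = ", ")),
             "bad_role")
  }
  dplyr::filter(wells, .data$target == !!target)
}

#' Mean reference Ct of the whole data set
#'
#' Arithmetic mean of the threshold cycles of every reference-DNA well of one
#' target gene, pooled across all plates. This is the anchor that per-plate
#' corrections recentre on.
#'
#' @param wells Well table (see [qpcr_calibration]).
#' @param target `"16S"` or `"18S"`.
#' @return A single numeric Ct (cycles).
#' @export
global_reference_mean <- function(wells, target) {
  w <- filter_target(wells, target)
  refs <- dplyr::filter(w, .data$role == "reference", !is.na(.data$ct))
  if (nrow(refs) == 0) {
    fb_abort(paste0("no reference wells for target ", target,
                    "; cannot calibrate"), "no_reference")
  }
  mean(refs$ct)
}

#' Per-plate Ct corrections (derivations)
#'
#' For each plate, the derivation is the plate's mean reference Ct minus the
#' global reference mean. Subtracting it from every Ct on the plate recentres
#' the plate on the pooled reference.
#'
#' @inheritParams global_reference_mean
#' @param global_mean Optional precomputed [global_reference_mean()]; computed
#'   from `wells` when `NULL`.
#' @return A tibble with one row per plate: `plate_id`, `target`, `n_ref`,
#'   `plate_ref_mean`, `derivation` (cycles), and `ref_sd_flag` (`TRUE` when
#'   the reference replicate SD exceeds 0.5 cycles — a precision diagnostic,
#'   not a filter).
#' @export
plate_derivations <- function(wells, target, global_mean = NULL) {
  w <- filter_target(wells, target)
  global_mean <- global_mean %||% global_reference_mean(wells, target)
  plates_with_samples <- unique(w$plate_id[w$role == "sample"])
  refs <- dplyr::filter(w, .data$role == "reference", !is.na(.data$ct))
  orphans <- setdiff(plates_with_samples, unique(refs$plate_id))
  if (length(orphans) > 0) {
    fb_abort(paste0("plate(s) with samples but no reference wells: ",
                    paste(orphans, collapse = ", ")), "no_reference")
  }
  refs |>
    dplyr::group_by(.data$plate_id) |>
    dplyr::summarise(
      n_ref = dplyr::n(),
      plate_ref_mean = mean(.data$ct),
      ref_sd = sd(.data$ct),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      target = target,
      derivation = .data$plate_ref_mean - global_mean,
      ref_sd_flag = !is.na(.data$ref_sd) & .data$ref_sd > 0.5
    ) |>
    dplyr::select("plate_id", "target", "n_ref", "plate_ref_mean",
                  "derivation", "ref_sd_flag")
}

#' Apply plate corrections to raw Ct values
#'
#' Subtracts each well's plate derivation from its Ct. Wells on a plate
#' without a correction raise an error naming the plate.
#'
#' @inheritParams global_reference_mean
#' @param corrections Output of [plate_derivations()].
#' @return `wells` (for the corrected target) with a `ct_corrected` column.
#' @export
correct_ct <- function(wells, corrections) {
  check_columns(corrections, c("plate_id", "target", "derivation"),
                "correction table")
  target <- unique(corrections$target)
  stopifnot(length(target) == 1)
  w <- filter_target(wells, target)
  missing <- setdiff(unique(w$plate_id), corrections$plate_id)
  if (length(missing) > 0) {
    fb_abort(paste0("no Ct correction for plate(s): ",
                    paste(missing, collapse = ", ")), "missing_correction")
  }
  w |>
    dplyr::left_join(
      dplyr::select(corrections, "plate_id", "derivation"),
      by = "plate_id"
    ) |>
    dplyr::mutate(ct_corrected = .data$ct - .data$derivation)
}

#' Fit the master calibration curve
#'
#' Ordinary least squares of corrected Ct on log10(copies per reaction),
#' pooling the standards of all plates. The amplification efficiency is
#' `10^(-1/slope) - 1` (1 = perfect doubling each cycle).
#'
#' @param wells Corrected well table (from [correct_ct()]), containing
#'   standard wells with `known_conc` > 0.
#' @param target `"16S"` or `"18S"`.
#' @return An object of class `master_curve`: list with `target`, `slope`
#'   (cycles per log10 copies), `intercept` (Ct at 1 copy), `r_squared`,
#'   `efficiency`, `n_standards`, and `positive_slope_flag`.
#' @export
fit_master_curve <- function(wells, target) {
  check_columns(wells, c("role", "target", "ct_corrected", "known_conc"),
                "corrected well table")
  std <- wells |>
    dplyr::filter(.data$target == !!target, .data$role == "standard",
                  !is.na(.data$ct_corrected))
  if (any(is.na(std$known_conc)) || any(std$known_conc <= 0)) {
    fb_abort("standards must have known_conc > 0", "bad_standard")
  }
  if (length(unique(std$known_conc)) < 2) {
    fb_abort("need standards at >= 2 distinct concentrations to fit a curve",
             "too_few_standards")
  }
  fit <- lm(ct_corrected ~ log10(known_conc), data = std)
  slope <- unname(coef(fit)[2])
  tss <- sum((std$ct_corrected - mean(std$ct_corrected))^2)
  r2 <- if (tss > 0) 1 - sum(fit$residuals^2) / tss else 1
  structure(
    list(
      target = target,
      slope = slope,
      intercept = unname(coef(fit)[1]),
      r_squared = r2,
      efficiency = 10^(-1 / slope) - 1,
      n_standards = nrow(std),
      positive_slope_flag = slope >= 0
    ),
    class = "master_curve"
  )
}

#' @export
print.master_curve <- function(x, ...) {
  cat("Master calibration curve (", x$target, ")\n", sep = "")
  cat(sprintf("  Ct = %.4f %+.4f * log10(copies)   (n = %d standards)\n",
              x$intercept, x$slope, x$n_standards))
  cat(sprintf("  r^2 = %.4f, efficiency = %.3f\n", x$r_squared, x$efficiency))
  if (x$positive_slope_flag) cat("  WARNING: non-negative slope\n")
  invisible(x)
}

#' @method tidy master_curve
#' @export
tidy.master_curve <- function(x, ...) {
  tibble::tibble(
    target = x$target,
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope)
  )
}

#' @method glance master_curve
#' @export
glance.master_curve <- function(x, ...) {
  tibble::tibble(
    target = x$target, slope = x$slope, intercept = x$intercept,
    r_squared = x$r_squared, efficiency = x$efficiency,
    n_standards = x$n_standards
  )
}

#' Quantify samples against a master curve
#'
#' Inverts the calibration line: `copies_per_reaction =
#' 10^((ct_corrected - intercept) / slope)`, then scales to copies per gram of
#' dry soil by the `conversion` factor (copies/g per copies/reaction).
#' Replicate wells of a sample are averaged on the Ct scale before inversion.
#' Absolute densities are only comparable across studies within one fixed
#' conversion convention; the default corresponds to a 20 ug DNA yield per g
#' soil and a 2 ng template per reaction.
#'
#' @param wells Corrected well table (from [correct_ct()]).
#' @param curve A [fit_master_curve()] object.
#' @param conversion Copies-per-g per copies-per-reaction factor (> 0).
#' @return A tibble: `sample_id`, `target`, `n_wells`, `ct_corrected` (mean),
#'   `copies_per_reaction`, `copies_per_g`. Samples whose wells are all
#'   missing Ct propagate `NA` densities.
#' @export
qpcr_quantify <- function(wells, curve, conversion = 1e4) {
  stopifnot(inherits(curve, "master_curve"))
  if (curve$slope >= 0) fb_abort("master curve slope must be negative",
                                 "bad_curve")
  if (!is.numeric(conversion) || conversion <= 0) {
    fb_abort("conversion factor must be > 0", "bad_conversion")
  }
  check_columns(wells, c("role", "target", "sample_id", "ct_corrected"),
                "corrected well table")
  wells |>
    dplyr::filter(.data$target == curve$target, .data$role == "sample") |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      n_wells = sum(!is.na(.data$ct_corrected)),
      ct_corrected = mean(.data$ct_corrected, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      ct_corrected = ifelse(.data$n_wells == 0, NA_real_, .data$ct_corrected),
      target = curve$target,
      copies_per_reaction =
        10^((.data$ct_corrected - curve$intercept) / curve$slope),
      copies_per_g = .data$copies_per_reaction * conversion
    ) |>
    dplyr::select("sample_id", "target", "n_wells", "ct_corrected",
                  "copies_per_reaction", "copies_per_g")
}

#' Fungal:bacterial ratio
#'
#' `100 * (18S rDNA copies per g soil) / (16S rDNA copies per g soil)`; the
#' x100 scale puts typical soils in the 1-5 band.
#'
#' @param fungal,bacterial Positive densities (copies/g), recycled as usual.
#' @return Numeric F:B ratio(s).
#' @export
fb_ratio <- function(fungal, bacterial) {
  if (any(!is.na(bacterial) & bacterial <= 0)) {
    fb_abort("bacterial density must be > 0 to form an F:B ratio",
             "bad_density")
  }
  if (any(!is.na(fungal) & fungal <= 0)) {
    fb_abort("fungal density must be > 0 to form an F:B ratio", "bad_density")
  }
  100 * fungal / bacterial
}

#' Calibrate a full plate set to densities
#'
#' Runs the complete master-curve chain for one target: global reference
#' mean, per-plate derivations, Ct correction, master-curve fit, and sample
#' quantification. 16S and 18S are calibrated independently (separate
#' reference means, derivations, and curves); call once per target.
#'
#' @inheritParams global_reference_mean
#' @inheritParams qpcr_quantify
#' @return An object of class `qpcr_calibration`: list with `densities`
#'   (tibble), `curve`, `derivations`, `global_reference_mean`, `conversion`,
#'   `n_samples`, `n_quantified`.
#' @examples
#' plates <- simulate_plates(
#'   tibble::tibble(sample_id = paste0("s", 1:6),
#'                  copies_per_g = 10^runif(6, 7, 10)),
#'   target = "16S", seed = 1
#' )
#' cal <- calibrate_plates(plates$wells, "16S")
#' cal$densities
#' @export
calibrate_plates <- function(wells, target, conversion = 1e4) {
  gm <- global_reference_mean(wells, target)
  der <- plate_derivations(wells, target, gm)
  corr <- correct_ct(wells, der)
  curve <- fit_master_curve(corr, target)
  dens <- qpcr_quantify(corr, curve, conversion)
  structure(
    list(
      densities = dens,
      curve = curve,
      derivations = der,
      global_reference_mean = gm,
      conversion = conversion,
      n_samples = nrow(dens),
      n_quantified = sum(!is.na(dens$copies_per_g))
    ),
    class = "qpcr_calibration"
  )
}

#' @export
print.qpcr_calibration <- function(x, ...) {
  cat("qPCR calibration (", x$curve$target, ")\n", sep = "")
  cat(sprintf("  global reference mean Ct: %.3f over %d plates\n",
              x$global_reference_mean, nrow(x$derivations)))
  cat(sprintf("  samples quantified: %d / %d\n", x$n_quantified, x$n_samples))
  print(x$curve)
  invisible(x)
}

#' @method glance qpcr_calibration
#' @export
glance.qpcr_calibration <- function(x, ...) {
  dplyr::bind_cols(
    glance(x$curve),
    tibble::tibble(
      global_reference_mean = x$global_reference_mean,
      n_plates = nrow(x$derivations),
      n_samples = x$n_samples,
      n_quantified = x$n_quantified
    )
  )
}

#' Serialize a calibration report to JSON
#'
#' @param x A [calibrate_plates()] object.
#' @param path File path to write.
#' @return `path`, invisibly.
#' @export
write_calibration_report <- function(x, path) {
  stopifnot(inherits(x, "qpcr_calibration"))
  jsonlite::write_json(
    list(
      target = x$curve$target,
      global_reference_mean = x$global_reference_mean,
      derivations = x$derivations,
      curve = as.list(glance(x$curve)),
      conversion = x$conversion,
      n_samples = x$n_samples,
      n_quantified = x$n_quantified
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
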