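test_that("global reference mean pools all reference wells across plates", {
  w <- toy_wells(list(P1 = c(20, 20, 20), P2 = c(22, 22, 22)))
  expect_equal(global_reference_mean(w, "16S"), 21.0)
  expect_equal(global_reference_mean(toy_wells(list(P1 = c(20, 21, 22))),
                                     "16S"), 21.0)
  empty <- toy_wells()[0, ]
  expect_error(global_reference_mean(empty, "16S"),
               class = "fbgeo_error_no_reference")
})

test_that("plate derivations are plate reference mean minus global mean", {
  w <- toy_wells(list(P1 = c(20, 20, 20), P2 = c(22, 22, 22)))
  der <- plate_derivations(w, "16S")
  expect_equal(der$derivation[der$plate_id == "P2"], 1.0)
  expect_equal(der$derivation[der$plate_id == "P1"], -1.0)
  # a plate whose references sit at the global mean gets derivation zero
  w1 <- toy_wells(list(P1 = c(21, 21, 21), P2 = c(20, 22)))
  der1 <- plate_derivations(w1, "16S")
  expect_equal(der1$derivation[der1$plate_id == "P1"], 0.0)
  # a plate with samples but no references is an error naming the plate
  bad <- dplyr::bind_rows(
    toy_wells(list(P1 = c(20, 21))),
    tibble::tibble(plate_id = "P9", target = "16S", role = "sample",
                   sample_id = "s1", replicate = 1L, ct = 25,
                   known_conc = NA_real_))
  expect_error(plate_derivations(bad, "16S"), "P9",
               class = "fbgeo_error_no_reference")
})

test_that("noiseless simulated plates recover planted offsets exactly (centred)", {
  cfg <- synthetic_config(plates = list(
    samples_per_plate = 5, offset_sd = 0.5, ct_sd = 0, reps = 3,
    standard_decades = 2:6, reference_copies = 1e5, slope = -3.3219,
    intercept = 38))
  tc <- tibble::tibble(sample_id = paste0("s", 1:50),
                       copies_per_g = 10^seq(7, 10, length.out = 50))
  pl <- simulate_plates(tc, cfg, seed = 11)
  der <- plate_derivations(pl$wells, "16S")
  planted <- pl$truth$plate_offsets[der$plate_id]
  # the global anchor absorbs the mean offset; the centred offsets are
  # identified exactly
  expect_equal(der$derivation, unname(planted - mean(pl$truth$plate_offsets)),
               tolerance = 1e-12)
})

test_that("Ct correction subtracts the derivation and recentres every plate", {
  w <- toy_wells(list(P1 = c(20, 20, 20), P2 = c(22, 22, 22)))
  w <- dplyr::bind_rows(w, tibble::tibble(
    plate_id = "P2", target = "16S", role = "sample", sample_id = "s1",
    replicate = 1L, ct = 25, known_conc = NA_real_))
  der <- plate_derivations(w, "16S")
  corr <- correct_ct(w, der)
  expect_equal(corr$ct_corrected[corr$role == "sample"], 24.0)
  # derivation zero leaves Ct unchanged
  w0 <- toy_wells(list(P1 = c(21, 21)))
  c0 <- correct_ct(w0, plate_derivations(w0, "16S"))
  expect_equal(c0$ct_corrected, c0$ct)
  # recentring identity on arbitrary noisy input
  set.seed(42)
  wn <- toy_wells(list(P1 = rnorm(3, 20), P2 = rnorm(3, 23),
                       P3 = rnorm(3, 19)))
  cn <- correct_ct(wn, plate_derivations(wn, "16S"))
  gm <- global_reference_mean(wn, "16S")
  per_plate <- tapply(cn$ct_corrected, cn$plate_id, mean)
  expect_true(all(abs(per_plate - gm) < 1e-12))
  # idempotence: derivations recomputed on corrected data are all zero
  cn2 <- dplyr::mutate(cn, ct = ct_corrected)
  der2 <- plate_derivations(cn2, "16S")
  expect_true(all(abs(der2$derivation) < 1e-12))
})

test_that("master curve recovers an exact calibration line", {
  std <- toy_standards(decades = 2:6)
  curve <- fit_master_curve(std, "16S")
  expect_equal(curve$slope, -3.3219, tolerance = 1e-10)
  expect_equal(curve$intercept, 40.0, tolerance = 1e-10)
  expect_equal(curve$r_squared, 1.0, tolerance = 1e-12)
  expect_equal(curve$efficiency, 1.0, tolerance = 1e-3)
})

test_that("master curve slope is stable under replicate Ct noise", {
  set.seed(7)
  std <- toy_standards(decades = 2:7, reps = 3, noise_sd = 0.1)
  curve <- fit_master_curve(std, "16S")
  expect_lt(abs(curve$slope - (-3.3219)), 0.05)
  expect_error(fit_master_curve(toy_standards(decades = 3), "16S"),
               class = "fbgeo_error_too_few_standards")
})

test_that("quantification inverts the curve and decreases in Ct", {
  std <- toy_standards(decades = 2:6)
  curve <- fit_master_curve(std, "16S")
  wells <- tibble::tibble(
    plate_id = "P1", target = "16S", role = "sample",
    sample_id = c("a", "b", "c"), replicate = 1L,
    ct = NA_real_, known_conc = NA_real_,
    ct_corrected = c(40, 36.6781, 30))
  q <- qpcr_quantify(wells, curve, conversion = 1)
  expect_equal(q$copies_per_reaction[q$sample_id == "a"], 1.0,
               tolerance = 1e-6)
  expect_equal(q$copies_per_reaction[q$sample_id == "b"], 10.0,
               tolerance = 1e-4)
  # strictly decreasing in corrected Ct
  ord <- order(q$ct_corrected)
  expect_true(all(diff(q$copies_per_g[ord]) < 0))
})

test_that("noiseless generate -> calibrate round trip is exact", {
  cfg <- synthetic_config(plates = list(
    samples_per_plate = 8, offset_sd = 0.8, ct_sd = 0, reps = 3,
    standard_decades = 2:7, reference_copies = 1e5, slope = -3.4,
    intercept = 37), conversion = 1e4)
  tc <- tibble::tibble(sample_id = paste0("s", 1:40),
                       copies_per_g = 10^runif(40, 6.5, 10.5))
  pl <- simulate_plates(tc, cfg, seed = 5)
  cal <- calibrate_plates(pl$wells, "16S", conversion = 1e4)
  got <- cal$densities$copies_per_g[match(tc$sample_id,
                                          cal$densities$sample_id)]
  expect_lt(max(abs(got / tc$copies_per_g - 1)), 1e-9)
  expect_equal(cal$n_quantified, 40L)
})

test_that("missing Ct propagates as missing density with a success count", {
  w <- dplyr::bind_rows(
    toy_wells(list(P1 = c(20, 20, 20))),
    toy_standards(decades = 2:6)[, 1:7],
    tibble::tibble(plate_id = "P1", target = "16S", role = "sample",
                   sample_id = c("ok", "failed"), replicate = 1L,
                   ct = c(30, NA), known_conc = NA_real_))
  cal <- calibrate_plates(w, "16S")
  expect_equal(cal$n_samples, 2L)
  expect_equal(cal$n_quantified, 1L)
  expect_true(is.na(
    cal$densities$copies_per_g[cal$densities$sample_id == "failed"]))
})

test_that("F:B ratio is the x100 fungal over bacterial density", {
  expect_equal(fb_ratio(1e8, 1e10), 1.0)
  expect_equal(fb_ratio(5e9, 5e9), 100.0)
  expect_equal(fb_ratio(2.72e8, 1e10), 2.72)
  expect_error(fb_ratio(1e8, 0), class = "fbgeo_error_bad_density")
  expect_error(fb_ratio(-1, 1e10), class = "fbgeo_error_bad_density")
})
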