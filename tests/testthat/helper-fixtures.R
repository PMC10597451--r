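# Shared fixture builders. Everything is generated in code; no stored data.

# minimal two-plate well table with hand-set reference Cts
toy_wells <- function(ref_cts = list(P1 = c(20, 20, 20), P2 = c(22, 22, 22)),
                      target = "16S") {
  dplyr::bind_rows(lapply(names(ref_cts), function(p) {
    tibble::tibble(
      plate_id = p, target = target, role = "reference",
      sample_id = "ref", replicate = seq_along(ref_cts[[p]]),
      ct = ref_cts[[p]], known_conc = NA_real_
    )
  }))
}

# exact calibration line: Ct = intercept + slope * log10(conc)
toy_standards <- function(decades = 2:6, slope = -3.3219, intercept = 40,
                          reps = 1, noise_sd = 0, target = "16S",
                          plate_id = "P1") {
  conc <- rep(10^decades, each = reps)
  tibble::tibble(
    plate_id = plate_id, target = target, role = "standard",
    sample_id = sprintf("std_%g", conc), replicate = 1L,
    ct = intercept + slope * log10(conc) + rnorm(length(conc), 0, noise_sd),
    known_conc = conc, ct_corrected = NA_real_
  ) |>
    dplyr::mutate(ct_corrected = ct)
}

# small spatial sample set drawn from a planted exponential field
toy_field_samples <- function(n = 120, extent = 400, nugget = 0.2,
                              psill = 0.8, eff_range = 84, seed = 1) {
  withr::with_seed(seed, {
    loc <- tibble::tibble(x = runif(n, 0, extent), y = runif(n, 0, extent))
    f <- simulate_field(loc, nugget, psill, eff_range, seed = seed + 1)[, 1]
    tibble::tibble(x = loc$x, y = loc$y, value = f)
  })
}

# direct generalized-least-squares kriging oracle using the full covariance:
# mu_gls = (1' S^-1 z)/(1' S^-1 1); zhat = mu + c' S^-1 (z - mu);
# var = sill - c' S^-1 c + (1 - 1' S^-1 c)^2 / (1' S^-1 1)
ok_oracle <- function(model, samples, target) {
  a <- model$range
  sill <- model$nugget + model$psill
  cov_h <- function(h) {
    cc <- model$psill * matern_correlation(h, a, model$nu)
    cc[h == 0] <- sill
    cc
  }
  S <- cov_h(as.matrix(dist(cbind(samples$x, samples$y))))
  d0 <- sqrt((samples$x - target[1])^2 + (samples$y - target[2])^2)
  cvec <- cov_h(d0)
  Si <- solve(S)
  one <- rep(1, nrow(samples))
  mu <- sum(Si %*% samples$value) / sum(Si %*% one)
  zhat <- mu + as.numeric(t(cvec) %*% Si %*% (samples$value - mu))
  v <- sill - as.numeric(t(cvec) %*% Si %*% cvec) +
    (1 - sum(Si %*% cvec))^2 / sum(Si %*% one)
  list(estimate = zhat, variance = v)
}
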