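# Shared fixtures: small-scale simulator scenes, a brute-force gamma
# oracle, and cached full-scale pipelines for the validation tests.

# Small calibration layout (8 x 6 mm films) keeps unit-test scenes tiny.
small_layout <- function(...) {
  calibration_layout(film_size_mm = c(8, 6), margin_mm = 3, ...)
}

noiseless_scanner <- function(drift_amplitude = 0.01, ...) {
  scanner_model(drift_amplitude = drift_amplitude, pixel_noise_sd = 0, ...)
}

# Smooth random dose field: a constant floor plus a few Gaussian bumps,
# so gamma values stay moderate and the full search disc is exercised.
smooth_field <- function(n, seed, base = 5) {
  set.seed(seed)
  x <- seq_len(n)
  X <- matrix(x, n, n, byrow = TRUE)
  Y <- matrix(x, n, n)
  m <- matrix(0.2, n, n)
  for (k in 1:4) {
    m <- m + runif(1, 1, base) *
      exp(-((X - runif(1, 2, n - 1))^2 + (Y - runif(1, 2, n - 1))^2) /
            (2 * runif(1, 2, 6)^2))
  }
  m
}

# Exhaustive gamma: bilinear-interpolate the evaluated plane on the full
# sub-pixel grid (no search-radius cut) and scan every sample for every
# reference pixel. Independent of the package's shifted-matrix search.
gamma_brute <- function(ref, ev, crit) {
  R <- ref$dose; E <- ev$dose; sp <- ref$pixel_spacing
  n <- nrow(R); m <- ncol(R)
  step <- crit$interp_step * crit$dta
  xs <- seq(0, (m - 1) * sp, by = step)
  ys <- seq(0, (n - 1) * sp, by = step)
  jx <- xs / sp + 1; iy <- ys / sp + 1
  j0 <- pmin(pmax(floor(jx), 1), m - 1); fj <- jx - j0
  i0 <- pmin(pmax(floor(iy), 1), n - 1); fi <- iy - i0
  Efine <- matrix(NA_real_, length(ys), length(xs))
  for (r in seq_along(ys)) {
    a <- E[i0[r], j0] * (1 - fi[r]) + E[i0[r] + 1, j0] * fi[r]
    b <- E[i0[r], j0 + 1] * (1 - fi[r]) + E[i0[r] + 1, j0 + 1] * fi[r]
    Efine[r, ] <- a * (1 - fj) + b * fj
  }
  dd <- crit$dose_diff / 100 * max(R)
  thr <- crit$low_dose_threshold / 100 * max(R)
  ef <- as.vector(Efine)
  px <- rep(xs, each = length(ys))
  py <- rep(ys, times = length(xs))
  G <- matrix(NA_real_, n, m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      if (R[i, j] < thr) next
      g2 <- ((ef - R[i, j]) / dd)^2 +
        ((px - (j - 1) * sp)^2 + (py - (i - 1) * sp)^2) / crit$dta^2
      G[i, j] <- sqrt(min(g2))
    }
  }
  G
}

# Full-scale synthetic pipelines, built once and shared between the
# round-trip and temporal-validation tests.
.fixture_cache <- new.env(parent = emptyenv())

# TCM + measurement series on a common schedule for one film type.
synthetic_pipeline <- function(times, key) {
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  layout <- calibration_layout()
  growth <- film_growth_models("EBT-XD")
  scanner <- noiseless_scanner()
  cal <- simulate_calibration_series(layout, growth, scanner, times = times)
  tcm <- build_tcm(cal, layout, channel = "red", film_type = "EBT-XD")
  truth <- make_dose_plane("gaussian", peak = 12, size_px = c(100, 100),
                           pixel_spacing = 1, sigma_mm = 15)
  meas <- simulate_measurement_series(truth, growth, scanner, times = times)
  out <- list(tcm = tcm, truth = truth, meas = meas, times = times)
  .fixture_cache[[key]] <- out
  out
}

roundtrip_pipeline <- function() {
  synthetic_pipeline(seq(5, 1440, by = 35), "roundtrip")
}

validation_pipeline <- function() {
  synthetic_pipeline(seq(30, 1440, by = 30), "validation")
}
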