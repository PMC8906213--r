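# A hand-built TCM with known coefficients for lookup/apply tests.
toy_curve <- function(t, coeffs = c(a = 0, b = 0, c = 10, d = 0),
                      bg = 40000, od_max = Inf) {
  structure(list(t_post = t, coeffs = coeffs, background_intensity = bg,
                 channel = "red", od_range = c(0, od_max),
                 rms_residual = 0),
            class = "calibration_curve")
}

toy_tcm <- function(times, interval = NULL, ...) {
  if (is.null(interval)) {
    interval <- if (length(times) > 1) diff(times)[1] else NA_real_
  }
  filmtcm:::new_tcm(lapply(times, toy_curve, ...), film_type = "toy",
                    batch = "toy", interval = interval, channel = "red")
}

test_that("curve lookup picks the nearest time, earlier on ties", {
  tcm <- toy_tcm(seq(5, 1440, by = 5))
  expect_equal(lookup_curve(tcm, 600)$t_post, 600)
  expect_equal(attr(lookup_curve(tcm, 600), "mismatch"), 0)
  expect_equal(lookup_curve(tcm, 602)$t_post, 600)
  expect_equal(attr(lookup_curve(tcm, 602), "mismatch"), -2)
  expect_equal(lookup_curve(tcm, 602.5)$t_post, 600)  # tie -> earlier
})

test_that("lookup rejects empty models and out-of-coverage times", {
  tcm <- toy_tcm(c(60, 120, 180))
  expect_error(lookup_curve(tcm, 600), "coverage")
  expect_lt(lookup_curve(tcm, 300)$t_post, 600)  # exactly at 2x interval: ok
  empty <- structure(list(curves = list(), interval = 5, channel = "red"),
                     class = "tcm")
  expect_error(lookup_curve(empty, 60), "no curves")
})

test_that("od_plane applies Eq-1 pixel-wise with clamping and zero patching", {
  base <- matrix(40000, 4, 4)
  scan <- scan_image(base, base, base, t_post = 60)
  od <- od_plane(scan, 40000, "red")
  expect_true(all(od == 0))

  m <- base; m[2, 2] <- 4000; m[3, 3] <- 0; m[1, 4] <- 50000  # brighter than i0
  scan2 <- scan_image(m, base, base, t_post = 60)
  od2 <- od_plane(scan2, 40000, "red")
  expect_equal(od2[2, 2], 1)                   # i0/10 -> OD 1
  expect_equal(od2[1, 4], 0)                   # I >= i0 clamps to 0
  expect_equal(attr(od2, "zero_pixels"), 1)    # zero patched and counted
  expect_equal(od2[3, 3], log10(40000))        # patched to 1 count
  expect_error(od_plane(scan, -1, "red"), "positive")
})

test_that("apply_curve evaluates the cubic with clamping and provenance counts", {
  od <- matrix(0.5, 3, 3)
  plane <- apply_curve(od, toy_curve(60), pixel_spacing = 1)
  expect_true(all(plane$dose == 5))  # linear curve: 10 * 0.5

  # negative doses clamp to zero and are counted
  neg <- apply_curve(matrix(0.01, 2, 2),
                     toy_curve(60, coeffs = c(a = 0, b = 0, c = 10, d = -1)),
                     pixel_spacing = 1)
  expect_true(all(neg$dose == 0))
  expect_equal(unname(attr(neg, "clamps")["negative_dose"]), 4)

  # out-of-range ODs clamp to the boundary dose and are counted
  capped <- apply_curve(matrix(c(0.2, 0.9), 1, 2),
                        toy_curve(60, od_max = 0.5), pixel_spacing = 1)
  expect_equal(as.vector(capped$dose), c(2, 5))
  expect_equal(unname(attr(capped, "clamps")["od_clamped"]), 1)
})

test_that("apply_curve is pixel-separable", {
  set.seed(11)
  od <- matrix(runif(48, 0, 0.6), 6, 8)
  cv <- toy_curve(60, coeffs = c(a = 3, b = -1, c = 12, d = 0))
  whole <- apply_curve(od, cv, pixel_spacing = 1)
  sub <- apply_curve(od[2:4, 3:6], cv, pixel_spacing = 1)
  expect_identical(whole$dose[2:4, 3:6], sub$dose)
})

test_that("time-matched conversion is accurate and unbiased on synthetic scans", {
  lay <- small_layout()
  gr <- film_growth_models("EBT-XD")
  sc <- noiseless_scanner()
  times <- seq(5, 1385, by = 345)
  series <- simulate_calibration_series(lay, gr, sc, times = times)
  tcm <- build_tcm(series, lay, channel = "red")
  truth <- make_dose_plane("gaussian", peak = 12, size_px = c(40, 40),
                           pixel_spacing = 1, sigma_mm = 8)
  for (t in times) {
    meas <- render_measurement_scan(truth, gr, sc, t)
    rec <- convert_scan(meas, tcm, t)
    err <- rec$dose - truth$dose
    expect_lt(max(abs(err)), 0.02 * max(truth$dose))
    expect_lt(abs(mean(err)), 0.005 * max(truth$dose))
    prov <- attr(rec, "provenance")
    expect_equal(prov$mismatch_min, 0)
    expect_equal(prov$i0_source, "tcm_background")
  }
})

test_that("converting an early scan with a late curve underestimates dose", {
  lay <- small_layout()
  gr <- film_growth_models("EBT-XD")
  # drift off isolates the OD-growth effect whose sign is under test
  sc <- noiseless_scanner(drift_amplitude = 0)
  series <- simulate_calibration_series(lay, gr, sc,
                                        times = seq(5, 1205, by = 600))
  tcm <- build_tcm(series, lay, channel = "red")
  truth <- make_dose_plane("gaussian", peak = 12, size_px = c(30, 30),
                           pixel_spacing = 1, sigma_mm = 8)
  meas <- render_measurement_scan(truth, gr, sc, 5)
  rec <- convert_scan(meas, tcm, t_post = 1205)  # wrong (late) curve
  # above ~3 Gy the growth deficit (~7% of dose) dominates the cubic-fit
  # residual, so the underestimate is strict pixel by pixel
  hot <- truth$dose > 3
  expect_true(all(rec$dose[hot] < truth$dose[hot]))
  expect_lt(mean(rec$dose[hot] - truth$dose[hot]), -0.05 * 3)
})

test_that("fixed-curve conversion error shrinks as scan time approaches the curve's", {
  lay <- small_layout()
  gr <- film_growth_models("EBT-XD")
  sc <- noiseless_scanner(drift_amplitude = 0)
  times <- seq(30, 1230, by = 300)
  series <- simulate_calibration_series(lay, gr, sc, times = times)
  tcm <- build_tcm(series, lay, channel = "red")
  truth <- make_dose_plane("uniform", peak = 10, size_px = c(10, 10))
  errs <- vapply(times, function(t) {
    meas <- render_measurement_scan(truth, gr, sc, t)
    rec <- convert_scan(meas, tcm, t_post = 1230)
    mean(abs(rec$dose - truth$dose))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("an in-scan reference rectangle can supply I0", {
  base <- matrix(40000, 6, 6)
  m <- base; m[4:6, 4:6] <- 4000
  scan <- scan_image(m, base, base, t_post = 60)
  tcm <- toy_tcm(c(30, 60, 90), bg = NA_real_)
  expect_error(convert_scan(scan, tcm, 60), "background")
  rec <- convert_scan(scan, tcm, 60, i0_rect = c(x = 1, y = 1, w = 3, h = 3))
  expect_equal(rec$dose[5, 5], 10)  # OD 1 through the linear toy curve
  expect_equal(attr(rec, "provenance")$i0_source, "in_scan_reference")
})
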