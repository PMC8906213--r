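test_that("calibrate detection returns all films in reading order", {
  lay <- small_layout()
  gr <- film_growth_models("EBT-XD")
  scan <- render_calibration_scan(lay, gr, noiseless_scanner(), 60)
  rects <- locate_calibrates(scan, lay)
  expect_length(rects, 10)
  xs <- vapply(rects, function(r) r[["x"]], numeric(1))
  ys <- vapply(rects, function(r) r[["y"]], numeric(1))
  # reading order: two rows of five, left to right within each row
  expect_true(all(ys[1:5] < min(ys[6:10])))
  expect_true(all(diff(xs[1:5]) > 0))
  expect_true(all(diff(xs[6:10]) > 0))
  # rectangles fully inside the image
  for (r in rects) {
    expect_gte(r[["x"]], 1)
    expect_gte(r[["y"]], 1)
    expect_lte(r[["x"]] + r[["w"]] - 1, ncol(scan$red))
    expect_lte(r[["y"]] + r[["h"]] - 1, nrow(scan$red))
  }
})

test_that("detection fails loudly on empty or cropped scenes", {
  lay <- small_layout()
  bg <- matrix(64224, 40, 120)
  empty <- scan_image(bg, bg, bg, t_post = 5)
  expect_error(locate_calibrates(empty, lay), "found 0")

  gr <- film_growth_models("EBT-XD")
  scan <- render_calibration_scan(lay, gr, noiseless_scanner(), 60)
  # occlude the last film of the bottom row with background
  last <- locate_calibrates(scan, lay)[[10]]
  rows <- last[["y"]]:(last[["y"]] + last[["h"]] - 1L)
  cols <- last[["x"]]:(last[["x"]] + last[["w"]] - 1L)
  occluded <- scan
  occluded$red[rows, cols] <- 64224
  expect_error(locate_calibrates(occluded, lay), "found 9")
})

test_that("central ROI has one-third area, same centre, floor rounding", {
  roi <- center_roi(c(x = 11, y = 21, w = 90, h = 60))
  expect_equal(unname(roi[c("w", "h")]), c(51, 34))  # floor(side / sqrt(3))
  area_ratio <- (roi[["w"]] * roi[["h"]]) / (90 * 60)
  expect_lt(abs(area_ratio - 1 / 3), 0.02)
  # concentric within half a pixel
  expect_lt(abs((roi[["x"]] + roi[["w"]] / 2) - (11 + 90 / 2)), 1)
  expect_lt(abs((roi[["y"]] + roi[["h"]] / 2) - (21 + 60 / 2)), 1)
  # degenerate film still yields a >= 1 px ROI
  tiny <- center_roi(c(x = 1, y = 1, w = 3, h = 3))
  expect_gte(tiny[["w"]], 1)
  expect_gte(tiny[["h"]], 1)
})

test_that("net optical density follows log10(I0/I)", {
  expect_equal(net_od(12345, 12345), 0)
  expect_equal(net_od(40000, 4000), 1)
  expect_equal(net_od(52000, 26000), log10(2), tolerance = 1e-9)
  expect_equal(net_od(52000, 26000), 0.301030, tolerance = 1e-6)
  expect_error(net_od(0, 100), "positive")
  expect_error(net_od(100, -3), "positive")
})

test_that("cubic fit recovers exact cubic data and flags degenerate designs", {
  od <- seq(0, 0.5, length.out = 10)
  dose <- 2.5 * od^3 - 1.2 * od^2 + 30 * od + 0
  cv <- fit_curve(dose, od, t_post = 60)
  expect_equal(unname(cv$coeffs), c(2.5, -1.2, 30, 0), tolerance = 1e-9)
  expect_error(fit_curve(c(0, 1, 2, 3), c(0, .1, .2, .3), 60), "at least 5")
  expect_error(fit_curve(c(1, 2, 3, 4, 5), c(.1, .2, .3, .4, .5), 60),
               "zero-dose")
  expect_error(fit_curve(c(0, 2, 4, 6, 8), rep(0.2, 5), 60), "rank-deficient")
})

test_that("cubic approximates the simulator's saturating response within 0.15 Gy", {
  gr <- film_growth_model("EBT-XD", "red")
  doses <- seq(0, 18, by = 2)
  ods <- od_at_time(doses, 1440, gr)
  cv <- fit_curve(doses, ods, t_post = 1440)
  expect_lt(max(abs(eval_curve(cv, ods) - doses)), 0.15)
  expect_lt(abs(cv$coeffs[["d"]]), 0.3)  # fit-quality gate at zero OD
  # monotone over the calibrated domain
  grid <- seq(0, cv$od_range[2], length.out = 200)
  expect_true(all(diff(eval_curve(cv, grid)) > 0))
})

test_that("ROI netOD from a noiseless scan matches the growth law, drift cancelled", {
  lay <- small_layout()
  gr <- film_growth_models("EBT-XD")
  sc <- noiseless_scanner(drift_amplitude = 0.01)  # drift ON
  for (t in c(5, 300, 1440)) {
    scan <- render_calibration_scan(lay, gr, sc, t)
    rects <- locate_calibrates(scan, lay)
    means <- vapply(rects, function(r)
      roi_stats(scan, center_roi(r))$mean_intensity[["red"]], numeric(1))
    ods <- net_od(means[1], means)
    expect_equal(ods, od_at_time(lay$doses, t, gr$red), tolerance = 1e-4)
  }
})

test_that("build_tcm yields one curve per scan with background from the same scan", {
  lay <- small_layout()
  gr <- film_growth_models("EBT3")
  sc <- noiseless_scanner()
  series <- simulate_calibration_series(lay, gr, sc, times = c(5, 35, 65))
  tcm <- build_tcm(series, lay, channel = "red", film_type = "EBT3",
                   batch = "sim")
  expect_length(tcm$curves, 3)
  expect_equal(tcm_times(tcm), c(5, 35, 65))
  expect_equal(tcm$interval, 30)
  # background intensity = zero-dose ROI of that scan (drift included)
  for (i in 1:3) {
    scan <- series$scans[[i]]
    r0 <- locate_calibrates(scan, lay)[[1]]
    expect_equal(tcm$curves[[i]]$background_intensity,
                 roi_stats(scan, center_roi(r0))$mean_intensity[["red"]])
  }
  # single-scan series degenerates to a conventional calibration
  one <- simulate_calibration_series(lay, gr, sc, times = 720)
  expect_length(build_tcm(one, lay)$curves, 1)
})

test_that("per-dose OD across a built TCM's scans is linear in log10(t)", {
  lay <- small_layout()
  gr <- film_growth_models("EBT-XD")
  sc <- noiseless_scanner()
  times <- seq(5, 1385, by = 115)
  series <- simulate_calibration_series(lay, gr, sc, times = times)
  for (D_idx in c(2, 10)) {  # 2 Gy and 18 Gy films
    ods <- vapply(series$scans, function(scan) {
      rects <- locate_calibrates(scan, lay)
      means <- vapply(rects, function(r)
        roi_stats(scan, center_roi(r))$mean_intensity[["red"]], numeric(1))
      net_od(means[1], means[D_idx])
    }, numeric(1))
    fit <- lm(ods ~ log10(times))
    expect_gt(summary(fit)$r.squared, 0.999)
  }
})

test_that("TCM CSV round-trips coefficients exactly and rejects bad files", {
  lay <- small_layout()
  series <- simulate_calibration_series(lay, film_growth_models("EBT-XD"),
                                        noiseless_scanner(),
                                        times = c(5, 605, 1205))
  tcm <- build_tcm(series, lay, channel = "red", film_type = "EBT-XD",
                   batch = "#04282002")
  path <- withr::local_tempfile(fileext = ".csv")
  tcm_to_csv(tcm, path)
  back <- csv_to_tcm(path)
  expect_equal(length(back$curves), 3)
  expect_equal(back$film_type, "EBT-XD")
  expect_equal(back$channel, "red")
  expect_equal(back$interval, 600)
  for (i in 1:3) {
    expect_identical(back$curves[[i]]$coeffs, tcm$curves[[i]]$coeffs)
    expect_identical(back$curves[[i]]$background_intensity,
                     tcm$curves[[i]]$background_intensity)
    expect_identical(back$curves[[i]]$od_range, tcm$curves[[i]]$od_range)
  }

  p2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_min,a,b,c,d",
               "5,1,2,3,0.1", "10,1,2,3,0.1"), p2)
  two <- csv_to_tcm(p2)
  expect_length(two$curves, 2)
  expect_equal(two$curves[[2]]$coeffs[["c"]], 3)

  writeLines(c("time_min,a,b,c,d", "10,1,2,3,0.1", "5,1,2,3,0.1"), p2)
  expect_error(csv_to_tcm(p2), "out of time order")
  writeLines(c("time_min,a,b,c,d", "5,1,2,oops,0.1"), p2)
  expect_error(csv_to_tcm(p2), "malformed.*row 1")
})
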