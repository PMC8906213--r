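#' Detect calibration films in a scan
#'
#' Films are darker than the background, so detection thresholds the red
#' channel and segments the grid by row/column projections: contiguous
#' dark column bands and row bands define the grid cells, and the bounding
#' box of dark pixels inside each occupied cell is one film rectangle.
#' Rectangles are returned in reading order (left to right, top to
#' bottom). Detection fails loudly if the count does not match the layout.
#'
#' @param image A [scan_image()].
#' @param layout A [calibration_layout()] giving the expected
#'   `rows x cols` count.
#' @param threshold Intensity below which a pixel counts as film; the
#'   default sits between the background sentinel and typical unexposed
#'   film.
#' @return List of rectangles `c(x, y, w, h)` in pixels (1-based,
#'   top-left anchored), length `prod(layout$grid)`.
#' @export
locate_calibrates <- function(image, layout, threshold = 60000) {
  stopifnot(inherits(image, "scan_image"),
            inherits(layout, "calibration_layout"))
  mask <- image$red < threshold
  expected <- prod(layout$grid)
  runs <- function(v) {
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    cbind(starts, ends)[r$values, , drop = FALSE]
  }
  col_bands <- runs(apply(mask, 2, any))
  row_bands <- runs(apply(mask, 1, any))
  rects <- list()
  for (rb in seq_len(nrow(row_bands))) {
    for (cb in seq_len(nrow(col_bands))) {
      sub <- mask[row_bands[rb, 1]:row_bands[rb, 2],
                  col_bands[cb, 1]:col_bands[cb, 2], drop = FALSE]
      if (!any(sub)) next
      ri <- range(which(apply(sub, 1, any)))
      ci <- range(which(apply(sub, 2, any)))
      rects[[length(rects) + 1L]] <-
        c(x = unname(col_bands[cb, 1]) + ci[1] - 1L,
          y = unname(row_bands[rb, 1]) + ri[1] - 1L,
          w = ci[2] - ci[1] + 1L,
          h = ri[2] - ri[1] + 1L)
    }
  }
  if (length(rects) != expected) {
    stop(sprintf("calibrate detection failed: found %d film(s), expected %d",
                 length(rects), expected))
  }
  rects
}

#' Central region of interest of a film rectangle
#'
#' Concentric rectangle with the same aspect ratio and one third of the
#' film's area (sides scaled by 1/sqrt(3)), floored to integer pixels with
#' a 1-px minimum side; centring ties resolve toward the top-left.
#'
#' @param rect Rectangle `c(x, y, w, h)` in pixels.
#' @return Rectangle `c(x, y, w, h)` of the ROI.
#' @export
center_roi <- function(rect) {
  w <- rect[["w"]]; h <- rect[["h"]]
  stopifnot(w > 0, h > 0)
  s <- 1 / sqrt(3)
  nw <- max(1L, as.integer(floor(w * s)))
  nh <- max(1L, as.integer(floor(h * s)))
  c(x = rect[["x"]] + as.integer(floor((w - nw) / 2)),
    y = rect[["y"]] + as.integer(floor((h - nh) / 2)),
    w = nw, h = nh)
}

#' Mean pixel statistics over a rectangle
#'
#' @param image A [scan_image()].
#' @param rect Rectangle `c(x, y, w, h)` in pixels.
#' @return Object of class `roi_stats`: per-channel mean intensity, pixel
#'   count and the rectangle.
#' @export
roi_stats <- function(image, rect) {
  rows <- rect[["y"]]:(rect[["y"]] + rect[["h"]] - 1L)
  cols <- rect[["x"]]:(rect[["x"]] + rect[["w"]] - 1L)
  stopifnot(min(rows) >= 1, max(rows) <= nrow(image$red),
            min(cols) >= 1, max(cols) <= ncol(image$red))
  structure(
    list(mean_intensity = c(red = mean(image$red[rows, cols]),
                            green = mean(image$green[rows, cols]),
                            blue = mean(image$blue[rows, cols])),
         pixel_count = length(rows) * length(cols),
         rectangle = rect),
    class = "roi_stats")
}

#' Net optical density
#'
#' `netOD = log10(I0 / I)` where `I0` is the mean pixel value of the
#' zero-dose reference and `I` the mean pixel value of the exposed region,
#' both from the same scan so that scanner drift cancels.
#'
#' @param i0 Zero-dose (reference) mean intensity, > 0.
#' @param i Exposed mean intensity, > 0 (vectorised).
#' @return netOD, zero when `i == i0`.
#' @export
net_od <- function(i0, i) {
  if (any(i0 <= 0) || any(i <= 0)) {
    stop("intensities must be positive to form an optical density")
  }
  log10(i0 / i)
}

#' Fit a cubic dose-response calibration curve
#'
#' Least-squares cubic with dose as the response and netOD as the
#' regressor, `dose = a*od^3 + b*od^2 + c*od + d`, so the stored
#' coefficients convert netOD to dose by direct evaluation (no root
#' finding). ODs are fit on their natural scale so the coefficients are
#' portable through the TCM CSV. The valid domain is
#' `od_range = (0, 1.05 * max(od))`; the fitted intercept (the dose at
#' zero netOD) is gated at |d| <= 0.3 Gy and monotonicity over the domain
#' is checked, each with a warning on violation.
#'
#' @param doses Doses in Gy (>= 5 points spanning the range, including
#'   the zero-dose point).
#' @param ods Matching netOD values.
#' @param t_post Minutes postirradiation of the scan the ODs came from.
#' @param channel Colour channel the ODs were measured in.
#' @param background_intensity Mean zero-dose pixel value of the same
#'   scan (the `I0` later applied to measurement films).
#' @return Object of class `calibration_curve` with fields `t_post`,
#'   `coeffs` (named a, b, c, d), `background_intensity`, `channel`,
#'   `od_range`, `rms_residual`.
#' @export
fit_curve <- function(doses, ods, t_post, channel = "red",
                      background_intensity = NA_real_) {
  stopifnot(length(doses) == length(ods))
  if (length(doses) < 5) {
    stop("calibration fit needs at least 5 dose points")
  }
  if (!any(doses == 0)) {
    stop("calibration fit requires the zero-dose point")
  }
  X <- cbind(1, ods, ods^2, ods^3)
  if (qr(X)$rank < 4) {
    stop("rank-deficient calibration design (degenerate netOD values)")
  }
  fit <- stats::lm.fit(X, doses)
  cf <- fit$coefficients
  coeffs <- c(a = unname(cf[4]), b = unname(cf[3]),
              c = unname(cf[2]), d = unname(cf[1]))
  od_range <- c(0, max(ods) * 1.05)
  curve <- structure(
    list(t_post = t_post, coeffs = coeffs,
         background_intensity = background_intensity,
         channel = channel, od_range = od_range,
         rms_residual = sqrt(mean(fit$residuals^2))),
    class = "calibration_curve")
  if (abs(coeffs[["d"]]) > 0.3) {
    warning(sprintf(
      "fit-quality gate: dose at zero netOD is %.3f Gy (|d| > 0.3 Gy)",
      coeffs[["d"]]))
  }
  if (!curve_is_monotone(curve)) {
    warning(sprintf(
      "calibration curve at t=%g min is not monotone over its OD domain",
      t_post))
  }
  curve
}

#' Evaluate a calibration curve
#' @param curve A [fit_curve()] result.
#' @param od netOD values (vector or matrix).
#' @return Dose in Gy, same shape as `od` (no clamping; see
#'   [apply_curve()] for the guarded pixel-wise version).
#' @export
eval_curve <- function(curve, od) {
  cf <- curve$coeffs
  cf[["a"]] * od^3 + cf[["b"]] * od^2 + cf[["c"]] * od + cf[["d"]]
}

curve_is_monotone <- function(curve, n = 256) {
  od <- seq(curve$od_range[1], curve$od_range[2], length.out = n)
  all(diff(eval_curve(curve, od)) > 0)
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "<calibration_curve> t=%g min, %s channel: dose = %.4g od^3 + %.4g od^2 + %.4g od + %.4g (rms %.3g Gy)\n",
    x$t_post, x$channel, x$coeffs[["a"]], x$coeffs[["b"]], x$coeffs[["c"]],
    x$coeffs[["d"]], x$rms_residual))
  invisible(x)
}

#' Build a temporal calibration model from a scan series
#'
#' For every scan of the series: detect the calibrates, take the central
#' one-third-area ROI of each, compute netOD against the zero-dose film of
#' the same scan (so scanner drift is factored into each curve), and fit
#' the cubic dose-response. The result is the TCM: a time-ordered series
#' of calibration curves, one per postirradiation scan time.
#'
#' @param series A [scan_series()] of calibration scans.
#' @param layout The [calibration_layout()]; `layout$doses` gives the dose
#'   of each film in reading order.
#' @param channel `"red"` or `"green"`.
#' @param film_type Label stored with the model (e.g. `"EBT3"`).
#' @param batch Batch label.
#' @return Object of class `tcm`: fields `curves` (time-ordered list of
#'   [fit_curve()] results), `film_type`, `batch`, `interval`, `channel`.
#' @export
build_tcm <- function(series, layout = calibration_layout(),
                      channel = c("red", "green"),
                      film_type = "unspecified", batch = "unspecified") {
  stopifnot(inherits(series, "scan_series"))
  channel <- match.arg(channel)
  zero_idx <- which(layout$doses == 0)
  if (length(zero_idx) != 1) {
    stop("layout must contain exactly one zero-dose film")
  }
  curves <- lapply(series$scans, function(scan) {
    tryCatch({
      rects <- locate_calibrates(scan, layout)
      means <- vapply(rects, function(r) {
        roi_stats(scan, center_roi(r))$mean_intensity[[channel]]
      }, numeric(1))
      i0 <- means[zero_idx]
      fit_curve(doses = layout$doses, ods = net_od(i0, means),
                t_post = scan$t_post, channel = channel,
                background_intensity = i0)
    }, error = function(e) {
      stop(sprintf("scan at t=%g min: %s", scan$t_post,
                   conditionMessage(e)), call. = FALSE)
    })
  })
  new_tcm(curves, film_type = film_type, batch = batch,
          interval = series$interval, channel = channel)
}

new_tcm <- function(curves, film_type, batch, interval, channel) {
  times <- vapply(curves, function(cv) cv$t_post, numeric(1))
  if (any(diff(times) <= 0)) {
    stop("TCM curves must be strictly increasing in time")
  }
  structure(list(curves = curves, film_type = film_type, batch = batch,
                 interval = interval, channel = channel),
            class = "tcm")
}

#' Curve timestamps of a TCM
#' @param tcm A [build_tcm()] result.
#' @return Numeric vector of minutes postirradiation.
#' @export
tcm_times <- function(tcm) {
  vapply(tcm$curves, function(cv) cv$t_post, numeric(1))
}

#' @export
print.tcm <- function(x, ...) {
  t <- tcm_times(x)
  cat(sprintf(
    "<tcm> %s (%s channel, batch %s): %d curves, t = %g..%g min\n",
    x$film_type, x$channel, x$batch, length(x$curves), min(t), max(t)))
  invisible(x)
}

#' Write a TCM to CSV
#'
#' One row per time point in the format
#' `time_min,a,b,c,d,background_intensity,od_max`, preceded by
#' `#`-prefixed metadata comments (film type, batch, channel, interval,
#' fit direction). The trailing `od_max` column preserves the valid netOD
#' domain across a round-trip; readers of the minimal
#' `time,a,b,c,d` interchange format simply ignore it. Coefficients are
#' written with 17 significant digits, so a round-trip is exact well
#' beyond the 12-digit contract.
#'
#' @param tcm A [build_tcm()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
tcm_to_csv <- function(tcm, path) {
  stopifnot(inherits(tcm, "tcm"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# filmtcm temporal calibration model",
    sprintf("# film_type=%s", tcm$film_type),
    sprintf("# batch=%s", tcm$batch),
    sprintf("# channel=%s", tcm$channel),
    sprintf("# interval_min=%s", format(tcm$interval)),
    "# direction=od_to_dose",
    "time_min,a,b,c,d,background_intensity,od_max"), con)
  for (cv in tcm$curves) {
    writeLines(paste(sprintf("%.17g", c(cv$t_post, cv$coeffs,
                                        cv$background_intensity,
                                        cv$od_range[2])),
                     collapse = ","), con)
  }
  invisible(path)
}

#' Read a TCM from CSV
#'
#' Accepts files written by [tcm_to_csv()]; metadata comments are
#' optional. Rows must be strictly increasing in time and fully numeric.
#'
#' @param path CSV path.
#' @return A `tcm` object.
#' @export
csv_to_tcm <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- function(key, default) {
    m <- grep(sprintf("^#\\s*%s=", key), meta_lines, value = TRUE)
    if (!length(m)) default else sub(sprintf("^#\\s*%s=", key), "", m[1])
  }
  direction <- meta("direction", "od_to_dose")
  if (direction != "od_to_dose") {
    stop(sprintf("unsupported fit direction '%s' in '%s'", direction, path))
  }
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(body) && grepl("^time", body[1])) body <- body[-1]
  if (!length(body)) stop(sprintf("'%s': no TCM rows", path))
  prev_t <- -Inf
  curves <- vector("list", length(body))
  for (i in seq_along(body)) {
    v <- suppressWarnings(as.numeric(strsplit(body[i], ",")[[1]]))
    if (length(v) < 5 || anyNA(v[1:5])) {
      stop(sprintf("'%s': malformed TCM row %d: '%s'", path, i, body[i]))
    }
    if (v[1] <= prev_t) {
      stop(sprintf("'%s': TCM rows out of time order at row %d (t=%g after t=%g)",
                   path, i, v[1], prev_t))
    }
    prev_t <- v[1]
    curves[[i]] <- structure(
      list(t_post = v[1],
           coeffs = c(a = v[2], b = v[3], c = v[4], d = v[5]),
           background_intensity = if (length(v) >= 6) v[6] else NA_real_,
           channel = meta("channel", "red"),
           od_range = c(0, if (length(v) >= 7 && is.finite(v[7])) v[7] else Inf),
           rms_residual = NA_real_),
      class = "calibration_curve")
  }
  new_tcm(curves, film_type = meta("film_type", "unspecified"),
          batch = meta("batch", "unspecified"),
          interval = suppressWarnings(as.numeric(meta("interval_min", "NA"))),
          channel = meta("channel", "red"))
}
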