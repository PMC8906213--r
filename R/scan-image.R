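#' Timestamped film scan
#'
#' Holds the three colour channels of a flatbed scan as 16-bit intensity
#' matrices together with the pixel spacing and the postirradiation time
#' the scan was acquired at. Channels are stored exactly as read — no
#' colour correction of any kind. The blue channel is carried but unused
#' by the analysis (the dose response is read from red or green).
#'
#' Coordinate convention (used throughout the package): (0, 0) mm is the
#' centre of the top-left pixel; x runs along columns, y increases
#' downward along rows; matrices are row-major in the image sense
#' (`m[row, col]`).
#'
#' @param red,green,blue Intensity matrices of identical dimensions,
#'   values in \[0, 65535\].
#' @param pixel_spacing Isotropic pixel spacing, mm per pixel.
#' @param t_post Minutes postirradiation.
#' @param source_path Provenance string (file of origin, or a simulator
#'   tag).
#' @return An object of class `scan_image`.
#' @export
scan_image <- function(red, green, blue, pixel_spacing = 25.4 / 72,
                       t_post = NA_real_, source_path = "") {
  stopifnot(is.matrix(red), is.matrix(green), is.matrix(blue),
            identical(dim(red), dim(green)),
            identical(dim(red), dim(blue)),
            all(dim(red) >= 1L),
            pixel_spacing > 0)
  rng <- range(red, green, blue)
  if (rng[1] < 0 || rng[2] > 65535) {
    stop("channel intensities must lie in [0, 65535]")
  }
  structure(
    list(red = red, green = green, blue = blue,
         pixel_spacing = pixel_spacing,
         t_post = as.numeric(t_post),
         source_path = source_path),
    class = "scan_image")
}

#' @export
print.scan_image <- function(x, ...) {
  cat(sprintf("<scan_image> %d x %d px, %.5f mm/px, t = %s min\n",
              nrow(x$red), ncol(x$red), x$pixel_spacing,
              format(x$t_post)))
  invisible(x)
}

#' 2-D absorbed-dose plane
#'
#' @param dose Matrix of absorbed dose in Gy; all values finite and >= 0.
#' @param pixel_spacing mm per pixel (isotropic).
#' @param origin `c(x, y)` offset in mm of the top-left pixel centre.
#' @return An object of class `dose_plane`.
#' @export
dose_plane <- function(dose, pixel_spacing, origin = c(0, 0)) {
  stopifnot(is.matrix(dose), all(dim(dose) >= 1L),
            pixel_spacing > 0, length(origin) == 2)
  if (!all(is.finite(dose))) stop("dose plane contains non-finite values")
  if (any(dose < 0)) stop("dose must be non-negative everywhere")
  structure(
    list(dose = dose, pixel_spacing = pixel_spacing,
         origin = as.numeric(origin)),
    class = "dose_plane")
}

#' @export
print.dose_plane <- function(x, ...) {
  cat(sprintf("<dose_plane> %d x %d px, %.4g mm/px, dose %.3g-%.3g Gy\n",
              nrow(x$dose), ncol(x$dose), x$pixel_spacing,
              min(x$dose), max(x$dose)))
  invisible(x)
}

#' Ordered, time-indexed scan series
#'
#' A scan series is the product of the automated repeat-scanning loop:
#' one `scan_image` per postirradiation time, at a constant interval. The
#' constructor verifies strictly increasing timestamps and a uniform
#' interval; a single-scan series is allowed (interval undefined).
#'
#' @param scans List of [scan_image()] objects with `t_post` set.
#' @param tol Tolerance (minutes) for interval uniformity.
#' @return An object of class `scan_series` with fields `scans`,
#'   `interval` (minutes, `NA` for a single scan) and `t_first`.
#' @export
scan_series <- function(scans, tol = 1e-6) {
  stopifnot(is.list(scans), length(scans) >= 1,
            all(vapply(scans, inherits, logical(1), "scan_image")))
  times <- vapply(scans, function(s) s$t_post, numeric(1))
  if (any(is.na(times))) stop("every scan in a series needs a t_post")
  ord <- order(times)
  scans <- scans[ord]
  times <- times[ord]
  if (any(diff(times) <= 0)) stop("scan timestamps must be strictly increasing")
  interval <- NA_real_
  if (length(times) >= 2) {
    d <- diff(times)
    interval <- d[1]
    bad <- which(abs(d - interval) > tol)
    if (length(bad)) {
      stop(sprintf(
        "non-uniform scan interval: expected %g min but found gap(s) %s",
        interval,
        paste(sprintf("%g->%g (%g min)", times[bad], times[bad + 1], d[bad]),
              collapse = ", ")))
    }
  }
  structure(list(scans = scans, interval = interval, t_first = times[1]),
            class = "scan_series")
}

#' Timestamps of a scan series
#' @param series A [scan_series()].
#' @return Numeric vector of `t_post` values, minutes.
#' @export
series_times <- function(series) {
  stopifnot(inherits(series, "scan_series"))
  vapply(series$scans, function(s) s$t_post, numeric(1))
}

#' @export
print.scan_series <- function(x, ...) {
  t <- series_times(x)
  cat(sprintf("<scan_series> %d scans, t = %g..%g min, interval %s min\n",
              length(x$scans), min(t), max(t), format(x$interval)))
  invisible(x)
}

#' Scan schedule of the automated readout loop
#'
#' Times at which the repeat-scanning loop fires: `t_first`, then every
#' `interval` minutes up to and including `t_last`. The default 24-h
#' schedule at 5-min intervals starting 5 min postirradiation yields 288
#' scans; a 30-min interval yields 48.
#'
#' @param t_first First scan time, minutes postirradiation.
#' @param interval Minutes between scans.
#' @param t_last End of the scanning period, minutes.
#' @return Numeric vector of scan times.
#' @export
scan_schedule <- function(t_first = 5, interval = 5, t_last = 1440) {
  stopifnot(t_first > 0, interval > 0, t_last >= t_first)
  seq(t_first, t_last, by = interval)
}
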