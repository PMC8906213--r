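#' Look up the calibration curve matching a postirradiation time
#'
#' Returns the TCM curve whose timestamp is nearest the requested time;
#' ties break toward the earlier curve. Requests farther than twice the
#' TCM interval from every curve are out of coverage.
#'
#' @param tcm A [build_tcm()] / [csv_to_tcm()] result.
#' @param t_post Minutes postirradiation of the measurement scan.
#' @return The matching `calibration_curve`, with attribute `"mismatch"`
#'   (curve time minus requested time, minutes).
#' @export
lookup_curve <- function(tcm, t_post) {
  stopifnot(inherits(tcm, "tcm"))
  if (!length(tcm$curves)) stop("TCM contains no curves")
  if (t_post <= 0) stop("t_post must be positive")
  times <- tcm_times(tcm)
  idx <- which.min(abs(times - t_post))  # first minimum = earlier curve on a tie
  mismatch <- times[idx] - t_post
  if (is.finite(tcm$interval) && !is.na(tcm$interval) &&
      abs(mismatch) > 2 * tcm$interval) {
    stop(sprintf(
      "t=%g min is outside TCM coverage: nearest curve at %g min (interval %g min)",
      t_post, times[idx], tcm$interval))
  }
  curve <- tcm$curves[[idx]]
  attr(curve, "mismatch") <- mismatch
  curve
}

#' Pixel-wise net optical density of a measurement scan
#'
#' Applies `netOD = log10(I0 / I)` to every pixel of one channel. Pixels
#' at least as bright as `I0` clamp to netOD 0; zero-valued pixels are
#' replaced by 1 count before the log and counted.
#'
#' @param scan A [scan_image()].
#' @param i0 Zero-dose reference intensity (> 0), typically the matched
#'   curve's stored background intensity.
#' @param channel `"red"` or `"green"`.
#' @return netOD matrix with attribute `"zero_pixels"` (count of
#'   zero-valued pixels patched).
#' @export
od_plane <- function(scan, i0, channel = c("red", "green")) {
  stopifnot(inherits(scan, "scan_image"))
  channel <- match.arg(channel)
  if (i0 <= 0) stop("reference intensity i0 must be positive")
  m <- scan[[channel]]
  zero_pixels <- sum(m == 0)
  m[m == 0] <- 1
  od <- log10(i0 / m)
  od[od < 0] <- 0
  attr(od, "zero_pixels") <- zero_pixels
  od
}

#' Convert a netOD plane to dose with one calibration curve
#'
#' Evaluates `dose = a*od^3 + b*od^2 + c*od + d` pixel-wise. netOD values
#' outside the curve's calibrated domain are clamped to the domain
#' boundary (conservative: no extrapolation) and counted; negative doses
#' clamp to 0 and are counted.
#'
#' @param od netOD matrix (e.g. from [od_plane()]).
#' @param curve A `calibration_curve`.
#' @param pixel_spacing mm per pixel of the resulting plane.
#' @param origin `c(x, y)` origin in mm.
#' @return A [dose_plane()] with attribute `"clamps"` =
#'   `c(od_clamped, negative_dose)` counts.
#' @export
apply_curve <- function(od, curve, pixel_spacing, origin = c(0, 0)) {
  stopifnot(inherits(curve, "calibration_curve"), is.matrix(od))
  lo <- curve$od_range[1]; hi <- curve$od_range[2]
  od_clamped <- sum(od < lo | od > hi)
  od <- pmin(pmax(od, lo), hi)
  dose <- eval_curve(curve, od)
  negative <- sum(dose < 0)
  dose[dose < 0] <- 0
  plane <- dose_plane(matrix(dose, nrow = nrow(od)),
                      pixel_spacing = pixel_spacing, origin = origin)
  attr(plane, "clamps") <- c(od_clamped = od_clamped,
                             negative_dose = negative)
  plane
}

#' Convert a measurement scan to dose via the TCM
#'
#' The user-entered postirradiation time selects the nearest TCM curve
#' (the time lookup); the scan is mapped to netOD against that curve's
#' stored zero-dose background intensity (or the mean of an unexposed
#' in-scan reference rectangle, when given) and then to dose through the
#' curve's cubic coefficients.
#'
#' @param scan A [scan_image()] of the measurement film.
#' @param tcm The temporal calibration model.
#' @param t_post Minutes postirradiation the scan corresponds to; defaults
#'   to the scan's own timestamp.
#' @param channel Colour channel; defaults to the TCM's channel.
#' @param i0_rect Optional rectangle `c(x, y, w, h)` of an unexposed
#'   reference region inside the scan to use as `I0` instead of the
#'   curve's stored background intensity.
#' @return A [dose_plane()] with attribute `"provenance"`: curve time
#'   used, time mismatch in minutes, `I0` source and value, clamp and
#'   zero-pixel counts.
#' @export
convert_scan <- function(scan, tcm, t_post = scan$t_post,
                         channel = tcm$channel, i0_rect = NULL) {
  stopifnot(inherits(scan, "scan_image"), inherits(tcm, "tcm"))
  if (is.na(t_post)) stop("postirradiation time t_post is required")
  curve <- lookup_curve(tcm, t_post)
  if (is.null(i0_rect)) {
    i0 <- curve$background_intensity
    i0_source <- "tcm_background"
    if (is.na(i0)) {
      stop("TCM curve stores no background intensity; supply i0_rect")
    }
  } else {
    i0 <- roi_stats(scan, i0_rect)$mean_intensity[[channel]]
    i0_source <- "in_scan_reference"
  }
  od <- od_plane(scan, i0, channel)
  plane <- apply_curve(od, curve, pixel_spacing = scan$pixel_spacing)
  attr(plane, "provenance") <- list(
    curve_time = curve$t_post,
    requested_time = t_post,
    mismatch_min = attr(curve, "mismatch"),
    channel = channel,
    i0_source = i0_source,
    i0 = i0,
    zero_pixels = attr(od, "zero_pixels"),
    clamps = attr(plane, "clamps"))
  plane
}
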