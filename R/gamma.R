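#' Gamma-analysis acceptance criteria
#'
#' @param dose_diff Dose-difference criterion, % of the normalisation
#'   dose.
#' @param dta Distance-to-agreement criterion, mm.
#' @param normalization `"global"` (percent of the reference-plane
#'   maximum) or `"local"` (percent of the local reference dose).
#' @param low_dose_threshold Reference pixels below this % of the
#'   reference maximum are excluded from evaluation.
#' @param search_radius_factor Spatial search radius, in multiples of
#'   `dta`.
#' @param interp_step Sub-pixel sampling step of the evaluated plane, as
#'   a fraction of `dta`.
#' @param max_gamma Optional cap: the search may stop refining a pixel
#'   once its gamma is known to exceed this value, in which case the
#'   reported gamma is a lower bound. Pass/fail at gamma = 1 is unaffected
#'   for caps above 1. `Inf` (default) computes exact minima.
#' @return An object of class `gamma_criteria`.
#' @export
gamma_criteria <- function(dose_diff = 1, dta = 1,
                           normalization = c("global", "local"),
                           low_dose_threshold = 10,
                           search_radius_factor = 3,
                           interp_step = 0.1,
                           max_gamma = Inf) {
  normalization <- match.arg(normalization)
  stopifnot(dose_diff > 0, dta > 0,
            low_dose_threshold >= 0, low_dose_threshold < 100,
            search_radius_factor > 0, interp_step > 0, max_gamma > 1)
  structure(list(dose_diff = dose_diff, dta = dta,
                 normalization = normalization,
                 low_dose_threshold = low_dose_threshold,
                 search_radius_factor = search_radius_factor,
                 interp_step = interp_step, max_gamma = max_gamma),
            class = "gamma_criteria")
}

# out[i, j] = M[i + di, j + dj], NA outside.
int_shift <- function(M, di, dj) {
  n <- nrow(M); m <- ncol(M)
  out <- matrix(NA_real_, n, m)
  i1 <- max(1L, 1L - di); i2 <- min(n, n - di)
  j1 <- max(1L, 1L - dj); j2 <- min(m, m - dj)
  if (i1 <= i2 && j1 <= j2) {
    out[i1:i2, j1:j2] <- M[(i1 + di):(i2 + di), (j1 + dj):(j2 + dj)]
  }
  out
}

# Bilinear sample of M at every pixel centre displaced by (sy, sx) pixels.
shift_bilinear <- function(M, sy, sx) {
  by <- floor(sy); fy <- sy - by
  bx <- floor(sx); fx <- sx - bx
  acc <- NULL
  add <- function(acc, w, di, dj) {
    if (w <= 0) return(acc)
    term <- w * int_shift(M, di, dj)
    if (is.null(acc)) term else acc + term
  }
  acc <- add(acc, (1 - fy) * (1 - fx), by, bx)
  acc <- add(acc, (1 - fy) * fx, by, bx + 1L)
  acc <- add(acc, fy * (1 - fx), by + 1L, bx)
  acc <- add(acc, fy * fx, by + 1L, bx + 1L)
  acc
}

# Bilinear resample of an evaluated plane onto the reference grid.
# Returns a matrix (NA where the reference grid falls outside the
# evaluated extent); the reference is never resampled.
resample_to_reference <- function(evaluated, reference) {
  rd <- dim(reference$dose)
  x <- reference$origin[1] + (seq_len(rd[2]) - 1) * reference$pixel_spacing
  y <- reference$origin[2] + (seq_len(rd[1]) - 1) * reference$pixel_spacing
  jx <- (x - evaluated$origin[1]) / evaluated$pixel_spacing + 1
  iy <- (y - evaluated$origin[2]) / evaluated$pixel_spacing + 1
  E <- evaluated$dose
  n <- nrow(E); m <- ncol(E)
  out <- matrix(NA_real_, rd[1], rd[2])
  ok_j <- jx >= 1 & jx <= m
  ok_i <- iy >= 1 & iy <= n
  if (!any(ok_i) || !any(ok_j)) return(out)
  i0 <- pmin(pmax(floor(iy), 1), n - 1); fi <- iy - i0
  j0 <- pmin(pmax(floor(jx), 1), m - 1); fj <- jx - j0
  for (r in which(ok_i)) {
    a <- E[i0[r], j0[ok_j]] * (1 - fi[r]) + E[i0[r] + 1, j0[ok_j]] * fi[r]
    b <- E[i0[r], j0[ok_j] + 1] * (1 - fi[r]) + E[i0[r] + 1, j0[ok_j] + 1] * fi[r]
    out[r, ok_j] <- a * (1 - fj[ok_j]) + b * fj[ok_j]
  }
  out
}

#' Gamma-index comparison of two dose planes
#'
#' Computes the 2-D gamma index of an evaluated dose plane against a
#' reference plane: for every evaluated reference pixel,
#' `gamma = min over the search disc of sqrt((dose diff / dd)^2 +
#' (distance / dta)^2)`, with the evaluated plane sampled by bilinear
#' interpolation on a sub-pixel grid (`interp_step * dta`) out to
#' `search_radius_factor * dta`. Reference pixels below the low-dose
#' threshold are excluded. If grids differ, the evaluated plane is
#' bilinearly resampled onto the reference grid first; the reference is
#' never resampled.
#'
#' @param reference Reference (ground-truth) [dose_plane()].
#' @param evaluated Evaluated [dose_plane()].
#' @param criteria A [gamma_criteria()].
#' @return Object of class `gamma_result`: `gamma` matrix (NA below
#'   threshold), `pass_rate` (% of evaluated pixels with gamma <= 1),
#'   `evaluated_count`, `criteria`.
#' @export
gamma_index <- function(reference, evaluated, criteria = gamma_criteria()) {
  stopifnot(inherits(reference, "dose_plane"),
            inherits(evaluated, "dose_plane"),
            inherits(criteria, "gamma_criteria"))
  ref <- reference$dose
  same_grid <- identical(dim(evaluated$dose), dim(ref)) &&
    isTRUE(all.equal(evaluated$pixel_spacing, reference$pixel_spacing)) &&
    isTRUE(all.equal(evaluated$origin, reference$origin))
  ev <- if (same_grid) evaluated$dose else resample_to_reference(evaluated, reference)

  norm_dose <- max(ref)
  if (norm_dose <= 0) stop("reference plane is identically zero")
  dd <- if (criteria$normalization == "global") {
    criteria$dose_diff / 100 * norm_dose
  } else {
    criteria$dose_diff / 100 * pmax(ref, .Machine$double.eps)
  }
  mask <- ref >= criteria$low_dose_threshold / 100 * norm_dose
  if (!any(mask)) {
    stop("no reference pixels above the low-dose threshold to evaluate")
  }

  sp <- reference$pixel_spacing
  dta2 <- criteria$dta^2
  step <- criteria$interp_step * criteria$dta
  radius <- criteria$search_radius_factor * criteria$dta
  k <- floor(radius / step + 1e-9)
  offs <- expand.grid(ix = -k:k, iy = -k:k)
  r2 <- (offs$ix * step)^2 + (offs$iy * step)^2
  keep <- r2 <= radius^2 + 1e-9
  offs <- offs[keep, ]; r2 <- r2[keep]
  ord <- order(r2)
  offs <- offs[ord, ]; r2 <- r2[ord]

  cap2 <- criteria$max_gamma^2
  g2 <- matrix(Inf, nrow(ref), ncol(ref))
  for (o in seq_along(r2)) {
    spatial2 <- r2[o] / dta2
    if (spatial2 >= max(pmin(g2[mask], cap2))) break
    E <- shift_bilinear(ev, offs$iy[o] * step / sp, offs$ix[o] * step / sp)
    cand <- ((E - ref) / dd)^2 + spatial2
    cand[is.na(cand)] <- Inf
    g2 <- pmin(g2, cand)
  }
  gamma <- sqrt(g2)
  gamma[!mask] <- NA_real_
  structure(
    list(gamma = gamma,
         pass_rate = 100 * sum(gamma[mask] <= 1) / sum(mask),
         evaluated_count = sum(mask),
         criteria = criteria),
    class = "gamma_result")
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf(
    "<gamma_result> %.1f%% pass (gamma<=1) over %d pixels at %g%%/%g mm\n",
    x$pass_rate, x$evaluated_count, x$criteria$dose_diff, x$criteria$dta))
  invisible(x)
}

#' Gamma pass rate versus postirradiation time
#'
#' The temporal validation of the TCM: the measurement-film scan at
#' `reference_time` (default 1200 min = 20 h) converted with its
#' time-matched curve is the ground truth; every scan of the series is
#' converted either with its own time-matched curve (`mode = "tcm"`) or
#' with the fixed reference-time curve (`mode = "single_curve"`), compared
#' to the ground truth by gamma analysis, and the pass rates are
#' normalised to the reference-time pass rate.
#'
#' @param series A [scan_series()] of measurement scans whose times
#'   include `reference_time`.
#' @param tcm The temporal calibration model.
#' @param criteria A [gamma_criteria()] (the validation default is
#'   1%/1 mm).
#' @param mode `"tcm"` or `"single_curve"`.
#' @param reference_time Minutes postirradiation of the ground-truth scan.
#' @return A data frame of class `temporal_validation` with columns
#'   `t_post`, `pass_rate`, `normalized`, and attributes `cov_pct`
#'   (coefficient of variation of the pass-rate column, %), `range_pct`
#'   (max - min), `mode`, `reference_time`.
#' @export
pass_rate_vs_time <- function(series, tcm,
                              criteria = gamma_criteria(max_gamma = 1.1),
                              mode = c("tcm", "single_curve"),
                              reference_time = 1200) {
  stopifnot(inherits(series, "scan_series"), inherits(tcm, "tcm"))
  mode <- match.arg(mode)
  times <- series_times(series)
  ref_idx <- which(abs(times - reference_time) < 1e-9)
  if (length(ref_idx) != 1) {
    stop(sprintf("reference time %g min is not in the scan series",
                 reference_time))
  }
  ground_truth <- convert_scan(series$scans[[ref_idx]], tcm,
                               t_post = reference_time)
  pass <- vapply(seq_along(series$scans), function(i) {
    t_conv <- if (mode == "tcm") times[i] else reference_time
    plane <- convert_scan(series$scans[[i]], tcm, t_post = t_conv)
    gamma_index(ground_truth, plane, criteria)$pass_rate
  }, numeric(1))
  out <- data.frame(t_post = times, pass_rate = pass,
                    normalized = pass / pass[ref_idx])
  class(out) <- c("temporal_validation", "data.frame")
  attr(out, "cov_pct") <- cov_percent(pass)
  attr(out, "range_pct") <- range_stat(pass)
  attr(out, "mode") <- mode
  attr(out, "reference_time") <- reference_time
  out
}

#' @export
print.temporal_validation <- function(x, ...) {
  cat(sprintf("Temporal validation (%s mode, reference %g min):\n",
              attr(x, "mode"), attr(x, "reference_time")))
  df <- data.frame(t_post = x$t_post,
                   pass_rate = round(x$pass_rate, 1),
                   normalized = round(x$normalized, 3))
  print.data.frame(df, row.names = FALSE)
  cat(sprintf("COV %.1f%%, range %.1f%%\n",
              attr(x, "cov_pct"), attr(x, "range_pct")))
  invisible(x)
}
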