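# Background (non-film) pixels are rendered at a bright sentinel so that
# rectangle detection is unambiguous: films are always darker.
BACKGROUND_SENTINEL <- round(0.98 * 65535)

# Evaluate an expression with a private RNG stream, restoring the caller's
# RNG state afterwards. Makes renders reproducible from (seed, t) alone.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Intensity of a film area: base * drift * 10^(-OD), with optional relative
# Gaussian pixel noise, rounded to integer counts and clamped to 16 bits.
render_intensity <- function(od, base, drift, noise_sd) {
  v <- base * drift * 10^(-od)
  if (noise_sd > 0) v <- v * (1 + stats::rnorm(length(od), sd = noise_sd))
  matrix(pmin(pmax(round(v), 0), 65535), nrow = nrow(od))
}

# Film rectangle positions (px) for a calibration layout, reading order.
layout_rectangles <- function(layout) {
  sp <- layout$pixel_spacing
  fw <- max(1L, round(layout$film_size_mm[1] / sp))
  fh <- max(1L, round(layout$film_size_mm[2] / sp))
  m <- max(1L, round(layout$margin_mm / sp))
  rows <- layout$grid[1]; cols <- layout$grid[2]
  rects <- vector("list", rows * cols)
  k <- 0L
  for (r in seq_len(rows)) {
    for (c in seq_len(cols)) {
      k <- k + 1L
      rects[[k]] <- c(x = m + (c - 1L) * (fw + m) + 1L,
                      y = m + (r - 1L) * (fh + m) + 1L,
                      w = fw, h = fh)
    }
  }
  list(rects = rects,
       canvas = c(h = rows * fh + (rows + 1L) * m,
                  w = cols * fw + (cols + 1L) * m))
}

#' Render a synthetic calibration scan
#'
#' Draws the calibration film set (one rectangle per dose, reading order
#' left to right then top to bottom) on a bright background sentinel, at
#' the intensity the growth and scanner models predict for time `t`:
#' `base_intensity * drift(t) * 10^(-OD(D, t))` plus optional pixel noise.
#' The blue channel carries no dose response (base intensity and drift
#' only); analysis uses red or green.
#'
#' @param layout A [calibration_layout()].
#' @param growth `list(red =, green =)` of [growth_model()] objects (see
#'   [film_growth_models()]).
#' @param scanner A [scanner_model()].
#' @param t Minutes postirradiation.
#' @return A [scan_image()] stamped with `t` and the layout's pixel
#'   spacing.
#' @export
render_calibration_scan <- function(layout, growth, scanner, t) {
  stopifnot(inherits(layout, "calibration_layout"),
            inherits(scanner, "scanner_model"),
            is.list(growth), inherits(growth$red, "growth_model"),
            inherits(growth$green, "growth_model"))
  geo <- layout_rectangles(layout)
  drift <- drift_factor(t, scanner)
  chans <- with_local_seed(scanner$seed + as.integer(round(t)) %% 100000L, {
    lapply(c("red", "green", "blue"), function(ch) {
      m <- matrix(BACKGROUND_SENTINEL, geo$canvas["h"], geo$canvas["w"])
      for (i in seq_along(geo$rects)) {
        rc <- geo$rects[[i]]
        od <- if (ch == "blue") 0 else od_at_time(layout$doses[i], t, growth[[ch]])
        block <- matrix(od, rc["h"], rc["w"])
        m[rc["y"]:(rc["y"] + rc["h"] - 1L),
          rc["x"]:(rc["x"] + rc["w"] - 1L)] <-
          render_intensity(block, scanner$base_intensity[[ch]], drift,
                           scanner$pixel_noise_sd)
      }
      m
    })
  })
  scan_image(red = chans[[1]], green = chans[[2]], blue = chans[[3]],
             pixel_spacing = layout$pixel_spacing, t_post = t,
             source_path = sprintf("simulated calibration scan t=%g", t))
}

#' Render a synthetic measurement scan from a ground-truth dose plane
#'
#' Every pixel of the dose plane is mapped to scanner intensity through
#' the growth law at time `t`: `base * drift(t) * 10^(-OD(D(x,y), t))`,
#' plus optional noise. Doses must lie within the simulator's valid range
#' \[0, 20\] Gy.
#'
#' @param ground_truth A [dose_plane()].
#' @inheritParams render_calibration_scan
#' @return A [scan_image()] with the plane's pixel spacing.
#' @export
render_measurement_scan <- function(ground_truth, growth, scanner, t) {
  stopifnot(inherits(ground_truth, "dose_plane"),
            inherits(scanner, "scanner_model"))
  if (max(ground_truth$dose) > 20) {
    stop("ground-truth dose exceeds the simulator's valid range [0, 20] Gy")
  }
  drift <- drift_factor(t, scanner)
  chans <- with_local_seed(scanner$seed + as.integer(round(t)) %% 100000L, {
    lapply(c("red", "green", "blue"), function(ch) {
      od <- if (ch == "blue") {
        matrix(0, nrow(ground_truth$dose), ncol(ground_truth$dose))
      } else {
        od_at_time(ground_truth$dose, t, growth[[ch]])
      }
      render_intensity(od, scanner$base_intensity[[ch]], drift,
                       scanner$pixel_noise_sd)
    })
  })
  scan_image(red = chans[[1]], green = chans[[2]], blue = chans[[3]],
             pixel_spacing = ground_truth$pixel_spacing, t_post = t,
             source_path = sprintf("simulated measurement scan t=%g", t))
}

#' Synthetic ground-truth dose planes
#'
#' Test patterns standing in for stereotactic treatment-plan dose planes,
#' which span dose from zero up past the prescription with steep
#' gradients. Gradient patterns cover at least a 10:1 internal dose range.
#'
#' Patterns:
#' * `uniform` — constant `peak` everywhere;
#' * `gaussian` — single lesion, isotropic Gaussian with SD `sigma_mm`,
#'   maximum `peak` at the plane centre;
#' * `multilesion` — one Gaussian per entry of `peaks`, centred at
#'   `centers` (fractions of the plane size);
#' * `saddle` — spine-like pattern: a dose ridge with a central trough
#'   (the cord-sparing region).
#'
#' @param pattern One of `"uniform"`, `"gaussian"`, `"multilesion"`,
#'   `"saddle"`.
#' @param peak Peak dose in Gy (> 0).
#' @param size_px `c(rows, cols)` of the grid.
#' @param pixel_spacing mm per pixel.
#' @param sigma_mm Gaussian SD for lesion patterns, mm.
#' @param peaks Peak doses for `multilesion` (Gy).
#' @param centers List of `c(fx, fy)` fractional centres for
#'   `multilesion`.
#' @return A [dose_plane()].
#' @export
make_dose_plane <- function(pattern = c("gaussian", "uniform", "multilesion",
                                        "saddle"),
                            peak = 12, size_px = c(100, 100),
                            pixel_spacing = 1, sigma_mm = 15,
                            peaks = c(8, 10),
                            centers = list(c(0.3, 0.35), c(0.7, 0.65))) {
  pattern <- match.arg(pattern)
  if (peak <= 0) stop("peak dose must be positive")
  nr <- size_px[1]; nc <- size_px[2]
  x <- (seq_len(nc) - 1) * pixel_spacing
  y <- (seq_len(nr) - 1) * pixel_spacing
  cx <- max(x) / 2; cy <- max(y) / 2
  X <- matrix(x, nr, nc, byrow = TRUE)
  Y <- matrix(y, nr, nc)
  d <- switch(pattern,
    uniform = matrix(peak, nr, nc),
    gaussian = peak * exp(-((X - cx)^2 + (Y - cy)^2) / (2 * sigma_mm^2)),
    multilesion = {
      if (any(peaks <= 0)) stop("peak dose must be positive")
      m <- matrix(0, nr, nc)
      for (i in seq_along(peaks)) {
        px <- centers[[i]][1] * max(x); py <- centers[[i]][2] * max(y)
        m <- pmax(m, peaks[i] *
                    exp(-((X - px)^2 + (Y - py)^2) / (2 * sigma_mm^2)))
      }
      m
    },
    saddle = {
      # widths scale with the plane so the pattern always spans a >10:1
      # internal dose range regardless of grid size
      sx <- 0.12 * max(x); sy <- 0.22 * max(y); st <- 0.08 * max(x)
      ridge <- exp(-(X - cx)^2 / (2 * sx^2) - (Y - cy)^2 / (2 * sy^2))
      trough <- 1 - 0.85 * exp(-((X - cx)^2 + (Y - cy)^2) / (2 * st^2))
      peak / max(ridge * trough) * ridge * trough
    })
  dose_plane(d, pixel_spacing = pixel_spacing)
}

#' Simulate a calibration scan series
#'
#' Renders one calibration scan per entry of the schedule, emulating the
#' automated readout loop (default: every 5 min from 5 min to 24 h
#' postirradiation, 288 scans).
#'
#' @inheritParams render_calibration_scan
#' @param times Scan times in minutes (see [scan_schedule()]).
#' @return A [scan_series()].
#' @export
simulate_calibration_series <- function(layout = calibration_layout(),
                                        growth = film_growth_models("EBT-XD"),
                                        scanner = scanner_model(),
                                        times = scan_schedule()) {
  scan_series(lapply(times, function(t)
    render_calibration_scan(layout, growth, scanner, t)))
}

#' Simulate a measurement scan series
#'
#' Renders the same ground-truth dose plane at every schedule time,
#' emulating the repeat scanning of one patient-specific QA film.
#'
#' @inheritParams render_measurement_scan
#' @param times Scan times in minutes.
#' @return A [scan_series()].
#' @export
simulate_measurement_series <- function(ground_truth,
                                        growth = film_growth_models("EBT-XD"),
                                        scanner = scanner_model(),
                                        times = scan_schedule()) {
  scan_series(lapply(times, function(t)
    render_measurement_scan(ground_truth, growth, scanner, t)))
}
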