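#' Postirradiation optical-density growth model
#'
#' Radiochromic film keeps darkening after exposure: the net optical density
#' (netOD) of an irradiated film grows approximately linearly in
#' log10(postirradiation time), at a rate that decreases with dose and
#' differs between colour channels. A `growth_model` captures this with
#' three ingredients:
#'
#' * a baseline 24-h dose response `od24(D) = a1 * D / (D + k) + a2 * D`
#'   (saturating plus linear, the typical shape of film response —
#'   deliberately not a polynomial, so the cubic calibration fit is a
#'   genuine approximation);
#' * the relative netOD growth from the first scan (`t_first`, default
#'   5 min) to the final scan (`t_final`, default 1440 min) at the 2 Gy
#'   anchor (`growth_low`) and the 18 Gy anchor (`growth_high`);
#' * linear-in-dose interpolation of the growth fraction between the two
#'   anchors, clamped outside \[2, 18\] Gy.
#'
#' The growth law is
#' `OD(D, t) = OD(D, t_first) * (1 + g(D) * log10(t/t_first) / log10(t_final/t_first))`
#' with `OD(D, t_first) = od24(D) / (1 + g(D))`, so that
#' `OD(D, t_final) = od24(D)` exactly and
#' `OD(D, t_final)/OD(D, t_first) - 1 = g(D)` exactly.
#'
#' @param channel Colour channel the model describes, `"red"` or `"green"`.
#' @param od24_a1,od24_k,od24_a2 Parameters of the 24-h baseline response:
#'   saturating amplitude (OD), half-saturation dose (Gy), and linear slope
#'   (OD per Gy).
#' @param growth_low Relative netOD increase from `t_first` to `t_final`
#'   at 2 Gy (fraction, e.g. 0.061 for 6.1%).
#' @param growth_high Same at 18 Gy. Must satisfy
#'   `0 <= growth_high <= growth_low < 1` (growth shrinks with dose).
#' @param t_first,t_final First and final scan times, minutes
#'   postirradiation.
#' @return An object of class `growth_model`.
#' @seealso [film_growth_model()] for EBT3/EBT-XD presets, [od_at_time()].
#' @export
growth_model <- function(channel = c("red", "green"),
                         od24_a1 = 0.45, od24_k = 6, od24_a2 = 0.004,
                         growth_low = 0.061, growth_high = 0.044,
                         t_first = 5, t_final = 1440) {
  channel <- match.arg(channel)
  stopifnot(od24_a1 > 0, od24_k > 0, od24_a2 >= 0,
            t_first > 0, t_final > t_first)
  if (!(growth_high >= 0 && growth_high <= growth_low && growth_low < 1)) {
    stop("growth fractions must satisfy 0 <= growth_high <= growth_low < 1 ",
         "(postirradiation growth decreases with dose)")
  }
  structure(
    list(channel = channel,
         od24_a1 = od24_a1, od24_k = od24_k, od24_a2 = od24_a2,
         growth_low = growth_low, growth_high = growth_high,
         t_first = t_first, t_final = t_final),
    class = "growth_model")
}

#' Growth-model presets for GafChromic EBT3 and EBT-XD film
#'
#' Default growth fractions are the measured relative netOD increases from
#' 5 min to 24 h postirradiation for each film type and channel:
#' EBT3 red 6.1% (2 Gy) / 4.4% (18 Gy), EBT3 green 7.9% / 6.3%,
#' EBT-XD red 8.2% / 5.7%, EBT-XD green 8.7% / 7.8%. The green-channel
#' baseline response is scaled to 0.7 of the red-channel response.
#'
#' @param film `"EBT3"` or `"EBT-XD"`.
#' @param channel `"red"` or `"green"`.
#' @inheritParams growth_model
#' @return A `growth_model`.
#' @export
film_growth_model <- function(film = c("EBT3", "EBT-XD"),
                              channel = c("red", "green"),
                              t_first = 5, t_final = 1440) {
  film <- match.arg(film)
  channel <- match.arg(channel)
  g <- switch(paste(film, channel),
    "EBT3 red"     = c(0.061, 0.044),
    "EBT3 green"   = c(0.079, 0.063),
    "EBT-XD red"   = c(0.082, 0.057),
    "EBT-XD green" = c(0.087, 0.078))
  scale <- if (channel == "green") 0.7 else 1
  growth_model(channel = channel,
               od24_a1 = 0.45 * scale, od24_k = 6, od24_a2 = 0.004 * scale,
               growth_low = g[1], growth_high = g[2],
               t_first = t_first, t_final = t_final)
}

#' Both-channel growth models for a film type
#'
#' Convenience wrapper returning the red and green [film_growth_model()]
#' presets as a named list, the form the rendering functions expect.
#'
#' @inheritParams film_growth_model
#' @return `list(red = <growth_model>, green = <growth_model>)`.
#' @export
film_growth_models <- function(film = c("EBT3", "EBT-XD"),
                               t_first = 5, t_final = 1440) {
  film <- match.arg(film)
  list(red = film_growth_model(film, "red", t_first, t_final),
       green = film_growth_model(film, "green", t_first, t_final))
}

#' Baseline 24-h net optical density
#'
#' @param dose Absorbed dose in Gy (vectorised, must be >= 0).
#' @param model A [growth_model()].
#' @return netOD at `t_final` for each dose.
#' @export
od_24h <- function(dose, model) {
  stopifnot(inherits(model, "growth_model"))
  if (any(dose < 0)) stop("dose must be non-negative")
  model$od24_a1 * dose / (dose + model$od24_k) + model$od24_a2 * dose
}

#' Dose-dependent growth fraction g(D)
#'
#' Linear interpolation of the relative 5-min-to-24-h netOD growth between
#' the 2 Gy and 18 Gy anchors, clamped to the anchor values outside
#' \[2, 18\] Gy.
#'
#' @inheritParams od_24h
#' @return Growth fraction for each dose.
#' @export
growth_fraction <- function(dose, model) {
  stopifnot(inherits(model, "growth_model"))
  if (any(dose < 0)) stop("dose must be non-negative")
  f <- pmin(pmax((dose - 2) / 16, 0), 1)
  model$growth_low + f * (model$growth_high - model$growth_low)
}

#' Net optical density at a postirradiation time
#'
#' Evaluates the log-time growth law: netOD rises linearly in log10(t) from
#' `od24(D) / (1 + g(D))` at `t_first` to `od24(D)` at `t_final`. Zero dose
#' always maps to zero netOD (net OD is measured relative to the unexposed
#' film scanned at the same time, so scanner drift cancels).
#'
#' @param dose Absorbed dose in Gy (vector or matrix, >= 0).
#' @param t Minutes postirradiation; must lie in
#'   `[model$t_first, model$t_final]`.
#' @param model A [growth_model()].
#' @return netOD with the shape of `dose`.
#' @examples
#' m <- film_growth_model("EBT3", "red")
#' od_at_time(2, 5, m)
#' od_at_time(2, 1440, m) / od_at_time(2, 5, m) - 1  # = growth_low
#' @export
od_at_time <- function(dose, t, model) {
  stopifnot(inherits(model, "growth_model"), length(t) == 1L, is.finite(t))
  if (t < model$t_first || t > model$t_final) {
    stop(sprintf("t = %g min is outside the modelled range [%g, %g] min",
                 t, model$t_first, model$t_final))
  }
  if (any(dose < 0)) stop("dose must be non-negative")
  g <- growth_fraction(dose, model)
  x <- log10(t / model$t_first) / log10(model$t_final / model$t_first)
  od <- od_24h(dose, model) / (1 + g) * (1 + g * x)
  od[dose == 0] <- 0
  od
}

#' @export
print.growth_model <- function(x, ...) {
  cat(sprintf("<growth_model> %s channel\n", x$channel))
  cat(sprintf("  od24(D) = %.4g D/(D + %.4g) + %.4g D\n",
              x$od24_a1, x$od24_k, x$od24_a2))
  cat(sprintf("  growth %.1f%% @2 Gy -> %.1f%% @18 Gy over t = [%g, %g] min\n",
              100 * x$growth_low, 100 * x$growth_high, x$t_first, x$t_final))
  invisible(x)
}

#' Flatbed-scanner response model
#'
#' Describes the simulated scanner: mean zero-dose pixel value per channel
#' (16-bit scale), a smooth multiplicative warm-up drift bounded by
#' `drift_amplitude` over the 24-h scanning period (applied identically to
#' every film on the bed, so the in-scan zero-dose reference cancels it),
#' and optional relative per-pixel Gaussian noise. Noise defaults to zero;
#' the drift bound defaults to the 1% scanner-stability envelope.
#'
#' @param base_intensity Named numeric vector `c(red=, green=, blue=)` of
#'   zero-dose mean pixel values on the 16-bit scale (0, 65536).
#' @param drift_amplitude Maximal relative multiplicative drift over 24 h.
#' @param pixel_noise_sd Relative per-pixel Gaussian noise SD (fraction).
#' @param seed Integer seed controlling the pixel noise; renders with the
#'   same seed are bit-identical.
#' @return An object of class `scanner_model`.
#' @export
scanner_model <- function(base_intensity = c(red = 42000, green = 44000,
                                             blue = 36000),
                          drift_amplitude = 0.01,
                          pixel_noise_sd = 0,
                          seed = 1L) {
  stopifnot(all(c("red", "green", "blue") %in% names(base_intensity)),
            all(base_intensity > 0), all(base_intensity < 65536),
            drift_amplitude >= 0, pixel_noise_sd >= 0)
  structure(
    list(base_intensity = base_intensity[c("red", "green", "blue")],
         drift_amplitude = drift_amplitude,
         pixel_noise_sd = pixel_noise_sd,
         seed = as.integer(seed)),
    class = "scanner_model")
}

# Multiplicative warm-up drift: smooth half-cosine ramp from 1 at t = 0 to
# 1 + amplitude at 24 h, identical for every film in a scan.
drift_factor <- function(t, scanner) {
  tt <- pmin(pmax(t, 0), 1440)
  1 + scanner$drift_amplitude * (1 - cos(pi * tt / 1440)) / 2
}

#' Calibration-film layout on the scanner bed
#'
#' The calibration set is ten small films ("calibrates") exposed to 0 to
#' 18 Gy in 2 Gy steps, arranged in two rows of five with consistent
#' orientation at the centre of the scan plane.
#'
#' @param doses Ordered dose list in Gy, one per film, in reading order
#'   (left to right, top to bottom).
#' @param film_size_mm Width x height of each calibrate in mm.
#' @param grid `c(rows, cols)` arrangement; `prod(grid)` must equal
#'   `length(doses)`.
#' @param margin_mm Background margin around and between films, mm.
#' @param pixel_spacing mm per pixel; default 25.4/72 (72 DPI).
#' @return An object of class `calibration_layout`.
#' @export
calibration_layout <- function(doses = seq(0, 18, by = 2),
                               film_size_mm = c(40, 30),
                               grid = c(2, 5),
                               margin_mm = 5,
                               pixel_spacing = 25.4 / 72) {
  stopifnot(length(doses) >= 1, all(doses >= 0), !anyDuplicated(doses),
            length(film_size_mm) == 2, all(film_size_mm > 0),
            length(grid) == 2, all(grid >= 1),
            prod(grid) == length(doses),
            margin_mm > 0, pixel_spacing > 0)
  structure(
    list(doses = doses, film_size_mm = film_size_mm,
         grid = as.integer(grid), margin_mm = margin_mm,
         pixel_spacing = pixel_spacing),
    class = "calibration_layout")
}
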