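---
title: "Temporal calibration of radiochromic film: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal calibration of radiochromic film: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(filmtcm)
```

## The problem

GafChromic film (EBT3, EBT-XD) self-develops: ionising radiation starts a
polymerisation in the active layer that continues for many hours after
exposure, so the film's net optical density (netOD) keeps growing after
irradiation, approximately linearly in log10(time). The growth is larger
in relative terms at low dose than at high dose, and larger in the green
channel than in the red. A dose-response calibration scanned at one
postirradiation time therefore misreads a measurement film scanned at
another time — which is why clinics traditionally wait 16–24 h before
film readout, a known bottleneck in patient-specific QA of stereotactic
treatments.

The temporal calibration model (TCM) removes the waiting period. Instead
of one calibration curve, the calibration film set is scanned repeatedly
on an automated schedule (e.g. every 5 min for 24 h) and one curve is
fitted per scan. A measurement film scanned at any postirradiation time
is then converted with the curve whose timestamp matches its own, so the
growth state of the calibration and the measurement always agree.

## The calibration model

For each calibration scan at time $t$, the mean pixel value $I$ of a
central region of interest (one third of the film area, same aspect
ratio) is extracted for each of the ten films (0–18 Gy in 2 Gy steps),
and the net optical density is

$$\mathrm{OD}_{net} = \log_{10}\!\left(\frac{I_0}{I}\right),$$

where $I_0$ is the mean pixel value of the *zero-dose film of the same
scan*. Because every film on the scanner bed sees the same bulb state,
taking $I_0$ from the same scan cancels scanner warm-up drift.

A least-squares cubic

$$D = a\,\mathrm{OD}^3 + b\,\mathrm{OD}^2 + c\,\mathrm{OD} + d$$

is fitted with dose as the response, so the stored coefficients convert
netOD to dose by direct evaluation. The TCM is the time-ordered list of
rows $[t, a, b, c, d, I_0]$, serialised as CSV
(`tcm_to_csv()` / `csv_to_tcm()`). Conversion of a measurement scan
(`convert_scan()`) looks up the curve nearest in time, forms the netOD
plane against that curve's stored $I_0$, and applies the cubic
pixel-wise.

### Design choices that were genuinely open

* **Fit direction.** A cubic could map dose to netOD (requiring root
  finding at conversion time) or netOD to dose (direct application). We
  fit netOD → dose, matching the lookup-and-apply conversion workflow;
  the CSV carries a `direction` comment so files from tools with the
  opposite convention are rejected rather than misread.
* **$I_0$ for measurement films.** A measurement film has no zero-dose
  companion. By default the matched curve's stored background intensity
  is used, which makes a single film self-sufficient; an unexposed
  in-scan reference rectangle can be supplied instead (`i0_rect`), which
  is preferable when the measurement scanner state differs from the
  calibration session.
* **Nearest-node lookup.** The curve nearest in time is applied (ties to
  the earlier curve); no interpolation between curves. Requests farther
  than twice the TCM interval from any node are refused rather than
  extrapolated.
* **Out-of-range netOD.** Values beyond the calibrated OD domain are
  clamped to the boundary (and counted in the provenance attributes),
  never extrapolated — a conservative choice for QA use, where a cubic's
  behaviour outside its support is meaningless.
* **ROI geometry.** Only the ROI *area* (one third of the film) is fixed
  by the workflow; we use a concentric rectangle of the same aspect
  ratio, sides scaled by $1/\sqrt{3}$, floored to integer pixels with a
  1-px minimum.

## The simulator

`render_calibration_scan()` / `render_measurement_scan()` emulate the
flatbed readout so the whole pipeline can be validated without physical
film. The generative model is, per colour channel,

$$I(x,y,t) = I_{base}\cdot \mathrm{drift}(t)\cdot
  10^{-\mathrm{OD}(D(x,y),\,t)}\;(1+\varepsilon),$$

with the netOD growth law

$$\mathrm{OD}(D,t) = \frac{\mathrm{od}_{24h}(D)}{1+g(D)}
  \left(1 + g(D)\,\frac{\log_{10}(t/t_{first})}
  {\log_{10}(t_{final}/t_{first})}\right),$$

so netOD is exactly linear in $\log_{10} t$, reaches the 24-h response
$\mathrm{od}_{24h}(D)$ at $t_{final}$, and has relative growth exactly
$g(D)$ from first to final scan.

Key parameter defaults and their rationale:

| Parameter | Default | Why |
|---|---|---|
| $g$(2 Gy), $g$(18 Gy), EBT3 red | 6.1%, 4.4% | measured film constants |
| EBT3 green | 7.9%, 6.3% | measured film constants |
| EBT-XD red | 8.2%, 5.7% | measured film constants |
| EBT-XD green | 8.7%, 7.8% | measured film constants |
| $g(D)$ between anchors | linear in $D$, clamped outside [2, 18] Gy | only per-dose-level growth is known; simplest monotone interpolant |
| $\mathrm{od}_{24h}(D)$ | $0.45\,D/(D+6) + 0.004\,D$ (red; green ×0.7) | saturating-plus-linear, the typical film response shape; deliberately *not* a cubic, so the calibration fit is a genuine approximation with ~0.1 Gy residual |
| drift amplitude | 1% over 24 h (smooth half-cosine ramp, identical for all films in a scan) | the measured scanner-stability envelope; applied multiplicatively so the in-scan zero-dose reference cancels it |
| pixel noise | 0 (off) | noiseless is the reference condition for the deterministic tests; enable `pixel_noise_sd` for robustness studies |
| background sentinel | 0.98 × 65535 | makes film-rectangle detection unambiguous |
| layout | ten 40 × 30 mm films, 2 × 5 grid, 72 DPI | the calibration-set geometry |
| time origin | minutes after the final calibration irradiation | the irradiation duration of the set (~15–20 min) is deliberately ignored, matching the workflow being modelled |

**What the simulator does and does not emulate.** It reproduces the
statistical structure the temporal analysis rests on: log-time OD
growth, its dose- and channel-dependence, bounded common-mode scanner
drift, optional pixel noise, and exact 16-bit quantisation. It does
*not* model film batch variation, temperature/humidity/UV response,
lateral scanner-response non-uniformity, or polarisation/orientation
effects. Passing synthetic tests therefore demonstrates the *software*
converts correctly whenever film behaves log-linearly — it does not
certify any particular physical film batch.

## Gamma analysis

`gamma_index()` implements the standard 2-D gamma comparison: for each
reference pixel above the low-dose threshold,

$$\gamma = \min_{\mathbf r'}\sqrt{
  \left(\frac{D_e(\mathbf r') - D_r(\mathbf r)}{\Delta D}\right)^2 +
  \left(\frac{|\mathbf r' - \mathbf r|}{\Delta d}\right)^2},$$

with the evaluated plane sampled by bilinear interpolation on a
sub-pixel grid. Defaults (all configurable): global normalisation to the
reference maximum, 10% low-dose threshold, search radius 3 × DTA,
interpolation step DTA/10. Offsets are visited in order of increasing
radius, and the search stops as soon as the spatial term alone exceeds
every pixel's current minimum — an exact optimisation. The optional
`max_gamma` cap truncates the search for pixels already known to fail
(reported values above the cap are lower bounds; pass/fail at
$\gamma \le 1$ is unaffected for caps above 1). The test suite checks
the engine against an exhaustive brute-force search to $10^{-6}$.

`pass_rate_vs_time()` reproduces the temporal validation: the scan at
the reference time (default 1200 min = 20 h) converted with its matched
curve is ground truth; all scans are converted either time-matched
(`mode = "tcm"`) or with the fixed reference curve
(`mode = "single_curve"`), and pass rates are normalised to the
reference. Column stability is summarised by the coefficient of
variation, defined with the *population* standard deviation
(divisor $n$): that convention reproduces the published per-case COV
values from the bundled tables, which the sample SD does not.

## Numerical choices and degenerate inputs

* Intensities are integer 16-bit counts end to end; TIFF round-trips are
  bit-exact. 8-bit inputs are scaled ×257 so white maps to white.
* Zero-valued pixels are patched to 1 count before the log (and
  counted); pixels at least as bright as $I_0$ clamp to netOD 0.
* Negative fitted doses clamp to 0 (and are counted); the fitted
  intercept is gated at |d| ≤ 0.3 Gy and curve monotonicity over the
  calibrated domain is checked, both with warnings.
* The cubic is fitted on the natural OD scale (no centring) so the CSV
  coefficients are portable; with netOD ≤ ~0.6 the design matrix is well
  conditioned.
* Dose grids are written with 9 significant digits (round-trip error
  < 1e-6 Gy); TCM coefficients with 17 (bit-faithful round-trip).
* A single-scan series is allowed (interval undefined) and degenerates
  to a conventional single-curve calibration.

## Validation problem sizes

The packaged validation runs at desk scale, chosen once as
representative: the end-to-end round trip uses 42 scan times (5–1440 min
at a 35-min interval, covering both endpoints exactly) with a 100 × 100
px, 12 Gy Gaussian dose plane, asserting every pixel within 2% of the
maximum dose at every time; the temporal-stability contrast uses 48
times (30–1440 min at 30 min, so the 20-h reference is a grid node) at
1%/1 mm. The gamma oracle comparison uses twenty seeded 12 × 12 plane
pairs. The full-resolution schedule (288 scans at 5-min intervals) is
exercised as schedule arithmetic and available through the simulator and
CLI.

## Known limitations

* The growth law is exactly log-linear by construction; real film shows
  small curvature at very early times, so sub-5-min behaviour is out of
  scope (as it is for the workflow itself).
* Blue-channel and triple-channel dosimetry, lateral scanner-response
  correction, film-to-TPS spatial registration and DICOM RT-Dose I/O are
  not implemented.
* The gamma engine is 2-D only and assumes co-registered grids (the
  evaluated plane is resampled onto the reference grid when spacings or
  origins differ, but no rigid registration is attempted).
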