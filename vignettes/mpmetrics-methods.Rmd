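---
title: "Models and methods behind mpmetrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mpmetrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpmetrics)
```

mpmetrics quantifies how well a deep-tissue multiphoton microscope performs
and when its excitation light starts to harm the sample. This vignette
explains the models the package fits, the conventions it fixes where the
underlying procedures leave room, and what its synthetic-data generator does
and does not emulate.

## The signal model

An n-photon-excited signal depends on the excitation pulse energy `E` as

    S(E) = A · E^n,

with `n = 2, 3, 4` for two-, three- and four-photon excitation and for
second/third harmonic generation. Inside scattering tissue the ballistic
excitation light decays as `exp(-z / l_e)` with depth `z`, where `l_e` is the
effective attenuation length, so the emitted n-photon signal decays as
`exp(-n z / l_e)`: a three-photon signal drops by `1/e³` over one `l_e`.
These two power laws are the backbone of every estimator in the package.

## Excitation-order determination

`normalize_power_series()` turns a power-series recording (frames at varying
pulse energy, each followed by a reference frame at a fixed low energy) into
the normalized, bleaching-corrected, background-subtracted signal

    S_k = F_norm · (I_mean,k − B_mean,k) / (I_ref,k − B_ref,k).

Because each measurement frame is divided by a reference acquired one scan
later, any bleaching that acts multiplicatively on the fluorophore pool
cancels exactly up to a constant factor absorbed into `F_norm` (for
mono-exponential bleaching at rate `r` per scan the ratio of residual-pool
factors is the constant `(1−r)^{-1}`). `F_norm` defaults to making
`max(S) = 1`; the constant is immaterial to the fitted order.

`fit_power_law()` fits `S = A·E^n` by orthogonal distance regression: both
the energy uncertainties (a relative measurement error, default 3% — a
configuration value, not a measured one, and flagged as such in reports) and
the propagated signal uncertainties weight the fit. The chi-square

    Σ_i (P_i − p_i)²/σ_P,i² + (S_i − A·p_i^n)²/σ_S,i²

is minimized over `A`, `n` and the latent true energies `p_i`, starting from
an ordinary log-log least-squares fit (a convex surrogate that makes the
start robust). Parameter standard errors come from the curvature of the
chi-square at the minimum scaled by the reduced chi-square, the ODRPACK
convention. The degrees of freedom are `N − 2`; the latent energies do not
count. Saturation and damage limits are not auto-detected: the fit range is
an explicit argument, because those limits come from independent knowledge of
the sample. `qc_fit()` applies the quality gates reduced chi-square `< 2`
and adjusted R-square `> 0.995`, both strict.

## SNR, depth limits and attenuation lengths

`snr_profile()` computes, per plane, `SNR = (I_mean − B_mean)/σ_B` where
`I_mean` is the mean of the brightest fraction of pixels of the
median-filtered plane (1% for harmonic signals with radius 1; 10% for nuclei
and 40% for cytosolic labels with radius 2) and the background statistics
come from a user-supplied dark ROI of the *unfiltered* stack. Whether `σ_B`
is estimated per plane or pooled over the stack is a flag
(`per_plane_background`); both conventions are defensible and the default is
per plane. `depth_limit()` reports the depth of the *last* crossing of the
SNR curve below the detection threshold (default 3), linearly interpolated
between the bracketing planes — linear interpolation keeps the estimate
deterministic and grid-independent to first order.

`attenuation_signal()` removes the applied energy ramp and the process order
from a depth profile,

    S(z) = N · ((I_mean − B_mean) / P(z)^n)^{1/n},

so that ballistic attenuation appears as the single exponential
`A·exp(−z/l_e)` that `fit_attenuation()` fits (Levenberg–Marquardt via
minpack.lm, initialized from the log-linear slope). The `1/n` exponent keeps
the `1/e^n` definition of `l_e` while presenting all orders on a common
scale; fitting `(I−B)/P³` against `exp(−3z/l_e)` gives the identical `l_e`,
and the test suite asserts that equivalence. Layered tissue is handled by
fitting per-layer depth windows, which are explicit arguments for the same
reason fit ranges are. For the deepest-plane background convention of
attenuation analysis, `last_frame_background()` provides the mean over the
final frame.

`axial_resolution()` scores resolution as the maximum derivative of 0–1
normalized feature z-profiles, with central differences in the interior and
one-sided differences at the profile ends. Flat profiles are excluded with a
warning; summaries outside the conventional 11–17 features per channel
trigger an informational note.

## Phototoxicity readouts

Per-cell analysis: `extract_traces()` averages a two-pixel-radius disc at
tracked coordinates ("two-pixel mean" is read as a radius; the display-only
×10 scaling of the original toolchain is omitted because every downstream
statistic is scale invariant). `sytox_trace()` divides the
background-subtracted nucleus trace by the cytosol trace to cancel
calcium-indicator crosstalk from the nuclear dead-cell-stain signal.
`smooth_normalize()` applies Savitzky–Golay smoothing with polynomial order
2 and a nominal 10-point window — widened to 11 because the filter needs a
centre sample — then normalizes to the maximum of a cytosol reference trace.
`classify_responder()` thresholds at `mean + 3·SD` of the *unsmoothed*
pre-exposure baseline (population SD, the package-wide convention) and by
default detects crossings on the smoothed trace; smoothing suppresses
single-sample noise excursions and is why the classifier keeps high
specificity over hundreds of post-baseline frames.

Under a Gaussian null the exact per-sample probability of exceeding the
estimated threshold is a Student-t tail,
`P(t_{n−1} > 3·sqrt((n−1)/(n+1)))` for an `n`-frame baseline
(`responder_null_rate()`); it converges from above to the one-tailed 3σ level
`1 − Φ(3) ≈ 0.00135` as the baseline grows. The finite-baseline value (about
0.0025 at 50 frames) is the correct calibration reference for simulated
nulls; the asymptotic value is what significance statements quote.

Area analysis: `area_response_fraction()` thresholds each median-filtered
frame at `mean + 3·SD` of the 95% dimmest ROI pixels of a pre-exposure
reference frame, subtracts the pre-exposure positive mask dilated six times
(3×3 square element) to absorb drift and expansion, and divides the
remaining positive area by the ROI area corrected for the *undilated*
pre-exposure positives. With the undilated correction the reported fraction
can only shrink when the dilation margin is widened — the property the
subtraction is meant to guarantee — whereas dividing by the dilated area
would let the fraction grow with the margin. Group comparisons use the
two-sided Mann–Whitney test with median/quartile summaries; two fully tied
samples are reported as `p = 1`.

`bleaching_curve()` follows background-subtracted, auto-threshold-selected
cell intensity over repeated scans (mean filter radius 2, Huang or IsoData
thresholds re-derived per scan so the curve is invariant to global intensity
rescaling) and reports the percent decline relative to the first scan.

## The synthetic-data generator

`make_depth_stack()` renders Gaussian-blob features over a uniform
background, scaled per plane by `(P(z)/P(0))^n · exp(−n·z/l_e)` (piecewise
for layered tissue), with Poisson shot noise (exact below 20 counts,
mean-preserving Gaussian above — correct asymptotics at a fraction of the
cost) plus Gaussian read noise. Defaults encode the conditions the
estimators target: a third-order process, `l_e = 220` µm, 0–400 µm in 5 µm
steps, an attenuation-compensating energy ramp (the experimenter raises the
power to hold emission constant), and a surface SNR of 50 set by calibrating
the feature amplitude against the analytic background SD. The top-left
corner of every frame is kept feature-free as a dark background ROI.

`make_power_series()` renders a uniform disc cell under the stepwise
decreasing-then-increasing energy protocol (ten energies spanning a factor
of three, 2–6 nJ, dimmest-frame signal 400 counts so the shot-noise SNR
stays at or above 20), with every scan — measurement or reference —
bleaching the fluorophore pool.

`make_viability_movie()` renders static cells (cytosol disc with nuclear
core) on a grid: per-cell scalar intensity series with a baseline
fluctuation SD, population-specific responses (quiet; spontaneous reversible
Gaussian transients; steep sigmoidal rises at exposure onset; gradual ramps)
and, for steep responders, a delayed nuclear stain influx that saturates
within about ten frames (~33 s) of membrane failure — fast uptake after a
broadly spread onset delay, which is the regime the delay-recovery analysis
assumes. The default response amplitude is 30 baseline-SD units, a
multi-fold intensity rise as sustained stress responses show; classifier
sensitivity analyses pass 5 SD explicitly to probe the near-threshold
regime. The default population mixture (16% quiet, 12% spontaneous, 11%
steep, 61% gradual) mirrors a toxic-exposure composition. Amplitudes are
expressed against the analytic SD of the extracted 13-pixel disc mean, so
ground truth and estimator operate on the same scale.

What the generator does *not* emulate: optical wave propagation, aberrations
and depth-dependent focal degradation; cell motion (drift robustness is
exercised through the dilation margin, which is exactly what the area
method's margin exists for); spectral crosstalk beyond the nucleus/cytosol
ratio model; and detector nonlinearity. Passing recovery tests therefore
demonstrate estimator correctness under the stated statistical model, not
robustness to every real-world confound.

## Numerical conventions

- Population SD (divide by N) for all image region statistics.
- 1-based indices; plane 1 is the shallowest depth or earliest frame.
- Median filters: square window of the given radius; integer-valued images
  are filtered bit-exactly; erosion/dilation use a 3×3 square element with
  replicated borders.
- Bright-pixel selection takes `ceil(fraction × N)` pixels, ties at the cut
  broken by raster order — deterministic and testable.
- Automatic thresholds (Otsu, Huang, IsoData) operate on a 256-bin histogram
  spanning the image range; masks keep pixels strictly above the threshold.
- Interpolations (depth limits, power schedules) are linear and exact at
  grid nodes; extrapolation is an error.
- Every stochastic generator takes an explicit integer seed and restores the
  caller's RNG state.

## Problem sizes

The shipped tests run on deliberately small scenes — 48-pixel frames, 81
planes, tens to hundreds of replicates, a 200-cell movie — chosen so the
whole suite exercises every estimator end-to-end at meaningful statistical
power while staying desk-scale. The estimators themselves are size-agnostic.

## Known limitations

- The ODR standard errors use the local curvature at the optimum; for very
  small or nearly noiseless series they are indicative, not exact.
- `bleaching_curve()` expects one plane per scan; volumetric recordings must
  be z-projected upstream.
- Thresholding methods assume a roughly bimodal histogram; near-constant
  images are rejected rather than guessed at.
- The immersion-absorption correction is a single Beer–Lambert factor with a
  user-supplied coefficient; instrument-specific calibration tables are the
  user's responsibility and no default coefficients are presented as ground
  truth.
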