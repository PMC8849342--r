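# mpmetrics

Quantitative analysis of deep-tissue multiphoton microscopy experiments, for
labs running 2-, 3- and 4-photon (and harmonic-generation) imaging in
strongly scattering samples — tumors, bone, brain — who need to answer, from
their own image stacks:

- **Which nonlinear process produced each signal?** The emission follows
  `S(E) = A·E^n`; `mpmetrics` fits the order `n` from power-series
  recordings by orthogonal distance regression, with interleaved
  reference-frame correction that cancels photobleaching exactly, and
  quality gates (reduced χ² < 2, adjusted R² > 0.995).
- **How deep can I image?** Per-plane `SNR = (I_mean − B_mean)/σ_B` from
  brightest-percentile statistics, and the SNR-limited depth as the
  interpolated last crossing of the detection threshold (SNR = 3).
- **How fast does the tissue attenuate my excitation?** The effective
  attenuation length `l_e` from the power- and order-normalized signal
  `S(z) = N·((I_mean − B_mean)/P^n)^{1/n}` fitted with `A·exp(−z/l_e)`
  (so an n-photon signal drops by `1/e^n` over one `l_e`), including layered
  tissue via per-layer fit windows.
- **How sharp do features stay at depth?** Axial-resolution scores
  `(δI/δz)_max` from normalized feature z-profiles.
- **Is the laser hurting my cells?** Calcium-indicator / dead-cell-stain
  (GCaMP/Sytox) analysis: per-cell responder classification at the
  `mean + 3·SD` baseline threshold, crosstalk-corrected nuclear stain
  ratios, image-area response fractions with drift-tolerant mask
  subtraction, photobleaching curves, and Mann-Whitney exposure-group
  comparisons.

A fully seeded synthetic-data generator (`make_depth_stack()`,
`make_power_series()`, `make_viability_movie()`) produces ground-truthed
image stacks so every estimator is testable without microscope data.

Results are tidyverse-native: tabular outputs are tibbles, fitted objects
have `tidy()`/`glance()` methods and `autoplot()` figures, and everything
chains with the pipe. Image stacks travel as TIFF plus a YAML metadata
sidecar.

## Worked example

Determine an excitation order from a bleach-referenced power series, then
profile a depth stack:

```r
library(mpmetrics)

# --- excitation order ----------------------------------------------------
sim <- make_power_series(n = 3, noise = list(shot = TRUE, read_sd = 1,
                                             rel_sd = 0.02), seed = 42)
fit <- sim$series |> normalize_power_series() |> fit_power_law()
fit
#> <power_law_fit> S = A * E^n: n = 3.036 +/- 0.016, A = 0.004339 +/- 9.29e-05
#>   19 points in [2, 6] nJ; red. chi-sq 0.0659, adj. R2 0.99926
qc_fit(fit)
#> # A tibble: 1 × 2
#>   pass  reasons
#>   <lgl> <chr>
#> 1 TRUE  ""

# --- SNR and attenuation vs depth ---------------------------------------
sim2 <- make_depth_stack(scene_config(l_e_um = 220, seed = 42))
prof <- snr_profile(sim2$stack, background_roi = sim2$truth$background_roi,
                    order_n = 3)
fit2 <- prof |> attenuation_signal(order_n = 3) |> fit_attenuation()
fit2
#> <attenuation_fit> l_e = 220.2 +/- 0.2 um (A = 1, 81 points in [0, 400] um)
depth_limit(prof)
#> # A tibble: 1 × 2
#>   depth_limit_um status
#>            <dbl> <chr>
#> 1            400 not_limited
```

The fitted order `n = 3.04 ± 0.02` identifies a three-photon process and
passes both quality gates; the recovered attenuation length matches the
generative 220 µm. Because this stack was recorded with an
attenuation-compensating energy ramp the SNR never drops below 3, so the
depth limit reports the deepest measured plane with a `not_limited` flag.

A command-line front end wraps the same pipelines
(`inst/exec/mpmetrics <subcommand> --config cfg.yaml --seed 1 --out dir`),
with subcommands `simulate`, `order-fit`, `snr-depth`, `attenuation`,
`resolution`, `bleaching`, `phototox-trace` and `phototox-area`; every run
logs the package version, seed and config hash.

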