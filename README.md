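# drsquant

Quantitative diffuse reflectance spectroscopy (DRS) of tissue in the
500–600 nm hemoglobin band.

A fiber-optic contact probe illuminates tissue with white light and collects
the diffusely backscattered spectrum. In the 500–600 nm window that spectrum
is shaped almost entirely by hemoglobin absorption and by tissue scattering,
so fitting it with a physical forward model recovers clinically meaningful
physiology: hemoglobin oxygen saturation (SO₂ = [HbO₂]/([HbO₂]+[dHb])),
total hemoglobin concentration (THb, µM), and the reduced scattering
coefficient μs′. Tumors are typically hypoxic, so SO₂ is a candidate optical
biomarker for discriminating cancerous from normal tissue at the bedside —
provided the measurement itself is reproducible, which is why the pipeline
also models the two instrumental safeguards of modern probes: real-time
self-calibration against a reflectance standard, and a contact-pressure gate
that only accepts measurements taken in a physiologically gentle pressure
window.

`drsquant` implements the full analysis chain as composable, pipe-friendly
functions:

* **Forward model** — a white (absorption-rescaled) Monte Carlo photon
  transport kernel (`simulate_baseline()`, Rcpp) for the two-fiber probe
  geometry. One baseline run at zero absorption records per-photon
  pathlengths and exit positions; reflectance at any (μa, μs′) follows by
  similarity rescaling and Beer–Lambert weighting (`reflectance()`), with a
  precomputed lookup table (`build_lut()`) for fast inversion and a
  closed-form diffusion-theory oracle (`diffusion_reflectance()`) as an
  independent cross-check.
* **Tissue optics** — absorption from oxy/deoxy-hemoglobin extinction with
  the cylindrical-vessel pigment-packing correction
  `C = (1 − exp(−2 μa,bl R)) / (2 μa,bl R)` and a smooth non-hemoglobin
  baseline (`mua_total()`, `packing_factor()`); scattering from the power law
  μs′ = A·λ⁻ᵇ (`mus_prime()`).
* **Self-calibration** — background subtraction and normalization to the
  Spectralon standard channel, `R = (T − T_bg)/(S − S_bg) · ρ_std`
  (`calibrate()`); lamp drift and fiber-bending losses multiply both
  channels and cancel exactly in the ratio.
* **Inversion** — bounded multi-start nonlinear least squares over
  (THb, SO₂, mean μs′, b, baseline scale) (`fit_spectrum()`, `fit_batch()`),
  with broom-style `tidy()`/`glance()` and `autoplot()` methods.
* **Pressure gate** — accepts samples with contact pressure inside an
  inclusive 24–72 mmHg window sustained for a dwell time (`gate_trace()`).
* **Statistics** — a subject-random-intercept linear mixed model fitted by
  profiled REML (`fit_lmm()`), a site-level permutation oracle
  (`permutation_test()`), and a per-site ANOVA (`anova_groups()`).
* **Synthetic cohorts** — `generate_cohort()` emulates a 19-subject
  repeated-measures optical biopsy study (12 cancer / 14 normal / 1 benign
  sites, 5 repeats per site), producing raw channel spectra, pressure traces
  and withheld ground truth, so the entire chain is testable without any
  clinical data.

## Worked example

```r
library(drsquant)

# 1. Build the probe's photon kernel once and attach its lookup table
kernel <- build_lut(simulate_baseline(n_photons = 2e5, seed = 11))
kernel
#> <mc_kernel> 200,000 photons launched, 182559 exits recorded
#>   mus_ref: 10 cm^-1  g: 0.9  seed: 11
#>   probe: d = 0.75 mm, separation = 1.5 mm, NA = 0.22
#>   baseline collection efficiency: 0.0004618  [lookup table attached]

# 2. Synthesize a well-oxygenated tissue spectrum and invert it
spec <- forward_spectrum(kernel, THb = 30, SO2 = 0.95, mean_mus_prime = 15, b = 1)
fit <- fit_spectrum(spec, kernel)
fit
#> <drs_fit> converged in 18 iterations; rss = 6.255e-11
#>   THb = 29.65 uM   SO2 = 0.947   mean mus' = 15.20 cm^-1   b = 1.266   s_base = 0.044
```

The fit recovers saturation to 0.003 and total hemoglobin to ~1% — SO₂ and
THb are strongly identified by the α/β oxyhemoglobin bands near 580/540 nm,
while the scatter power `b` trades off against the featureless baseline and
is recovered only loosely (see the methods vignette).

```r
# 3. Full synthetic study: simulate -> gate -> calibrate -> fit -> compare
run <- run_pipeline(cohort_config(seed = 1), kernel)
print(run)
#> <drs_run> 135 measurements fitted; 0 rejected by the pressure gate
#>
#> Group summaries (median [q1, q3]):
#>   SO2             non-cancer    0.731 [   0.656,    0.785]
#>   THb             non-cancer   23.968 [  21.108,   30.586]
#>   mean_mus_prime  non-cancer   12.857 [   9.550,   20.234]
#>   SO2             cancer        0.388 [   0.300,    0.427]
#>   THb             cancer       29.614 [  22.680,   34.965]
#>   mean_mus_prime  cancer       16.222 [  12.794,   20.400]
#>
#> Mixed-effects p-values (Wald):
#>   SO2             group: p = 2.2e-308   repeat: p = 0.602
#>   THb             group: p = 0.69       repeat: p = 0.235
#>   mean_mus_prime  group: p = 0.69       repeat: p = 0.732
```

The run reproduces the qualitative pattern the analysis is designed to
detect: cancer sites show markedly lower hemoglobin saturation (group
p ≪ 0.001) while THb and scattering show no group difference, and no
endpoint drifts across the five repeated measurements (all repeat p > 0.1).
`plot_cohort_endpoints(run$cohort_table)` and
`plot_repeat_differences(run$repeat_diff)` draw the corresponding box plots;
`autoplot(fit)` shows a measured/fitted spectrum with residuals.

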