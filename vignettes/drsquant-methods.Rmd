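---
title: "Models and methods behind drsquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind drsquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(drsquant)
```

This vignette is the package's own account of its science: the forward
model and its assumptions, the inversion, the measurement-side arithmetic
(self-calibration and pressure gating), the statistical comparison stage,
what the synthetic cohort generator does and does not emulate, and the
numerical choices that were genuinely open.

## The physical picture

A two-fiber contact probe delivers broadband light into tissue and collects
the diffusely backscattered spectrum a millimeter or two away. Between 500
and 600 nm the spectrum is dominated by two things:

* **Absorption by hemoglobin.** Oxyhemoglobin has two absorption maxima in
  this window (the β band near 542 nm and the α band near 577 nm);
  deoxyhemoglobin has a single broad band near 556 nm. The shape of the
  measured spectrum therefore encodes the oxygen saturation
  SO₂ = [HbO₂]/([HbO₂]+[dHb]) and the total concentration
  THb = [HbO₂]+[dHb], reported in µM of tissue volume.
* **Elastic scattering** by cells and fibrous structure, summarized by the
  reduced scattering coefficient μs′(λ), modeled by the power law
  μs′ = A·λ⁻ᵇ with amplitude `A` and scatter power `b`.

Because hemoglobin is confined to discrete vessels rather than dissolved
uniformly, strong absorption bands saturate within vessels and appear
flattened at the tissue level. The model corrects for this with the
cylindrical-vessel pigment-packing factor

> C(λ) = (1 − exp(−2 μa,bl(λ) R)) / (2 μa,bl(λ) R),

where μa,bl is the hemoglobin absorption at the fitted concentration and
`R` an effective vessel radius. `C → 1` as μa,bl·R → 0 (the limit is
evaluated analytically) and decreases monotonically as vessels become
optically opaque. The total absorption is

> μa(λ) = C(λ) · ln(10) · [ε_HbO₂(λ)·SO₂ + ε_dHb(λ)·(1−SO₂)] · THb·10⁻⁶
>        + s_base · μa,base(λ),

with a smooth non-hemoglobin baseline μa,base(λ) = (λ/500)⁻³·²⁵⁵ cm⁻¹
scaled by the dimensionless `s_base`. Two conventions matter for users:

* μa,bl is *tissue-level* hemoglobin absorption at the fitted µM
  concentration, not whole-blood absorption; if you prefer the whole-blood
  convention, rescale `R_vessel` accordingly.
* `R_vessel` defaults to 10 µm and is held fixed during fitting. Whether a
  vessel radius should be fitted at all is an open modeling question in this
  wavelength window; it is exposed as configuration rather than guessed at.

### The bundled extinction table is synthetic

The package ships `hemoglobin_extinction_synthetic.tsv`: a *parametric*
approximation of the hemoglobin molar extinction spectra (Gaussian visible
bands plus a Soret-edge tail and a long-wavelength shoulder), with band
positions and magnitudes set to the well-established published values. It
has the correct band structure — two oxy maxima at 542/577 nm, one deoxy
maximum near 556 nm, realistic amplitudes of ~5×10⁴ cm⁻¹M⁻¹ — and is
exactly what the simulation-based tests need, but it is not a digitized
laboratory measurement. For quantitative work on real spectra, substitute a
measured compilation via `load_extinction(path)`; any 3-column table on a
strictly ascending grid works, and linear interpolation reproduces stored
nodes exactly.

## Forward model: white Monte Carlo with similarity rescaling

`simulate_baseline()` runs photon transport once, at zero absorption
("white" Monte Carlo), in a semi-infinite homogeneous medium: photons
launch uniformly over the source fiber face within its acceptance cone,
propagate with exponential step sampling at μs = μs′/(1−g), scatter by
Henyey–Greenstein with anisotropy `g`, and undergo Fresnel/total-internal
reflection at the surface when the relative index differs from 1. Each
photon exiting the top surface contributes a record (pathlength, exit
displacement from its launch point, launch radius, weight, exit angle
cosine).

`reflectance()` then evaluates the probe signal for any per-wavelength
(μa, μs′): pathlengths and exit displacements scale by μs_ref/μs(λ)
(similarity rescaling at fixed g), detector capture is re-tested against
the scaled exit position, and each record is weighted by exp(−μa·L). The
detector is treated as an annulus with arc-overlap weighting — the classic
radial-symmetry trick that lets one baseline run serve every wavelength of
every fit. `build_lut()` tabulates this on a (μa, μs′) grid so the
inversion evaluates the forward model by bilinear interpolation of
log-reflectance; this is the scaled-Monte-Carlo lookup-table strategy
standard in DRS instrumentation, and it agrees with the exact per-record
sum to better than ~1–2% across the fit bounds (asserted in tests).

Defaults, all exposed in `probe_geometry()` / `simulate_baseline()`:
750 µm fiber faces, 1.5 mm center-to-center separation (two adjacent clad
fibers), NA 0.22, index-matched contact (n_relative = 1), g = 0.9,
μs′_ref = 10 cm⁻¹, 10⁶ launched photons (test and example kernels use
2×10⁵, which leaves Monte Carlo noise well below the fitting tolerances
because all wavelengths share one record set). A pathlength cutoff of
200 cm discards photons whose Beer–Lambert weight would be negligible at
any tissue-like absorption. Queries more than a factor 10 in μs′ from the
baseline refuse to extrapolate rather than degrade silently.

Two independent oracles check the kernel:

* `diffusion_reflectance()`, the steady-state extrapolated-boundary dipole
  solution, matches the kernel's per-area radial reflectance within 15% in
  the high-albedo regime (μs′/μa ≥ 100) at the probe separation.
* Conventional *absorbing* Monte Carlo runs (`mua > 0`, albedo weighting
  with Russian roulette) agree with white-MC rescaling within Monte Carlo
  error at μa from 0.5 to 5 cm⁻¹.

A caveat stated honestly: the similarity relation μs′ = μs(1−g) is exact
only in the diffusive regime. At this probe's 1.5 mm separation, kernels
built at g = 0 versus g = 0.9 with equal μs′ differ by tens of percent in
collected fraction — real transition-zone physics, not Monte Carlo error.
Kernels are therefore built at the anisotropy you intend to model
(default 0.9), and only μs magnitude is rescaled between wavelengths, which
leaves g fixed and the rescaling exact in the similarity sense used.

## Self-calibration and the pressure gate

`calibrate()` implements
R(λ) = (T − T_bg)/(S − S_bg) · ρ_std — tissue and Spectralon-standard
channels, each background-subtracted, ratioed, and scaled by the standard's
reflectivity (default 0.99, spectrally flat, overridable per wavelength).
Any multiplicative distortion common to both channels — lamp intensity
drift, fiber bending loss — cancels exactly in the ratio; the test suite
asserts invariance to 10⁻¹² relative over random drift curves. Negative
post-subtraction values are *retained and flagged* (count in attribute
`n_negative`), never clipped, because clipping biases low-signal fits.
Channels on different grids are resampled to the tissue grid before
ratioing; `resample_to_grid()` linearly interpolates onto the closed
500–600 nm, 2.5 nm analysis grid (41 points) and refuses to extrapolate.

`gate_trace()` accepts a sample when contact pressure lies in the
*inclusive* window [24, 72] mmHg and reports trigger intervals as maximal
accepted runs sustained at least `dwell` seconds. Published descriptions of
such triggers do not fix a dwell time; the default 0.5 s
exercises the run-length logic, and a dwell below the sampling interval
reproduces instantaneous triggering, covering both readings of the design.

## Inversion

`fit_spectrum()` minimizes Σ_λ [R_meas − scale·R_model(θ)]² with
θ = (THb, SO₂, mean μs′, b, s_base), by bounded Levenberg–Marquardt
(`minpack.lm`) from a documented grid of starting points, keeping the best
minimum. Choices that were genuinely open:

* **Parameterization.** (THb, SO₂) are fitted directly rather than
  ([HbO₂], [dHb]) so bounds stay physiological (THb ∈ [0, 500] µM,
  SO₂ ∈ [0, 1]); the scattering amplitude is parameterized by the grid-mean
  μs′ so its bounds are in cm⁻¹. The reported `mean_mus_prime` *is* that
  grid mean over 500–600 nm (whether a single-wavelength value would be
  preferable is unstated in the underlying design; the grid mean is
  documented and consistent).
* **Bounds.** mean μs′ ∈ [2, 70] cm⁻¹ — pulled in from the kernel's nominal
  [1, 100] rescaling range so the power-law extremes at the grid edges stay
  inside it for any `b` ∈ [0, 3]; s_base ∈ [0, 5].
* **Multi-start.** The default start set is the 27-point grid
  THb ∈ {10, 30, 80} × SO₂ ∈ {0.2, 0.6, 0.9} × b ∈ {0.5, 1.5, 2.5}. The
  oxygenation starts cover the physiological regimes; the scatter-power
  starts exist because the objective has a shallow valley in which `b`
  collapses toward 0 with the baseline and amplitude compensating
  (residuals ~0.5%, far below the global minimum of a self-consistent
  spectrum but above machine precision). With a single mid-bounds `b`
  start, a few percent of fits land in that valley; the grid removes
  essentially all such cases at ~0.5 s per spectrum.
* **Identifiability.** SO₂ and THb are strongly identified by the α/β band
  structure (noiseless recovery to ±0.02 absolute and ±5% relative in ≥95%
  of draws across the prior ranges; ±0.05 SO₂ in ≥90% under 1%
  multiplicative noise). The scatter power `b` is only weakly identified in
  a 100 nm window and should be interpreted cautiously.
* **Scale.** `scale` is fixed at 1 by default — self-calibration makes
  synthetic spectra absolute relative to the standard — and can be freed
  for real instruments (`fit_config(fit_scale = TRUE)`); freeing it leaves
  the shape parameters invariant and absorbs constant factors, which is
  asserted as a test.
* **Weighting** is uniform (no per-wavelength noise model is assumed), and
  convergence uses relative tolerance 10⁻¹⁰ with a 500-iteration cap; a fit
  failing from every start returns `converged = FALSE` with the best-found
  parameters rather than aborting a batch.

## The mixed-effects comparison stage

Endpoints from repeated measurements of multiple sites per subject are
compared with the random-intercept model
y_ij = x_ijᵀβ + u_i + ε_ij, u_i ~ N(0, σ_u²), ε_ij ~ N(0, σ_e²),
with diagnosis group (cancer vs non-cancer, benign grouped with normal) as
a factor and repeat number as a continuous covariate. With a single
variance ratio γ = σ_u²/σ_e², REML reduces to one-dimensional profiling:
β(γ) is closed-form generalized least squares via the Sherman–Morrison
block inverse, and γ is found by bounded search on [0, 10⁶] (the boundary
γ = 0 is always evaluated). This implementation agrees with `nlme::lme` to
five significant figures on shared fits (asserted in tests) — `nlme` serves
as the independent oracle, not the implementation. Wald p-values use the
standard normal reference; with ~130 observations the normal-versus-t
distinction is immaterial, and `permutation_test()` (site-level label
permutation, repeats kept intact, exact enumeration when the arrangement
count is small) provides the finite-sample check. `anova_groups()` runs the
accompanying one-way ANOVA on per-site means, with sites as units.
Pressure enters the default formula not at all: the gate's job is to make
it uninformative, and binning an optional pressure column into a factor is
left to the user's formula.

A "multivariate" reading of this comparison (both endpoints as joint
responses) is possible; the package fits separate univariate models per
endpoint, which is what per-endpoint effect reporting requires.

## What the synthetic generator emulates — and what it does not

`generate_cohort()` reproduces the *design* of a 19-subject repeated-
measures optical biopsy study: 12 subjects contribute a cancer site, 14 a
distant-normal site, 1 a benign site (sites exceed subjects because
subjects contribute up to two), 5 repeats per site. (Study descriptions
sometimes quote 10 repeats in summary text and 5 in methods; the generator
default follows the methods-level count and is configurable.) Endpoint
distributions are *generator choices* that reproduce the qualitative
contrasts the analysis is designed to detect, not values read from any
measured cohort: site SO₂ ~ mean 0.70 (normal/benign) vs 0.35 (cancer)
with SDs 0.10/0.12; THb log-normal (median 25 µM, geometric SD 1.6) with
no group difference; mean μs′ uniform on 5–25 cm⁻¹, b on [0.5, 1.5]; zero
repeat trend.

Two structural choices deserve emphasis:

* **Variance placement.** All between-site variation is carried at the
  subject level — a subject's sites share one standardized random effect
  per endpoint, scaled by the site-type SD — plus small repeat-level jitter
  (SO₂ SD 0.02; THb/μs′ multiplicative 3%/2%). This makes the generated
  variance structure (subject + repeat) match the subject-random-intercept
  analysis model, so the Wald tests are correctly sized against it:
  empirical type-I error at α = 0.05 lands in [0.03, 0.07] and the
  repeat-effect p exceeds 0.1 in ≈90% of null cohorts (both asserted over
  hundreds of simulated cohorts). Real tissue adds site-level variance
  components the subject intercept cannot absorb; against such data the
  same tests can be conservative for within-site effects and anticonservative
  for between-site contrasts — a caveat for transferring conclusions, not a
  defect of the tests.
* **Raw-data realism.** In spectra mode the generator synthesizes the true
  reflectance through the same forward model, then *inverts the calibration
  arithmetic* to produce four raw channels under a sampled lamp-drift curve
  (smooth halogen-like lamp shape, per-measurement drift in amplitude and
  tilt), adds 1% multiplicative noise plus small additive noise anchored to
  each channel's own signal level, and attaches a pressure trace built to
  pass the gate. With noise off and drift arbitrary, `calibrate()`
  reproduces the true reflectance to 10⁻¹² — the drift cancels by
  construction, which is exactly the self-calibration claim at the
  arithmetic level. The generator does not emulate wavelength-dependent
  instrument response beyond the lamp shape, detector nonlinearity,
  pressure-induced physiology, or histopathology beyond the site label.

Ground truth joins 1:1 with measurements but is never consumed by the
fitting path, so recovery benchmarks are leakage-free by construction.

Passing tests on these cohorts demonstrate that the *pipeline* is correct
and well-calibrated under its stated model; they do not certify accuracy on
real tissue, where extinction-table fidelity, probe coupling and layered
anatomy all intrude.

## Simulation sizes and runtime

Problem sizes in the tests and acceptance checks are chosen to estimate
each quantity comfortably on one CPU: kernels of 2×10⁵ photons (shared
across test files), 50-spectrum recovery suites, 200 cohorts for test size
and 100 for power, 1000 random traces for the gate oracle. Each is large
enough that the binomial or Monte Carlo error of the checked rate is small
against its acceptance band.

## Known limitations

* The bundled extinction table is a labelled synthetic stand-in (above).
* `b` is weakly identified over 500–600 nm; treat fitted scatter power as
  qualitative. Whether this window is optimal for diagnostic accuracy is
  explicitly out of scope.
* The kernel models a homogeneous semi-infinite medium; layered mucosa,
  finite lesions and probe-face perturbation of the tissue are not modeled.
* No confidence intervals on fitted optical parameters are reported, and no
  multiple-testing correction is applied across endpoints.
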