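#' Fiber-optic probe geometry
#'
#' Describes the two-fiber contact probe: source and detector face diameter,
#' center-to-center separation, fiber numerical aperture, and the relative
#' refractive index at the tissue surface (`n_relative = n_tissue / n_ambient`;
#' 1 means index-matched contact, the default). The detector is modelled as an
#' annulus around the source axis with arc-overlap weighting, which preserves
#' radial symmetry so one baseline photon run serves every wavelength.
#'
#' @param fiber_diameter Fiber face diameter, mm (default 0.75).
#' @param sd_separation Source-detector center-to-center separation, mm
#'   (default 1.5, i.e. two adjacent 750 um fibers with cladding).
#' @param numerical_aperture Fiber NA (default 0.22).
#' @param n_relative Refractive index ratio at the surface (default 1).
#' @return A list of class `probe_geometry`.
#' @export
probe_geometry <- function(fiber_diameter = 0.75, sd_separation = 1.5,
                           numerical_aperture = 0.22, n_relative = 1.0) {
  if (fiber_diameter <= 0) abort("fiber_diameter must be > 0")
  if (sd_separation < fiber_diameter) {
    abort("sd_separation must be >= fiber_diameter (non-overlapping faces)")
  }
  if (numerical_aperture <= 0 || numerical_aperture >= 1) {
    abort("numerical_aperture must lie in (0, 1)")
  }
  if (n_relative < 1) abort("n_relative must be >= 1")
  structure(list(
    fiber_diameter = fiber_diameter, sd_separation = sd_separation,
    numerical_aperture = numerical_aperture, n_relative = n_relative
  ), class = "probe_geometry")
}

#' Run the baseline white Monte Carlo photon simulation
#'
#' Launches photons uniformly over the source face, within the fiber
#' acceptance cone, into a semi-infinite homogeneous medium with reduced
#' scattering `mus_ref` and Henyey-Greenstein anisotropy `g`, at zero
#' absorption (white Monte Carlo). Surface crossings are handled with
#' Fresnel/total-internal-reflection sampling when `n_relative > 1`. Each
#' photon exiting the top surface is recorded (pathlength, exit displacement,
#' launch radius, weight, exit direction cosine); the record set is the
#' reusable forward-model kernel queried by [reflectance()].
#'
#' Setting `mua > 0` runs a conventional absorbing simulation (step sampling
#' at `mus + mua`, albedo weighting, Russian roulette); this mode exists as an
#' independent cross-check of the white-MC rescaling and is not needed for
#' fitting.
#'
#' @param geom A [probe_geometry()].
#' @param mus_ref Baseline reduced scattering coefficient, cm^-1 (default 10).
#' @param g Scattering anisotropy in \[0, 1) (default 0.9). The simulation
#'   runs at `mus = mus_ref / (1 - g)`.
#' @param n_photons Photons to launch (default 1e6, minimum 1e4).
#' @param seed Integer seed for the kernel's own RNG; same seed, same records.
#' @param mua Absorption coefficient for the absorbing mode, cm^-1 (default 0).
#' @param l_max Pathlength cutoff, cm (default 200): photons still inside the
#'   medium beyond this carry negligible Beer-Lambert weight at any tissue-like
#'   absorption and are dropped.
#' @param r_max Maximum stored exit displacement, cm; default covers the
#'   detector annulus under the full allowed rescaling range.
#' @param max_scale_factor Largest allowed ratio between `mus_ref` and a
#'   queried scattering value before [reflectance()] refuses to extrapolate
#'   (default 10).
#' @param w_min,p_survive Russian roulette threshold and survival probability
#'   (absorbing mode only).
#' @return A list of class `mc_kernel`.
#' @export
#' @examples
#' k <- simulate_baseline(probe_geometry(), n_photons = 1e4, seed = 1)
#' k$baseline_efficiency
simulate_baseline <- function(geom = probe_geometry(), mus_ref = 10, g = 0.9,
                              n_photons = 1e6, seed = 1, mua = 0,
                              l_max = 200, r_max = NULL,
                              max_scale_factor = 10,
                              w_min = 1e-4, p_survive = 0.1) {
  stopifnot(inherits(geom, "probe_geometry"))
  if (n_photons < 1e4) abort("n_photons must be at least 1e4")
  if (mus_ref <= 0) abort("mus_ref must be positive")
  if (g < 0 || g >= 1) abort("g must lie in [0, 1)")
  sep <- geom$sd_separation / 10           # mm -> cm
  r_f <- geom$fiber_diameter / 20
  if (is.null(r_max)) r_max <- max_scale_factor * (sep + r_f) + 2 * r_f
  mus_total <- mus_ref / (1 - g)
  sim <- mc_run(r_f, geom$numerical_aperture, geom$n_relative, mus_total, g,
                as.integer(n_photons), as.numeric(seed), mua, r_max, l_max,
                w_min, p_survive)
  kernel <- structure(list(
    records = sim$records, n_launched = sim$n_launched,
    n_truncated = sim$n_truncated, mus_ref = mus_ref, g = g, geom = geom,
    seed = seed, mua = mua, l_max = l_max, r_max = r_max,
    max_scale_factor = max_scale_factor, lut = NULL
  ), class = "mc_kernel")
  base <- reflectance_raw(kernel, mua = 0, musp = mus_ref)
  if (base[3, 1] == 0) {
    abort(sprintf(
      "insufficient statistics: no photons collected from %d launched; increase n_photons",
      as.integer(n_photons)
    ), class = "drsquant_mc_error")
  }
  kernel$baseline_efficiency <- base[1, 1]
  kernel
}

#' @export
print.mc_kernel <- function(x, ...) {
  cat("<mc_kernel>", format(x$n_launched, big.mark = ","), "photons launched,",
      nrow(x$records), "exits recorded\n")
  cat("  mus_ref:", x$mus_ref, "cm^-1  g:", x$g, " seed:", x$seed, "\n")
  cat("  probe: d =", x$geom$fiber_diameter, "mm, separation =",
      x$geom$sd_separation, "mm, NA =", x$geom$numerical_aperture, "\n")
  cat("  baseline collection efficiency:",
      format(x$baseline_efficiency, digits = 4),
      if (!is.null(x$lut)) " [lookup table attached]\n" else "\n")
  invisible(x)
}

# raw interface: 3 x n matrix (estimate, MC standard error, capture count)
reflectance_raw <- function(kernel, mua, musp) {
  n <- max(length(mua), length(musp))
  mua <- rep_len(mua, n); musp <- rep_len(musp, n)
  scale <- kernel$mus_ref / musp
  geom <- kernel$geom
  mc_reflectance(kernel$records, kernel$n_launched, mua, scale,
                 geom$sd_separation / 10, geom$fiber_diameter / 20,
                 geom$fiber_diameter / 20,
                 sqrt(1 - geom$numerical_aperture^2))
}

check_scale <- function(kernel, musp) {
  f <- kernel$max_scale_factor
  if (any(musp <= 0)) abort("mus' must be positive", class = "drsquant_domain_error")
  if (any(musp > kernel$mus_ref * f) || any(musp < kernel$mus_ref / f)) {
    abort(sprintf(
      "requested mus' outside the kernel's rescaling range [%g, %g] cm^-1",
      kernel$mus_ref / f, kernel$mus_ref * f
    ), class = "drsquant_scale_error")
  }
}

#' Probe reflectance from the photon kernel
#'
#' Evaluates the modelled probe reflectance for per-wavelength optical
#' properties by similarity rescaling of the white Monte Carlo record set:
#' each photon's pathlength and exit displacement are scaled by
#' `mus_ref / mus(lambda)` (anisotropy held fixed, so equivalently by the
#' ratio of reduced scattering values), detector capture is re-tested against
#' the scaled exit position, and the Beer-Lambert weight `exp(-mua * L)` is
#' applied. The result is the collected fraction of launched photons
#' (dimensionless, per this probe's collection geometry).
#'
#' @param kernel An `mc_kernel` from [simulate_baseline()].
#' @param mua Absorption coefficient(s), cm^-1.
#' @param musp Reduced scattering coefficient(s), cm^-1; recycled against
#'   `mua`.
#' @param method `"exact"` (per-record sum, default) or `"lut"` (interpolated
#'   lookup table, requires [build_lut()]; the fitting path's route).
#' @return Numeric vector of reflectance values with attribute `"se"` holding
#'   per-value Monte Carlo standard errors (`"exact"` method only).
#' @export
reflectance <- function(kernel, mua, musp, method = c("exact", "lut")) {
  stopifnot(inherits(kernel, "mc_kernel"))
  method <- match.arg(method)
  if (any(mua < 0)) abort("mua must be nonnegative", class = "drsquant_domain_error")
  check_scale(kernel, musp)
  if (method == "lut") return(lut_reflectance(kernel, mua, musp))
  out <- reflectance_raw(kernel, mua, musp)
  structure(out[1, ], se = out[2, ])
}

#' Attach a reflectance lookup table to a kernel
#'
#' Precomputes probe reflectance on a (mua, mus') grid from the record set and
#' attaches it to the kernel, so spectral fits evaluate the forward model by
#' bilinear interpolation (log-reflectance, linear in mua and log mus')
#' instead of per-record sums. This is the scaled-Monte-Carlo lookup-table
#' strategy standard in DRS inversion.
#'
#' @param kernel An `mc_kernel`.
#' @param mua_max Largest tabulated absorption, cm^-1 (default 80).
#' @param n_mua,n_musp Grid sizes (defaults 121 and 49).
#' @return The kernel with a `lut` component.
#' @export
build_lut <- function(kernel, mua_max = 80, n_mua = 121, n_musp = 49) {
  stopifnot(inherits(kernel, "mc_kernel"))
  f <- kernel$max_scale_factor
  mua_grid <- seq(0, mua_max, length.out = n_mua)
  musp_grid <- exp(seq(log(kernel$mus_ref / f), log(kernel$mus_ref * f),
                       length.out = n_musp))
  geom <- kernel$geom
  tab <- mc_lut(kernel$records, kernel$n_launched, mua_grid,
                kernel$mus_ref / musp_grid,
                geom$sd_separation / 10, geom$fiber_diameter / 20,
                geom$fiber_diameter / 20,
                sqrt(1 - geom$numerical_aperture^2))
  kernel$lut <- list(mua = mua_grid, musp = musp_grid,
                     log_r = log(pmax(tab, 1e-300)))
  kernel
}

lut_reflectance <- function(kernel, mua, musp) {
  if (is.null(kernel$lut)) abort("kernel has no lookup table; call build_lut() first")
  lut <- kernel$lut
  n <- max(length(mua), length(musp))
  mua <- rep_len(mua, n); musp <- rep_len(musp, n)
  if (any(mua > max(lut$mua))) {
    abort(sprintf("mua beyond tabulated maximum %g cm^-1", max(lut$mua)),
          class = "drsquant_range_error")
  }
  check_scale(kernel, musp)
  fi <- findInterval(mua, lut$mua, rightmost.closed = TRUE)
  fi <- pmin(pmax(fi, 1), length(lut$mua) - 1)
  wa <- (mua - lut$mua[fi]) / (lut$mua[fi + 1] - lut$mua[fi])
  lm_ <- log(musp)
  lg <- log(lut$musp)
  fj <- findInterval(lm_, lg, rightmost.closed = TRUE)
  fj <- pmin(pmax(fj, 1), length(lg) - 1)
  wb <- (lm_ - lg[fj]) / (lg[fj + 1] - lg[fj])
  lr <- lut$log_r
  v <- (1 - wa) * (1 - wb) * lr[cbind(fi, fj)] +
    wa * (1 - wb) * lr[cbind(fi + 1, fj)] +
    (1 - wa) * wb * lr[cbind(fi, fj + 1)] +
    wa * wb * lr[cbind(fi + 1, fj + 1)]
  exp(v)
}

#' Spatially resolved reflectance per unit area from the kernel
#'
#' All-exit-angle estimate of diffuse reflectance per unit area in a thin
#' annulus around radial distance `rho` from the launch point, used to compare
#' the photon kernel against diffusion theory ([diffusion_reflectance()]).
#'
#' @param kernel An `mc_kernel`.
#' @param mua,musp Optical properties, cm^-1 (scalars).
#' @param rho Radial distance, mm.
#' @param drho Annulus width, mm (default 0.2).
#' @return Reflectance per unit area (cm^-2) with attribute `"n"` (records in
#'   the annulus).
#' @export
radial_reflectance <- function(kernel, mua, musp, rho, drho = 0.2) {
  stopifnot(inherits(kernel, "mc_kernel"), length(mua) == 1, length(musp) == 1)
  check_scale(kernel, musp)
  s <- kernel$mus_ref / musp
  r <- kernel$records[, "r_disp"] * s
  rho_cm <- rho / 10; dr <- drho / 10
  sel <- r >= rho_cm - dr / 2 & r < rho_cm + dr / 2
  wt <- kernel$records[sel, "w"] * exp(-mua * kernel$records[sel, "L"] * s)
  structure(sum(wt) / (kernel$n_launched * 2 * pi * rho_cm * dr), n = sum(sel))
}

#' Diffusion-approximation reflectance (closed form)
#'
#' Steady-state diffusion-theory diffuse reflectance per unit area at radial
#' distance `rho` from a point source on a semi-infinite medium, using the
#' standard extrapolated-boundary dipole solution. Valid in the high-albedo,
#' large-distance regime; used in this package only as an independent oracle
#' for the Monte Carlo kernel.
#'
#' @param mua Absorption coefficient, cm^-1, > 0.
#' @param musp Reduced scattering coefficient, cm^-1, > 0.
#' @param rho Source-detector distance, mm, > 0.
#' @param n_relative Refractive index ratio at the boundary (default 1).
#' @return Reflectance per unit area (cm^-2).
#' @export
diffusion_reflectance <- function(mua, musp, rho, n_relative = 1) {
  if (any(rho <= 0)) {
    abort("diffusion theory is invalid at contact (rho must be > 0)",
          class = "drsquant_domain_error")
  }
  if (any(mua <= 0) || any(musp <= 0)) {
    abort("mua and musp must be positive", class = "drsquant_domain_error")
  }
  rho_cm <- rho / 10
  mut <- mua + musp
  D <- 1 / (3 * mut)
  mueff <- sqrt(3 * mua * mut)
  z0 <- 1 / mut
  if (n_relative == 1) {
    A <- 1
  } else {
    rd <- -1.440 / n_relative^2 + 0.710 / n_relative + 0.668 + 0.0636 * n_relative
    A <- (1 + rd) / (1 - rd)
  }
  zb <- 2 * A * D
  r1 <- sqrt(z0^2 + rho_cm^2)
  r2 <- sqrt((z0 + 2 * zb)^2 + rho_cm^2)
  (z0 * (mueff + 1 / r1) * exp(-mueff * r1) / r1^2 +
    (z0 + 2 * zb) * (mueff + 1 / r2) * exp(-mueff * r2) / r2^2) / (4 * pi)
}

#' Synthesize a model reflectance spectrum
#'
#' Convenience wrapper composing the chromophore model and the photon kernel:
#' builds `mua(lambda)` from a hemodynamic state and `mus'(lambda)` from the
#' scattering power law, then queries [reflectance()]. The scattering
#' amplitude is specified through the grid-mean reduced scattering
#' `mean_mus_prime`, i.e. `A = mean_mus_prime / mean(lambda^-b)`.
#'
#' @param kernel An `mc_kernel`.
#' @param lambda Wavelength grid, nm (default 500-600 at 2.5).
#' @param THb,SO2,R_vessel,s_base Absorber parameters (see
#'   [hemodynamic_state()]).
#' @param mean_mus_prime Grid-mean reduced scattering, cm^-1.
#' @param b Scatter power.
#' @param ext,baseline Chromophore tables (defaults: bundled fixtures).
#' @param method Forward evaluation route, `"exact"` or `"lut"`.
#' @return A spectrum tibble (`wavelength`, `value`).
#' @export
#' @examples
#' k <- simulate_baseline(n_photons = 2e4, seed = 7)
#' forward_spectrum(k, THb = 25, SO2 = 0.7, mean_mus_prime = 15, b = 1)
forward_spectrum <- function(kernel, lambda = analysis_grid(),
                             THb, SO2, mean_mus_prime = 15, b = 1,
                             R_vessel = 10, s_base = 0,
                             ext = load_extinction(),
                             baseline = load_baseline_absorption(),
                             method = c("exact", "lut")) {
  method <- match.arg(method)
  state <- hemodynamic_state(THb, SO2, R_vessel, s_base)
  A <- mean_mus_prime / mean(lambda^(-b))
  mua <- mua_total(lambda, state, ext, baseline)
  musp <- mus_prime(lambda, A, b)
  tibble(wavelength = lambda,
         value = as.numeric(reflectance(kernel, mua, musp, method = method)))
}

#' The default spectral analysis grid
#'
#' The closed 500-600 nm grid at 2.5 nm spacing (41 points) on which spectra
#' are resampled and fitted.
#'
#' @param start,stop,step Grid limits and spacing, nm.
#' @return Numeric vector of wavelengths.
#' @export
analysis_grid <- function(start = 500, stop = 600, step = 2.5) {
  seq(start, stop, by = step)
}

#' Save / load a photon kernel
#'
#' Kernels serialize losslessly with their geometry, seed and metadata via
#' R's native serialization; `read_kernel()` verifies the class on load.
#'
#' @param kernel An `mc_kernel`.
#' @param path File path.
#' @return `read_kernel()` returns the kernel; `write_kernel()` its path,
#'   invisibly.
#' @export
write_kernel <- function(kernel, path) {
  stopifnot(inherits(kernel, "mc_kernel"))
  saveRDS(kernel, path)
  invisible(path)
}

#' @rdname write_kernel
#' @export
read_kernel <- function(path) {
  k <- readRDS(path)
  if (!inherits(k, "mc_kernel")) abort("file does not contain an mc_kernel")
  k
}
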