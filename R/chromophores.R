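#' Reduced scattering power law
#'
#' Evaluates the wavelength-dependent reduced scattering coefficient
#' `mus' = A * lambda^-b` (lambda in nm, mus' in cm^-1), the standard
#' power-law approximation for soft tissue in the visible band. `A` is the
#' scattering amplitude and `b` the dimensionless scatter power; larger `b`
#' means a steeper decay with wavelength.
#'
#' @param lambda Wavelengths (nm), all positive.
#' @param A Scattering amplitude (units such that mus' is cm^-1 for lambda in nm).
#' @param b Scatter power (dimensionless, >= 0).
#' @return Numeric vector of mus' (cm^-1).
#' @export
#' @examples
#' mus_prime(c(500, 550, 600), A = 5e5, b = 1.2)
mus_prime <- function(lambda, A, b) {
  if (any(!is.finite(lambda)) || any(lambda <= 0)) {
    abort("wavelengths must be positive and finite", class = "drsquant_domain_error")
  }
  if (A <= 0) abort("scattering amplitude A must be > 0", class = "drsquant_domain_error")
  if (b < 0) abort("scatter power b must be >= 0", class = "drsquant_domain_error")
  A * lambda^(-b)
}

#' Vessel pigment-packing correction factor
#'
#' Hemoglobin in tissue is confined to discrete vessels rather than uniformly
#' dissolved, which flattens strong absorption bands. The correction applied
#' here is the cylindrical-vessel packing factor
#' `C = (1 - exp(-2 mua_bl R)) / (2 mua_bl R)`,
#' where `mua_bl` is the absorption coefficient of the (hemoglobin-bearing)
#' blood compartment and `R` the effective vessel radius. `C -> 1` as
#' `mua_bl * R -> 0` (evaluated analytically, not by division) and decreases
#' monotonically toward 0 as the vessels become optically opaque.
#'
#' @param mua_bl Blood-compartment absorption coefficient(s), cm^-1, >= 0.
#' @param R_vessel Effective vessel radius, micrometers, > 0.
#' @return Correction factor(s) in (0, 1], same length as `mua_bl`.
#' @export
#' @examples
#' packing_factor(c(0, 10, 100), R_vessel = 10)
packing_factor <- function(mua_bl, R_vessel) {
  if (!is.finite(R_vessel) || R_vessel <= 0) {
    abort("R_vessel must be a positive radius in micrometers",
          class = "drsquant_domain_error")
  }
  if (any(mua_bl < 0)) {
    abort("mua_bl must be nonnegative", class = "drsquant_domain_error")
  }
  x <- 2 * mua_bl * (R_vessel * 1e-4)  # dimensionless; radius um -> cm
  out <- rep(1, length(x))
  nz <- x > 0
  # -expm1(-x)/x is accurate down to tiny x; x = 0 handled by the analytic limit
  out[nz] <- -expm1(-x[nz]) / x[nz]
  out
}

#' Hemodynamic state of a tissue volume
#'
#' Bundles the absorber parameters of the tissue model: total hemoglobin
#' `THb` (micromolar), oxygen saturation `SO2` (fraction of hemoglobin bound
#' to oxygen, so `[HbO2] = SO2 * THb` and `[dHb] = (1 - SO2) * THb`), the
#' effective vessel radius for the packing correction, and the scale of the
#' non-hemoglobin baseline absorption.
#'
#' @param THb Total hemoglobin, micromolar, >= 0.
#' @param SO2 Hemoglobin oxygen saturation, in \[0, 1\].
#' @param R_vessel Effective vessel radius, micrometers (default 10).
#' @param s_base Dimensionless baseline absorption scale, >= 0 (default 0).
#' @return A list of class `hemodynamic_state`.
#' @export
hemodynamic_state <- function(THb, SO2, R_vessel = 10, s_base = 0) {
  if (THb < 0) abort("THb must be >= 0", class = "drsquant_domain_error")
  if (SO2 < 0 || SO2 > 1) abort("SO2 must lie in [0, 1]", class = "drsquant_domain_error")
  if (R_vessel <= 0) abort("R_vessel must be > 0", class = "drsquant_domain_error")
  if (s_base < 0) abort("s_base must be >= 0", class = "drsquant_domain_error")
  structure(list(THb = THb, SO2 = SO2, R_vessel = R_vessel, s_base = s_base),
            class = "hemodynamic_state")
}

#' Total tissue absorption coefficient
#'
#' Evaluates the tissue absorption model on a wavelength grid: the
#' Beer-Lambert hemoglobin term
#' `mua_bl = ln(10) * (eps_HbO2 SO2 + eps_dHb (1 - SO2)) * THb * 1e-6`
#' (THb in micromolar), attenuated by the vessel [packing_factor()], plus the
#' scaled non-hemoglobin baseline shape. `mua_bl` here is the tissue-level
#' hemoglobin absorption at the stated concentration, not whole-blood
#' absorption; rescale `R_vessel` accordingly if you prefer the whole-blood
#' convention.
#'
#' @param lambda Wavelengths (nm), within the extinction table's coverage.
#' @param state A [hemodynamic_state()].
#' @param ext An `extinction_table` from [load_extinction()].
#' @param baseline Baseline absorption shape tibble from
#'   [load_baseline_absorption()]; set `NULL` to omit the baseline term.
#' @return Numeric vector of mua (cm^-1), nonnegative.
#' @export
#' @examples
#' ext <- load_extinction()
#' mua_total(seq(500, 600, 2.5), hemodynamic_state(THb = 25, SO2 = 0.7), ext)
mua_total <- function(lambda, state, ext, baseline = load_baseline_absorption()) {
  stopifnot(inherits(state, "hemodynamic_state"))
  e <- extinction_at(ext, lambda)
  mua_bl <- log(10) * (e$eps_HbO2 * state$SO2 + e$eps_dHb * (1 - state$SO2)) *
    state$THb * 1e-6
  hb <- packing_factor(mua_bl, state$R_vessel) * mua_bl
  if (!is.null(baseline) && state$s_base > 0) {
    shape <- interp_strict(baseline$wavelength, baseline$mua_base, lambda,
                           "baseline absorption table")
    hb <- hb + state$s_base * shape
  }
  hb
}
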