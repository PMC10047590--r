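#' Load a hemoglobin molar extinction table
#'
#' Reads a 3-column tab-delimited table (`wavelength_nm`, `eps_HbO2`,
#' `eps_dHb`; molar extinction in cm^-1 M^-1 on a strictly ascending
#' wavelength grid) into the extinction object used by the absorption model.
#' The default is the table bundled with the package, a *synthetic* parametric
#' approximation whose visible band positions and magnitudes match the
#' published hemoglobin values (oxyhemoglobin beta/alpha bands at 542/577 nm,
#' deoxyhemoglobin single visible band near 556 nm) but whose shapes are
#' analytic, not digitized measurements. Substitute a measured compilation of
#' the same format for quantitative work on real spectra.
#'
#' @param path Path to the table. Default: the bundled synthetic table.
#' @return A tibble of class `extinction_table` with columns `wavelength`,
#'   `eps_HbO2`, `eps_dHb`.
#' @export
#' @examples
#' ext <- load_extinction()
#' range(ext$wavelength)
load_extinction <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "hemoglobin_extinction_synthetic.tsv",
                        package = "drsquant", mustWork = TRUE)
  }
  d <- utils::read.table(path, header = TRUE, comment.char = "#")
  if (ncol(d) < 3) abort("extinction table needs 3 columns: wavelength_nm, eps_HbO2, eps_dHb")
  names(d)[1:3] <- c("wavelength", "eps_HbO2", "eps_dHb")
  if (is.unsorted(d$wavelength, strictly = TRUE)) {
    abort("extinction table wavelengths must be strictly ascending")
  }
  if (any(d$eps_HbO2 <= 0) || any(d$eps_dHb <= 0)) {
    abort("extinction values must all be positive")
  }
  out <- as_tibble(d[, c("wavelength", "eps_HbO2", "eps_dHb")])
  class(out) <- c("extinction_table", class(out))
  out
}

#' Load the non-hemoglobin baseline absorption shape
#'
#' Reads the 2-column table holding the non-melanin baseline tissue absorption
#' shape, by default `(lambda/500)^-3.255` cm^-1 — a smooth, featureless decay.
#' At fit time this shape is scaled by the dimensionless parameter `s_base`.
#' Any 2-column table (`wavelength_nm`, `mua_base`) may be substituted.
#'
#' @param path Path to the table. Default: the bundled shape.
#' @return A tibble with columns `wavelength`, `mua_base` (cm^-1).
#' @export
load_baseline_absorption <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "baseline_absorption.tsv",
                        package = "drsquant", mustWork = TRUE)
  }
  d <- utils::read.table(path, header = TRUE, comment.char = "#")
  names(d)[1:2] <- c("wavelength", "mua_base")
  if (is.unsorted(d$wavelength, strictly = TRUE)) {
    abort("baseline table wavelengths must be strictly ascending")
  }
  as_tibble(d[, c("wavelength", "mua_base")])
}

# strict interpolation: queries outside the covered range are an error
interp_strict <- function(x, y, xout, what = "table") {
  if (any(xout < x[1] - 1e-9) || any(xout > x[length(x)] + 1e-9)) {
    abort(sprintf(
      "%s covers %.1f-%.1f nm; requested %.1f-%.1f nm",
      what, x[1], x[length(x)], min(xout), max(xout)
    ), class = "drsquant_range_error")
  }
  approx(x, y, xout = xout, rule = 1)$y
}

#' Interpolate molar extinction onto a wavelength grid
#'
#' Linear interpolation of the oxy- and deoxy-hemoglobin molar extinction onto
#' `lambda`. Wavelengths outside the table's coverage raise an error rather
#' than extrapolating.
#'
#' @param ext An `extinction_table` from [load_extinction()].
#' @param lambda Wavelengths (nm).
#' @return A tibble with columns `wavelength`, `eps_HbO2`, `eps_dHb`.
#' @export
extinction_at <- function(ext, lambda) {
  stopifnot(inherits(ext, "extinction_table"))
  tibble(
    wavelength = lambda,
    eps_HbO2 = interp_strict(ext$wavelength, ext$eps_HbO2, lambda, "extinction table"),
    eps_dHb = interp_strict(ext$wavelength, ext$eps_dHb, lambda, "extinction table")
  )
}
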