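#' Spectra as tibbles
#'
#' Spectra are plain tibbles with a `wavelength` column (nm) and a `value`
#' column. `as_spectrum()` coerces a two-column data frame (taking the first
#' two columns in order) and validates the grid; `read_spectrum()` /
#' `write_spectrum()` exchange the two-column delimited text format
#' (`wavelength_nm`, `value`) used for all on-disk spectra.
#'
#' @param x A data frame whose first two columns are wavelength (nm) and value.
#' @return A tibble with columns `wavelength`, `value`.
#' @export
as_spectrum <- function(x) {
  x <- as.data.frame(x)
  if (ncol(x) < 2) abort("a spectrum needs two columns: wavelength, value")
  out <- tibble(wavelength = as.numeric(x[[1]]), value = as.numeric(x[[2]]))
  if (anyNA(out$wavelength) || is.unsorted(out$wavelength, strictly = TRUE)) {
    abort("spectrum wavelengths must be strictly ascending and non-missing")
  }
  out
}

#' @rdname as_spectrum
#' @param path File path.
#' @export
read_spectrum <- function(path) {
  as_spectrum(utils::read.table(path, header = TRUE, comment.char = "#"))
}

#' @rdname as_spectrum
#' @param spec A spectrum tibble.
#' @export
write_spectrum <- function(spec, path) {
  utils::write.table(
    data.frame(wavelength_nm = spec$wavelength, value = spec$value),
    path, sep = "\t", row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

check_same_grid <- function(a, b, what = "spectra") {
  if (nrow(a) != nrow(b) || any(abs(a$wavelength - b$wavelength) > 1e-9)) {
    abort(paste(what, "are on different wavelength grids"),
          class = "drsquant_alignment_error")
  }
}

#' Subtract a background (shutter-closed) spectrum
#'
#' Elementwise `raw - background` on a shared wavelength grid. Negative
#' results (possible at low signal) are retained, not clipped — clipping
#' would bias low-signal fits — and their count is attached as attribute
#' `"n_negative"`.
#'
#' @param raw,background Spectrum tibbles on the same grid.
#' @return A spectrum tibble.
#' @export
background_subtract <- function(raw, background) {
  check_same_grid(raw, background)
  out <- tibble(wavelength = raw$wavelength, value = raw$value - background$value)
  attr(out, "n_negative") <- sum(out$value < 0)
  out
}

#' Bundle the four calibration channels
#'
#' A calibration set holds the four raw spectra of one self-calibrated
#' acquisition — tissue and reflectance-standard channels, each with its
#' shutter-closed background — plus the standard's known reflectivity
#' (spectrally flat scalar, typical Spectralon 0.99, or a per-wavelength
#' spectrum tibble). Channels on differing grids are resampled to the tissue
#' grid before ratioing.
#'
#' @param tissue_raw,tissue_background,standard_raw,standard_background
#'   Spectrum tibbles.
#' @param standard_reflectivity Scalar in (0, 1] or a spectrum tibble.
#' @return A list of class `calibration_set`.
#' @export
calibration_set <- function(tissue_raw, tissue_background,
                            standard_raw, standard_background,
                            standard_reflectivity = 0.99) {
  specs <- lapply(
    list(tissue_raw = tissue_raw, tissue_background = tissue_background,
         standard_raw = standard_raw, standard_background = standard_background),
    as_spectrum
  )
  grid <- specs$tissue_raw$wavelength
  specs[-1] <- lapply(specs[-1], function(s) {
    if (nrow(s) == length(grid) && all(abs(s$wavelength - grid) < 1e-9)) return(s)
    resample_to_grid(s, grid[1], grid[length(grid)], NULL, grid = grid)
  })
  if (is.numeric(standard_reflectivity) && length(standard_reflectivity) == 1) {
    if (standard_reflectivity <= 0 || standard_reflectivity > 1) {
      abort("standard_reflectivity must lie in (0, 1]")
    }
  } else {
    standard_reflectivity <- as_spectrum(standard_reflectivity)
  }
  structure(c(specs, list(standard_reflectivity = standard_reflectivity)),
            class = "calibration_set")
}

#' Self-calibrate a tissue spectrum against the reflectance standard
#'
#' The self-calibration ratio
#' `R = (tissue_raw - tissue_bg) / (standard_raw - standard_bg) * reflectivity`
#' converts raw counts to diffuse reflectance relative to the spectrally flat
#' standard. Because lamp intensity drift and fiber bending losses multiply
#' both channels equally, they cancel exactly in the ratio — the arithmetic
#' core of real-time self-calibration.
#'
#' @param cs A [calibration_set()].
#' @return A calibrated reflectance spectrum tibble (dimensionless).
#' @export
calibrate <- function(cs) {
  stopifnot(inherits(cs, "calibration_set"))
  tis <- background_subtract(cs$tissue_raw, cs$tissue_background)
  std <- background_subtract(cs$standard_raw, cs$standard_background)
  bad <- std$value <= 0
  if (any(bad)) {
    abort(sprintf(
      "calibration failure: non-positive standard signal at %d wavelength(s): %s nm",
      sum(bad), paste(utils::head(std$wavelength[bad], 5), collapse = ", ")
    ), class = "drsquant_calibration_error")
  }
  refl <- cs$standard_reflectivity
  if (is.data.frame(refl)) {
    refl <- interp_strict(refl$wavelength, refl$value, tis$wavelength,
                          "standard reflectivity table")
  }
  out <- tibble(wavelength = tis$wavelength,
                value = tis$value / std$value * refl)
  attr(out, "n_negative") <- attr(tis, "n_negative")
  out
}

#' Resample a spectrum onto a regular analysis grid
#'
#' Linear interpolation onto the closed grid `start, start + step, ..., stop`
#' (default: the 500-600 nm grid at 2.5 nm, 41 points). The input must cover
#' the requested range; no extrapolation is performed.
#'
#' @param spec A spectrum tibble.
#' @param start,stop,step Grid limits and spacing, nm.
#' @param grid Optional explicit grid (overrides `start`/`stop`/`step`).
#' @return A spectrum tibble on the requested grid.
#' @export
resample_to_grid <- function(spec, start = 500, stop = 600, step = 2.5,
                             grid = NULL) {
  spec <- as_spectrum(spec)
  if (is.null(grid)) grid <- seq(start, stop, by = step)
  tibble(
    wavelength = grid,
    value = interp_strict(spec$wavelength, spec$value, grid, "spectrum")
  )
}
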