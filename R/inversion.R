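#' Fit configuration
#'
#' Settings for the bounded nonlinear least-squares inversion. Parameters are
#' fitted as (THb, SO2, mean mus', b, s_base) — total hemoglobin and
#' saturation directly, so their bounds are physiological, and the scattering
#' amplitude through the grid-mean reduced scattering, so its bounds are in
#' cm^-1. The default bounds on mean mus' (2-70 cm^-1) are pulled in from the
#' kernel's nominal 1-100 cm^-1 rescaling range so that the power-law extremes
#' at the grid edges stay inside it for any `b` in bounds. An optional
#' multiplicative instrument `scale` can be freed for real data; calibrated
#' synthetic spectra are absolute relative to the standard, so it defaults to
#' fixed 1.
#'
#' @param lower,upper Named bounds for `THb` (uM), `SO2`, `mus_mean` (cm^-1),
#'   `b`, `s_base`.
#' @param starts Matrix of documented starting points with columns `THb`,
#'   `SO2` and optionally `b`, `mus_mean`, `s_base` (missing columns start
#'   mid-bounds, `s_base` at 0.01). The default is the 27-point grid
#'   `THb in {10, 30, 80} x SO2 in {0.2, 0.6, 0.9} x b in {0.5, 1.5, 2.5}`:
#'   the oxygenation starts cover the physiological regimes, and the scatter
#'   power starts guard against the shallow trade-off valley between `b`,
#'   the baseline scale and the scattering amplitude.
#' @param fit_scale Free the instrument scale factor? (default `FALSE`).
#' @param R_vessel Effective vessel radius held fixed during fitting, um
#'   (default 10).
#' @param ftol Relative convergence tolerance (default 1e-10).
#' @param maxit Iteration cap per start (default 500).
#' @param method Forward-model route: `"lut"` (default) or `"exact"`.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(lower = c(THb = 0, SO2 = 0, mus_mean = 2, b = 0, s_base = 0),
                       upper = c(THb = 500, SO2 = 1, mus_mean = 70, b = 3, s_base = 5),
                       starts = as.matrix(expand.grid(THb = c(10, 30, 80),
                                                      SO2 = c(0.2, 0.6, 0.9),
                                                      b = c(0.5, 1.5, 2.5))),
                       fit_scale = FALSE, R_vessel = 10,
                       ftol = 1e-10, maxit = 500, method = c("lut", "exact")) {
  structure(list(lower = lower, upper = upper, starts = starts,
                 fit_scale = fit_scale, R_vessel = R_vessel,
                 ftol = ftol, maxit = maxit, method = match.arg(method)),
            class = "fit_config")
}

#' Invert a calibrated reflectance spectrum
#'
#' Fits the measured diffuse reflectance with the Monte Carlo forward model by
#' bounded nonlinear least squares, minimizing
#' `sum_lambda (R_meas - scale * R_model(theta))^2` over
#' `theta = (THb, SO2, mean mus', b, s_base)` from several documented starting
#' points, and returns the extracted hemodynamic and scattering parameters.
#' The absorption model constrains the fit through the known hemoglobin
#' extinction spectra with the vessel packing correction; scattering through
#' the power law `A * lambda^-b`.
#'
#' @param spec Calibrated reflectance spectrum tibble (`wavelength`, `value`),
#'   strictly positive, on a grid inside the extinction table's coverage.
#' @param kernel An `mc_kernel`; a lookup table is built on the fly if the
#'   `"lut"` route is configured and none is attached.
#' @param ext Extinction table (default: bundled fixture).
#' @param baseline Baseline absorption shape (default: bundled fixture).
#' @param config A [fit_config()].
#' @return An object of class `drs_fit`: a list with elements `THb` (uM),
#'   `SO2`, `A`, `b`, `s_base`, `scale`, `mean_mus_prime` (cm^-1, grid mean of
#'   the fitted power law), `residuals`, `rss`, `n_iter`, `converged`, plus
#'   the fitted spectrum. Has [tidy()], [glance()] and `autoplot()` methods.
#' @export
fit_spectrum <- function(spec, kernel, ext = load_extinction(),
                         baseline = load_baseline_absorption(),
                         config = fit_config()) {
  spec <- as.data.frame(spec)
  spec <- as_spectrum(spec[order(spec[[1]]), ])   # objective is order-invariant
  if (any(spec$value <= 0)) {
    abort("measured reflectance must be strictly positive on the fit grid",
          class = "drsquant_input_error")
  }
  if (config$method == "lut" && is.null(kernel$lut)) kernel <- build_lut(kernel)
  lambda <- spec$wavelength
  e <- extinction_at(ext, lambda)
  base_shape <- interp_strict(baseline$wavelength, baseline$mua_base, lambda,
                              "baseline absorption table")
  lam_pow <- function(b) lambda^(-b)
  R_cm <- config$R_vessel * 1e-4

  model_r <- function(th) {
    mua_bl <- log(10) * (e$eps_HbO2 * th[["SO2"]] +
                           e$eps_dHb * (1 - th[["SO2"]])) * th[["THb"]] * 1e-6
    x <- 2 * mua_bl * R_cm
    C <- ifelse(x > 0, -expm1(-x) / pmax(x, 1e-300), 1)
    mua <- C * mua_bl + th[["s_base"]] * base_shape
    lp <- lam_pow(th[["b"]])
    musp <- th[["mus_mean"]] / mean(lp) * lp
    if (config$method == "lut") lut_reflectance(kernel, mua, musp)
    else as.numeric(reflectance(kernel, mua, musp))
  }

  par_names <- c("THb", "SO2", "mus_mean", "b", "s_base")
  lo <- config$lower[par_names]; hi <- config$upper[par_names]
  mid <- c(mus_mean = exp(mean(log(c(lo[["mus_mean"]], hi[["mus_mean"]])))),
           b = mean(c(lo[["b"]], hi[["b"]])))
  if (config$fit_scale) {
    par_names <- c(par_names, "scale")
    lo <- c(lo, scale = 1e-3); hi <- c(hi, scale = 1e3)
  }

  resid_fn <- function(p) {
    p <- setNames(p, par_names)
    sc <- if (config$fit_scale) p[["scale"]] else 1
    spec$value - sc * model_r(p)
  }

  st_default <- c(mus_mean = mid[["mus_mean"]], b = mid[["b"]], s_base = 0.01)
  best <- NULL
  for (i in seq_len(nrow(config$starts))) {
    row <- config$starts[i, ]
    st <- c(THb = row[["THb"]], SO2 = row[["SO2"]],
            mus_mean = if ("mus_mean" %in% names(row)) row[["mus_mean"]] else st_default[["mus_mean"]],
            b = if ("b" %in% names(row)) row[["b"]] else st_default[["b"]],
            s_base = if ("s_base" %in% names(row)) row[["s_base"]] else st_default[["s_base"]])
    if (config$fit_scale) st <- c(st, scale = 1)
    fit <- try(minpack.lm::nls.lm(
      par = pmin(pmax(st, lo), hi), lower = lo, upper = hi, fn = resid_fn,
      control = minpack.lm::nls.lm.control(
        ftol = config$ftol, ptol = config$ftol, maxiter = config$maxit
      )
    ), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) abort("all optimizer starts failed", class = "drsquant_fit_error")

  th <- setNames(best$par, par_names)
  conv <- best$info %in% 1:4 && best$deviance < Inf
  res <- as.numeric(resid_fn(best$par))
  lp <- lam_pow(th[["b"]])
  A <- th[["mus_mean"]] / mean(lp)
  structure(list(
    THb = unname(th[["THb"]]), SO2 = unname(th[["SO2"]]),
    A = unname(A), b = unname(th[["b"]]),
    s_base = unname(th[["s_base"]]),
    scale = if (config$fit_scale) unname(th[["scale"]]) else 1,
    mean_mus_prime = unname(th[["mus_mean"]]),
    residuals = res, rss = sum(res^2),
    n_iter = best$niter, converged = conv,
    spectrum = spec,
    fitted = spec$value - res
  ), class = "drs_fit")
}

#' @export
print.drs_fit <- function(x, ...) {
  cat("<drs_fit>", if (x$converged) "converged" else "NOT converged",
      "in", x$n_iter, "iterations; rss =", format(x$rss, digits = 4), "\n")
  cat(sprintf("  THb = %.2f uM   SO2 = %.3f   mean mus' = %.2f cm^-1   b = %.3f   s_base = %.3f\n",
              x$THb, x$SO2, x$mean_mus_prime, x$b, x$s_base))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a spectral fit
#'
#' @param x A `drs_fit`.
#' @param ... Unused.
#' @return One row per fitted parameter with `term`, `estimate`, `unit`.
#' @export
tidy.drs_fit <- function(x, ...) {
  tibble(
    term = c("THb", "SO2", "mean_mus_prime", "b", "s_base", "scale"),
    estimate = c(x$THb, x$SO2, x$mean_mus_prime, x$b, x$s_base, x$scale),
    unit = c("uM", "fraction", "cm^-1", "", "", "")
  )
}

#' @rdname tidy.drs_fit
#' @export
glance.drs_fit <- function(x, ...) {
  tibble(rss = x$rss, n_lambda = nrow(x$spectrum), n_iter = x$n_iter,
         converged = x$converged)
}

#' Plot a spectral fit
#'
#' Measured and fitted reflectance with a residual panel, the standard visual
#' check of inversion quality.
#'
#' @param object A `drs_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.drs_fit <- function(object, ...) {
  d <- tibble(
    wavelength = rep(object$spectrum$wavelength, 2),
    value = c(object$spectrum$value, object$fitted),
    which = rep(c("measured", "fitted"), each = nrow(object$spectrum))
  )
  r <- tibble(wavelength = object$spectrum$wavelength,
              value = object$residuals, which = "residual")
  ggplot2::ggplot(dplyr::bind_rows(d, r),
                  ggplot2::aes(x = .data$wavelength, y = .data$value,
                               colour = .data$which)) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$which == "residual"),
      scales = "free_y", labeller = ggplot2::as_labeller(
        c("FALSE" = "reflectance", "TRUE" = "residual"))) +
    ggplot2::labs(x = "wavelength (nm)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Fit a batch of labelled spectra into a cohort table
#'
#' Runs [fit_spectrum()] over a tibble of calibrated spectra carrying
#' subject / site / repeat labels and returns the long-format cohort table
#' consumed by the statistics stage. A failed or non-convergent fit does not
#' abort the batch: its row is flagged (`converged = FALSE`, endpoints `NA`
#' on hard failure).
#'
#' @param measurements A tibble with columns `subject`, `site_type`,
#'   `repeat_idx` and a list-column `spectrum` of calibrated spectrum tibbles.
#'   `(subject, site_type, repeat_idx)` keys must be unique.
#' @inheritParams fit_spectrum
#' @return A tibble (one row per measurement) with the labels and `THb`,
#'   `SO2`, `mean_mus_prime`, `b`, `s_base`, `rss`, `converged`.
#' @export
fit_batch <- function(measurements, kernel, ext = load_extinction(),
                      baseline = load_baseline_absorption(),
                      config = fit_config()) {
  need <- c("subject", "site_type", "repeat_idx", "spectrum")
  if (!all(need %in% names(measurements))) {
    abort(paste("measurements must have columns:", paste(need, collapse = ", ")))
  }
  keys <- paste(measurements$subject, measurements$site_type,
                measurements$repeat_idx)
  if (anyDuplicated(keys)) {
    abort(sprintf("duplicate (subject, site_type, repeat_idx) keys: %s",
                  paste(unique(keys[duplicated(keys)]), collapse = "; ")),
          class = "drsquant_integrity_error")
  }
  if (config$method == "lut" && is.null(kernel$lut)) kernel <- build_lut(kernel)
  rows <- purrr::map(measurements$spectrum, function(s) {
    f <- try(fit_spectrum(s, kernel, ext, baseline, config), silent = TRUE)
    if (inherits(f, "try-error")) {
      return(tibble(THb = NA_real_, SO2 = NA_real_, mean_mus_prime = NA_real_,
                    b = NA_real_, s_base = NA_real_, rss = NA_real_,
                    converged = FALSE))
    }
    tibble(THb = f$THb, SO2 = f$SO2, mean_mus_prime = f$mean_mus_prime,
           b = f$b, s_base = f$s_base, rss = f$rss, converged = f$converged)
  })
  dplyr::bind_cols(
    measurements[, c("subject", "site_type", "repeat_idx")],
    dplyr::bind_rows(rows)
  )
}
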