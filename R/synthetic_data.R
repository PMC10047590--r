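# run code with a local, restored RNG state
with_local_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Synthetic cohort configuration
#'
#' Parameters of the synthetic study generator, which emulates a
#' repeated-measures optical biopsy design: 19 subjects of whom 12 contribute
#' a cancer site, 14 a distant-normal site and 1 a benign site (subjects may
#' contribute more than one site, so site counts exceed the subject count),
#' with 5 repeated measurements per site. Endpoint distributions are generator
#' choices that reproduce the qualitative contrasts the analysis expects —
#' markedly lower cancer-site oxygen saturation, no group difference in total
#' hemoglobin or scattering, and no repeat-number trend — they are not values
#' taken from any measured cohort.
#'
#' @param n_subjects,n_cancer_subjects,n_normal_subjects,n_benign_subjects
#'   Study-design counts (defaults 19, 12, 14, 1).
#' @param repeats_per_site Repeated measurements per site (default 5).
#' @param so2_mean Named per-site-type means of true SO2
#'   (defaults: normal 0.70, cancer 0.35, benign 0.70).
#' @param so2_sd Named per-site-type SDs of site-level SO2 (defaults 0.10,
#'   0.12, 0.10). Between-site variation is carried entirely at the subject
#'   level — a subject's sites share one standardized random effect per
#'   endpoint, scaled by these SDs — so the generated variance structure
#'   (subject + repeat) matches the subject-random-intercept analysis model.
#' @param so2_repeat_sd Repeat-to-repeat SO2 jitter SD (default 0.02).
#' @param thb_log_median,thb_log_gsd Total hemoglobin site distribution:
#'   log-normal with median 25 uM, geometric SD 1.6, identical across groups.
#' @param thb_repeat_cv Repeat-level multiplicative jitter on THb (default 0.03).
#' @param mus_range Mean mus' range, cm^-1 (default 5-25; subject-level draw).
#' @param b_range Site-level scatter power range (default 0.5-1.5).
#' @param mus_repeat_cv Repeat-level multiplicative jitter on mus' (default 0.02).
#' @param s_base_range Site-level baseline absorption scale range (default 0-0.2).
#' @param trend Named per-endpoint additive trend per repeat index (defaults
#'   all 0: the design assumes pressure gating removes time effects).
#' @param noise_mult_sd Multiplicative Gaussian noise SD on raw channels
#'   (default 0.01, i.e. 1 percent).
#' @param noise_add_frac Additive Gaussian noise SD as a fraction of each
#'   channel's own mean signal level above background (default 0.001); the
#'   two channels carry very different absolute count levels, so a common
#'   anchor would drown the weaker one.
#' @param drift_amp,drift_tilt Ranges of the lamp-drift draw: each
#'   measurement's channels are multiplied by `d0 * (1 + d1 (lambda - 550)/100)`
#'   with `d0 ~ U(drift_amp)`, `d1 ~ U(drift_tilt)`; the calibration ratio
#'   cancels it.
#' @param standard_reflectivity Spectralon reflectivity (default 0.99).
#' @param seed Integer seed; every draw is reproducible from it.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 19, n_cancer_subjects = 12,
                          n_normal_subjects = 14, n_benign_subjects = 1,
                          repeats_per_site = 5,
                          so2_mean = c(normal = 0.70, cancer = 0.35, benign = 0.70),
                          so2_sd = c(normal = 0.10, cancer = 0.12, benign = 0.10),
                          so2_repeat_sd = 0.02,
                          thb_log_median = 25, thb_log_gsd = 1.6,
                          thb_repeat_cv = 0.03,
                          mus_range = c(5, 25), b_range = c(0.5, 1.5),
                          mus_repeat_cv = 0.02, s_base_range = c(0, 0.2),
                          trend = c(SO2 = 0, THb = 0, mean_mus_prime = 0),
                          noise_mult_sd = 0.01, noise_add_frac = 0.001,
                          drift_amp = c(0.8, 1.2), drift_tilt = c(-0.05, 0.05),
                          standard_reflectivity = 0.99, seed = 1) {
  if (any(so2_mean <= 0) || any(so2_mean >= 1)) {
    abort("SO2 means must lie strictly inside (0, 1)", class = "drsquant_config_error")
  }
  if (repeats_per_site < 1) abort("repeats_per_site must be >= 1")
  if (n_cancer_subjects > n_subjects || n_normal_subjects > n_subjects) {
    abort("per-site-type subject counts cannot exceed n_subjects")
  }
  structure(as.list(environment()), class = "cohort_config")
}

# draw site/repeat-level ground-truth endpoint records
#
# All between-site variation of the endpoints is carried at the subject level
# (a subject's sites share one standardized random effect per endpoint,
# scaled by the site-type SD), so the repeated-measures structure matches the
# subject-random-intercept analysis model: variance = subject + repeat.
draw_truth <- function(cfg) {
  subjects <- sprintf("S%02d", seq_len(cfg$n_subjects))
  sites <- dplyr::bind_rows(
    tibble(subject = subjects[seq_len(cfg$n_cancer_subjects)], site_type = "cancer"),
    tibble(subject = subjects[seq(cfg$n_subjects - cfg$n_normal_subjects + 1,
                                  cfg$n_subjects)], site_type = "normal"),
    tibble(subject = subjects[seq_len(cfg$n_benign_subjects)], site_type = "benign")
  )
  z_so2 <- setNames(rnorm(cfg$n_subjects), subjects)
  z_thb <- setNames(rnorm(cfg$n_subjects), subjects)
  z_mus <- setNames(runif(cfg$n_subjects), subjects)

  sites$so2_site <- cfg$so2_mean[sites$site_type] +
    cfg$so2_sd[sites$site_type] * z_so2[sites$subject]
  sites$thb_site <- exp(log(cfg$thb_log_median) +
                          log(cfg$thb_log_gsd) * z_thb[sites$subject])
  sites$mus_site <- cfg$mus_range[1] +
    diff(cfg$mus_range) * z_mus[sites$subject]
  sites$b <- runif(nrow(sites), cfg$b_range[1], cfg$b_range[2])
  sites$s_base <- runif(nrow(sites), cfg$s_base_range[1], cfg$s_base_range[2])

  reps <- tidyr::expand_grid(sites, repeat_idx = seq_len(cfg$repeats_per_site))
  n <- nrow(reps)
  reps$SO2 <- pmin(pmax(
    reps$so2_site + cfg$trend[["SO2"]] * (reps$repeat_idx - 1) +
      rnorm(n, 0, cfg$so2_repeat_sd), 0.02), 0.98)
  reps$THb <- pmax(
    reps$thb_site * exp(rnorm(n, 0, cfg$thb_repeat_cv)) +
      cfg$trend[["THb"]] * (reps$repeat_idx - 1), 0.5)
  reps$mean_mus_prime <- pmax(
    reps$mus_site * exp(rnorm(n, 0, cfg$mus_repeat_cv)) +
      cfg$trend[["mean_mus_prime"]] * (reps$repeat_idx - 1), 1)
  reps[, c("subject", "site_type", "repeat_idx",
           "THb", "SO2", "mean_mus_prime", "b", "s_base")]
}

#' Generate a synthetic study cohort
#'
#' Draws ground-truth endpoint records for every (subject, site, repeat)
#' measurement of the configured design and — when `spectra = TRUE` —
#' synthesizes the full raw-data package for each measurement: a noiseless
#' true reflectance spectrum from the photon kernel, inverted through the
#' calibration arithmetic into four raw channels (tissue/standard, each with
#' background) under a sampled lamp-drift curve with measurement noise, plus
#' a contact-pressure trace constructed to pass the gate. The ground truth is
#' returned separately and is never consumed by the fitting path.
#'
#' @param cfg A [cohort_config()].
#' @param spectra Generate raw channel spectra and pressure traces? If
#'   `FALSE` (default) only endpoint records are produced, which is what the
#'   statistics-stage simulations consume.
#' @param kernel An `mc_kernel`; required when `spectra = TRUE`.
#' @param lambda Generation wavelength grid, nm (default 495-605 at 1 nm, so
#'   the analysis grid lies strictly inside it).
#' @return A list of class `drs_cohort`: `truth` (ground-truth records),
#'   `endpoints` (observed endpoint table, equal to the truth endpoints in
#'   endpoint-only mode), and with `spectra = TRUE` also `measurements`, a
#'   tibble with list-columns `calibration` ([calibration_set()] per
#'   measurement) and `pressure` (trace per measurement).
#' @export
#' @examples
#' coh <- generate_cohort(cohort_config(seed = 42))
#' head(coh$endpoints)
generate_cohort <- function(cfg = cohort_config(), spectra = FALSE,
                            kernel = NULL, lambda = seq(495, 605, by = 1)) {
  stopifnot(inherits(cfg, "cohort_config"))
  if (spectra && is.null(kernel)) abort("spectra generation needs a photon kernel")
  out <- with_local_seed(cfg$seed, {
    truth <- draw_truth(cfg)
    res <- list(
      truth = truth,
      endpoints = truth[, c("subject", "site_type", "repeat_idx",
                            "THb", "SO2", "mean_mus_prime")]
    )
    if (spectra) {
      ext <- load_extinction(); basl <- load_baseline_absorption()
      lamp <- 4000 * (lambda / 550)^2        # smooth halogen-like shape, counts
      bg_level <- 50
      method <- if (!is.null(kernel$lut)) "lut" else "exact"
      ms <- purrr::pmap(truth, function(subject, site_type, repeat_idx,
                                        THb, SO2, mean_mus_prime, b, s_base) {
        r_true <- forward_spectrum(kernel, lambda, THb = THb, SO2 = SO2,
                                   mean_mus_prime = mean_mus_prime, b = b,
                                   s_base = s_base, ext = ext, baseline = basl,
                                   method = method)$value
        d0 <- runif(1, cfg$drift_amp[1], cfg$drift_amp[2])
        d1 <- runif(1, cfg$drift_tilt[1], cfg$drift_tilt[2])
        drift <- d0 * (1 + d1 * (lambda - 550) / 100)
        std_sig <- lamp * drift
        tis_sig <- r_true / cfg$standard_reflectivity * std_sig
        noisy <- function(sig) {
          sig * (1 + rnorm(length(sig), 0, cfg$noise_mult_sd)) +
            rnorm(length(sig), 0, cfg$noise_add_frac * mean(sig)) + bg_level
        }
        cs <- calibration_set(
          tissue_raw = tibble(wavelength = lambda, value = noisy(tis_sig)),
          tissue_background = tibble(wavelength = lambda, value = rep(bg_level, length(lambda))),
          standard_raw = tibble(wavelength = lambda, value = noisy(std_sig)),
          standard_background = tibble(wavelength = lambda, value = rep(bg_level, length(lambda))),
          standard_reflectivity = cfg$standard_reflectivity
        )
        pt <- make_pressure_trace("noisy-hold", seed = sample.int(2^30, 1))
        list(calibration = cs, pressure = pt)
      })
      res$measurements <- dplyr::bind_cols(
        truth[, c("subject", "site_type", "repeat_idx")],
        tibble(calibration = purrr::map(ms, "calibration"),
               pressure = purrr::map(ms, "pressure"))
      )
    }
    res
  })
  structure(c(out, list(config = cfg)), class = "drs_cohort")
}

#' @export
print.drs_cohort <- function(x, ...) {
  cat("<drs_cohort>", nrow(x$truth), "measurements:",
      length(unique(x$truth$subject)), "subjects,",
      nrow(unique(x$truth[, c("subject", "site_type")])), "sites,",
      x$config$repeats_per_site, "repeats/site\n")
  if (!is.null(x$measurements)) cat("  raw channel spectra + pressure traces attached\n")
  invisible(x)
}

#' Generate a synthetic contact-pressure trace
#'
#' Three deterministic-from-seed families for exercising the measurement
#' gate: `"ramp-hold"` ramps up and settles mid-window; `"noisy-hold"` holds
#' mid-window with Gaussian jitter; `"overshoot"` exceeds the upper window
#' bound before settling in-window, so a correctly configured gate triggers
#' only after the overshoot.
#'
#' @param family One of `"ramp-hold"`, `"noisy-hold"`, `"overshoot"`.
#' @param duration Trace length, s (default 6).
#' @param rate Sampling rate, Hz (default 10).
#' @param target Hold pressure, mmHg (default 48, mid-window).
#' @param noise_sd Jitter SD for `"noisy-hold"`, mmHg (default 3).
#' @param peak Overshoot peak, mmHg (default 90).
#' @param seed Integer seed.
#' @return A tibble with columns `time`, `pressure`.
#' @export
make_pressure_trace <- function(family = c("ramp-hold", "noisy-hold", "overshoot"),
                                duration = 6, rate = 10, target = 48,
                                noise_sd = 3, peak = 90, seed = 1) {
  if (is.character(family) && length(family) == 1 &&
      !family %in% c("ramp-hold", "noisy-hold", "overshoot")) {
    abort(paste("unknown pressure-trace family:", family),
          class = "drsquant_config_error")
  }
  family <- match.arg(family)
  tm <- seq(0, duration, by = 1 / rate)
  with_local_seed(seed, {
    pr <- switch(family,
      "ramp-hold" = pmin(target, target * tm / 1.5) + rnorm(length(tm), 0, 0.3),
      "noisy-hold" = target + rnorm(length(tm), 0, noise_sd),
      "overshoot" = {
        # fast rise (crosses the window in < dwell), overshoot plateau, settle
        p <- ifelse(tm < 0.5, peak * tm / 0.5,
                    ifelse(tm < 1.5, peak,
                           ifelse(tm < 2, peak + (target - peak) * (tm - 1.5) / 0.5,
                                  target)))
        p + rnorm(length(tm), 0, 0.3)
      }
    )
    tibble(time = tm, pressure = pmax(pr, 0))
  })
}
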