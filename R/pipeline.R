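#' Repeat-difference table
#'
#' For every site, subtracts the first repeat's endpoint value from each
#' repeat, giving the change relative to the initial probe placement. Under a
#' stable, non-perturbing measurement the per-repeat median difference is
#' expected to sit at zero.
#'
#' @param table Cohort tibble with `subject`, `site_type`, `repeat_idx` and
#'   endpoint columns.
#' @param endpoints Endpoint column names (default `SO2`, `THb`,
#'   `mean_mus_prime`, intersected with what is present).
#' @return A long tibble: `subject`, `site_type`, `repeat_idx`, `endpoint`,
#'   `difference`.
#' @export
repeat_differences <- function(table,
                               endpoints = c("SO2", "THb", "mean_mus_prime")) {
  endpoints <- intersect(endpoints, names(table))
  table %>%
    dplyr::select(dplyr::all_of(c("subject", "site_type", "repeat_idx", endpoints))) %>%
    tidyr::pivot_longer(dplyr::all_of(endpoints), names_to = "endpoint",
                        values_to = "value") %>%
    dplyr::group_by(.data$subject, .data$site_type, .data$endpoint) %>%
    dplyr::arrange(.data$repeat_idx, .by_group = TRUE) %>%
    dplyr::mutate(difference = .data$value - .data$value[.data$repeat_idx == 1][1]) %>%
    dplyr::ungroup() %>%
    dplyr::select(-"value")
}

#' Group summary statistics of cohort endpoints
#'
#' Median and quartiles of each endpoint by the two-group diagnosis factor —
#' the box-plot statistics of the group comparison.
#'
#' @inheritParams repeat_differences
#' @return A tibble with `group`, `endpoint`, `n`, `median`, `q1`, `q3`.
#' @export
group_summary <- function(table, endpoints = c("SO2", "THb", "mean_mus_prime")) {
  endpoints <- intersect(endpoints, names(table))
  add_group(table) %>%
    tidyr::pivot_longer(dplyr::all_of(endpoints), names_to = "endpoint",
                        values_to = "value") %>%
    dplyr::group_by(.data$group, .data$endpoint) %>%
    dplyr::summarise(
      n = dplyr::n(),
      median = stats::median(.data$value, na.rm = TRUE),
      q1 = stats::quantile(.data$value, 0.25, na.rm = TRUE, names = FALSE),
      q3 = stats::quantile(.data$value, 0.75, na.rm = TRUE, names = FALSE),
      .groups = "drop"
    )
}

#' Run the full synthetic analysis pipeline
#'
#' Orchestrates simulate -> gate -> calibrate -> fit -> compare as one
#' reproducible run: generates a synthetic cohort with raw channels and
#' pressure traces, keeps only measurements whose pressure trace triggers the
#' gate, applies the self-calibration ratio and resamples to the analysis
#' grid, inverts every spectrum, and runs the mixed-effects and ANOVA
#' comparisons on the extracted endpoints. The run is a pure function of
#' (configuration, seeds, kernel).
#'
#' @param cohort A [cohort_config()].
#' @param kernel An `mc_kernel` (a lookup table is attached if missing).
#' @param grid Analysis grid, nm (default [analysis_grid()]).
#' @param p_min,p_max,dwell Pressure-gate settings (defaults 24, 72, 0.5).
#' @param fit A [fit_config()].
#' @param endpoints Endpoints to compare.
#' @return An object of class `drs_run`: `cohort_table` (fitted endpoints per
#'   measurement), `group_summary`, `repeat_diff`, `lmm` (per-endpoint
#'   [fit_lmm()] results), `anova` (per-endpoint [anova_groups()] rows),
#'   `n_gated_out`, and `provenance` (seeds and kernel metadata).
#' @export
run_pipeline <- function(cohort = cohort_config(), kernel,
                         grid = analysis_grid(),
                         p_min = 24, p_max = 72, dwell = 0.5,
                         fit = fit_config(),
                         endpoints = c("SO2", "THb", "mean_mus_prime")) {
  stopifnot(inherits(kernel, "mc_kernel"))
  if (fit$method == "lut" && is.null(kernel$lut)) kernel <- build_lut(kernel)
  coh <- generate_cohort(cohort, spectra = TRUE, kernel = kernel)

  gated <- vapply(coh$measurements$pressure, function(tr) {
    nrow(gate_trace(tr, p_min = p_min, p_max = p_max, dwell = dwell)) > 0
  }, logical(1))
  meas <- coh$measurements[gated, ]

  meas$spectrum <- purrr::map(meas$calibration, function(cs) {
    resample_to_grid(calibrate(cs), grid = grid)
  })
  cohort_table <- fit_batch(meas, kernel, config = fit)

  lmm <- lapply(setNames(endpoints, endpoints), function(ep) {
    fit_lmm(cohort_table, ep, fixed = c("group", "repeat_idx"))
  })
  anova_tbl <- dplyr::bind_rows(lapply(endpoints, function(ep) {
    dplyr::mutate(anova_groups(cohort_table, ep), endpoint = ep, .before = 1)
  }))

  structure(list(
    cohort_table = cohort_table,
    group_summary = group_summary(cohort_table, endpoints),
    repeat_diff = repeat_differences(cohort_table, endpoints),
    lmm = lmm, anova = anova_tbl,
    n_gated_out = sum(!gated),
    provenance = list(
      cohort_seed = cohort$seed, kernel_seed = kernel$seed,
      kernel_n_launched = kernel$n_launched, mus_ref = kernel$mus_ref,
      g = kernel$g, geometry = kernel$geom, grid = grid,
      gate = c(p_min = p_min, p_max = p_max, dwell = dwell)
    )
  ), class = "drs_run")
}

#' @export
print.drs_run <- function(x, ...) {
  cat("<drs_run>", nrow(x$cohort_table), "measurements fitted;",
      x$n_gated_out, "rejected by the pressure gate\n\n")
  cat("Group summaries (median [q1, q3]):\n")
  gs <- x$group_summary
  for (i in seq_len(nrow(gs))) {
    cat(sprintf("  %-15s %-10s %8.3f [%8.3f, %8.3f]\n", gs$endpoint[i],
                as.character(gs$group[i]), gs$median[i], gs$q1[i], gs$q3[i]))
  }
  cat("\nMixed-effects p-values (Wald):\n")
  for (ep in names(x$lmm)) {
    p <- x$lmm[[ep]]$p_values
    gi <- grep("^group", names(p)); ri <- grep("repeat_idx", names(p))
    cat(sprintf("  %-15s group: p = %-10.3g repeat: p = %.3g\n", ep,
                if (length(gi)) p[gi[1]] else NA, if (length(ri)) p[ri[1]] else NA))
  }
  invisible(x)
}

#' Box plots of cohort endpoints by diagnosis group
#'
#' @param table Cohort tibble.
#' @param endpoints Endpoint columns to show.
#' @return A ggplot object.
#' @export
plot_cohort_endpoints <- function(table,
                                  endpoints = c("THb", "mean_mus_prime", "SO2")) {
  endpoints <- intersect(endpoints, names(table))
  d <- add_group(table) %>%
    tidyr::pivot_longer(dplyr::all_of(endpoints), names_to = "endpoint",
                        values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$value,
                                  fill = .data$group)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::facet_wrap(~endpoint, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Box plots of repeat differences against the first measurement
#'
#' @param repeat_diff Output of [repeat_differences()].
#' @return A ggplot object.
#' @export
plot_repeat_differences <- function(repeat_diff) {
  ggplot2::ggplot(repeat_diff,
                  ggplot2::aes(x = factor(.data$repeat_idx), y = .data$difference)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(~endpoint, scales = "free_y") +
    ggplot2::labs(x = "repeat number", y = "difference vs first measurement") +
    ggplot2::theme_minimal()
}
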