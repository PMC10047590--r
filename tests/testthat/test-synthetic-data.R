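test_that("cohort generation reproduces the study design arithmetic", {
  coh <- generate_cohort(cohort_config(seed = 1))
  truth <- coh$truth
  sites <- unique(truth[, c("subject", "site_type")])
  expect_identical(nrow(sites), 12L + 14L + 1L)
  expect_identical(sum(sites$site_type == "cancer"), 12L)
  expect_identical(sum(sites$site_type == "normal"), 14L)
  expect_identical(sum(sites$site_type == "benign"), 1L)
  expect_identical(length(unique(truth$subject)), 19L)
  expect_identical(nrow(truth), 27L * 5L)
  # repeats contiguous from 1 within each site
  reps <- tapply(truth$repeat_idx, paste(truth$subject, truth$site_type),
                 function(r) identical(sort(r), 1:5))
  expect_true(all(reps))
  # endpoints join 1:1 with the truth
  expect_identical(truth[, 1:3], coh$endpoints[, 1:3])
})

test_that("the generator is bit-reproducible from its seed", {
  a <- generate_cohort(cohort_config(seed = 123))
  b <- generate_cohort(cohort_config(seed = 123))
  expect_identical(a$truth, b$truth)
  k <- test_kernel_small()
  c1 <- generate_cohort(cohort_config(n_subjects = 3, n_cancer_subjects = 2,
                                      n_normal_subjects = 2, repeats_per_site = 2,
                                      seed = 11), spectra = TRUE, kernel = k)
  c2 <- generate_cohort(cohort_config(n_subjects = 3, n_cancer_subjects = 2,
                                      n_normal_subjects = 2, repeats_per_site = 2,
                                      seed = 11), spectra = TRUE, kernel = k)
  expect_identical(c1$measurements$calibration, c2$measurements$calibration)
  expect_identical(c1$measurements$pressure, c2$measurements$pressure)
})

test_that("noise-free channels invert the calibration arithmetic exactly", {
  k <- test_kernel_small()
  cfg <- cohort_config(n_subjects = 3, n_cancer_subjects = 2, n_normal_subjects = 2,
                       repeats_per_site = 2, noise_mult_sd = 0, noise_add_frac = 0,
                       seed = 21)
  coh <- generate_cohort(cfg, spectra = TRUE, kernel = k)
  lam <- seq(495, 605, by = 1)
  for (i in seq_len(nrow(coh$measurements))) {
    r_cal <- calibrate(coh$measurements$calibration[[i]])
    tr <- coh$truth[i, ]
    r_true <- forward_spectrum(k, lam, THb = tr$THb, SO2 = tr$SO2,
                               mean_mus_prime = tr$mean_mus_prime, b = tr$b,
                               s_base = tr$s_base, method = "lut")
    expect_equal(r_cal$value, r_true$value, tolerance = 1e-12)
  }
})

test_that("generated cancer sites carry lower oxygen saturation than normal sites", {
  truth <- generate_cohort(cohort_config(seed = 31))$truth
  m <- tapply(truth$SO2, truth$site_type, mean)
  expect_lt(m[["cancer"]], m[["normal"]] - 0.15)
  # and no engineered group difference in total hemoglobin
  thb <- tapply(log(truth$THb), truth$site_type, mean)
  expect_lt(abs(thb[["cancer"]] - thb[["normal"]]), 0.5)
})

test_that("noiseless spectra show the oxy/deoxy band structure", {
  k <- test_kernel()
  lam <- analysis_grid()
  oxy <- forward_spectrum(k, lam, THb = 30, SO2 = 0.95, mean_mus_prime = 15, b = 1)
  mins_oxy <- lam[local_minima(oxy$value)]
  expect_length(mins_oxy[mins_oxy >= 530 & mins_oxy <= 590], 2)
  deoxy <- forward_spectrum(k, lam, THb = 30, SO2 = 0, mean_mus_prime = 15, b = 1)
  mins_deoxy <- lam[local_minima(deoxy$value)]
  expect_length(mins_deoxy, 1)
  expect_true(mins_deoxy >= 540 && mins_deoxy <= 570)
})

test_that("pressure trace families drive the gate as designed", {
  ramp <- make_pressure_trace("ramp-hold", seed = 2)
  iv <- gate_trace(ramp)
  expect_gte(nrow(iv), 1)
  over <- make_pressure_trace("overshoot", seed = 3)
  iv2 <- gate_trace(over)
  expect_identical(nrow(iv2), 1L)
  expect_gte(iv2$start, 1.5)   # trigger only after the overshoot settles
  expect_lt(max(gate_flags(over)$pressure), 95)
  split <- make_pressure_trace("noisy-hold", noise_sd = 25, seed = 4)
  expect_gt(nrow(gate_trace(split, dwell = 0.3)), 1)
  expect_error(make_pressure_trace("banana"), class = "drsquant_config_error")
  expect_identical(make_pressure_trace("noisy-hold", seed = 8),
                   make_pressure_trace("noisy-hold", seed = 8))
})

test_that("config validation rejects impossible settings", {
  expect_error(cohort_config(so2_mean = c(normal = 1.2, cancer = 0.3, benign = 0.7)),
               class = "drsquant_config_error")
  expect_error(cohort_config(n_cancer_subjects = 25))
  expect_error(cohort_config(repeats_per_site = 0))
})
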