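test_that("noiseless self-consistent spectra are recovered to tight tolerances", {
  k <- test_kernel()
  cases <- list(c(THb = 20, SO2 = 0.30, mus = 10, b = 0.8, sb = 0.05),
                c(THb = 45, SO2 = 0.85, mus = 18, b = 1.3, sb = 0.10))
  for (th in cases) {
    s <- forward_spectrum(k, THb = th[["THb"]], SO2 = th[["SO2"]],
                          mean_mus_prime = th[["mus"]], b = th[["b"]],
                          s_base = th[["sb"]], method = "lut")
    f <- fit_spectrum(s, k)
    expect_true(f$converged)
    expect_lt(abs(f$SO2 - th[["SO2"]]), 0.02)
    expect_lt(abs(f$THb / th[["THb"]] - 1), 0.05)
    expect_lt(abs(f$b / th[["b"]] - 1), 0.10)
    # residuals vanish in relative terms for a self-generated spectrum
    expect_lt(max(abs(f$residuals) / s$value), 1e-6)
    # reported mean mus' is consistent with the fitted power law
    lam <- s$wavelength
    expect_equal(f$mean_mus_prime, mean(mus_prime(lam, f$A, f$b)), tolerance = 1e-8)
  }
})

test_that("a fully oxygenated spectrum fits with both oxyhemoglobin bands", {
  k <- test_kernel()
  s <- forward_spectrum(k, THb = 30, SO2 = 1, mean_mus_prime = 15, b = 1,
                        method = "lut")
  f <- fit_spectrum(s, k)
  expect_gte(f$SO2, 0.95)
  mins <- s$wavelength[local_minima(f$fitted)]
  mins <- mins[mins >= 530 & mins <= 590]
  expect_length(mins, 2)
})

test_that("the objective is invariant to wavelength ordering of the input", {
  k <- test_kernel()
  s <- forward_spectrum(k, THb = 35, SO2 = 0.6, mean_mus_prime = 12, b = 1.1,
                        method = "lut")
  set.seed(5)
  perm <- s[sample(nrow(s)), ]
  f1 <- fit_spectrum(s, k)
  f2 <- fit_spectrum(perm, k)
  expect_equal(tidy(f1), tidy(f2))
})

test_that("a constant instrument factor is absorbed by the scale parameter", {
  k <- test_kernel()
  s <- forward_spectrum(k, THb = 30, SO2 = 0.7, mean_mus_prime = 14, b = 1,
                        method = "lut")
  cfg <- fit_config(fit_scale = TRUE)
  f1 <- fit_spectrum(s, k, config = cfg)
  s2 <- s; s2$value <- 2.5 * s$value
  f2 <- fit_spectrum(s2, k, config = cfg)
  expect_equal(f2$scale / f1$scale, 2.5, tolerance = 0.01)
  expect_equal(f2$SO2, f1$SO2, tolerance = 0.01)
  expect_equal(f2$THb, f1$THb, tolerance = 0.02 * f1$THb)
  expect_equal(f2$b, f1$b, tolerance = 0.05)
})

test_that("the returned minimum beats every documented starting point", {
  k <- test_kernel()
  s <- forward_spectrum(k, THb = 25, SO2 = 0.5, mean_mus_prime = 16, b = 1.2,
                        method = "lut")
  f <- fit_spectrum(s, k)
  cfg <- fit_config()
  mid_mus <- exp(mean(log(c(cfg$lower[["mus_mean"]], cfg$upper[["mus_mean"]]))))
  for (i in seq_len(nrow(cfg$starts))) {
    st <- cfg$starts[i, ]
    r0 <- forward_spectrum(k, s$wavelength, THb = st[["THb"]], SO2 = st[["SO2"]],
                           mean_mus_prime = mid_mus, b = st[["b"]],
                           s_base = 0.01, method = "lut")
    expect_lte(f$rss, sum((s$value - r0$value)^2))
  }
})

test_that("invalid spectra are rejected", {
  k <- test_kernel_small()
  s <- forward_spectrum(k, THb = 30, SO2 = 0.7, method = "lut")
  s$value[3] <- -1e-5
  expect_error(fit_spectrum(s, k), class = "drsquant_input_error")
})

test_that("batch fitting enforces keys, isolates failures, and is deterministic", {
  k <- test_kernel()
  s <- forward_spectrum(k, THb = 30, SO2 = 0.7, mean_mus_prime = 14, b = 1,
                        method = "lut")
  meas <- tibble::tibble(
    subject = "S01", site_type = "normal", repeat_idx = 1:3,
    spectrum = list(s, s, s)
  )
  out <- fit_batch(meas, k)
  expect_identical(nrow(out), 3L)
  # identical inputs give identical rows
  expect_identical(out$SO2[1], out$SO2[2])
  expect_identical(out$THb[2], out$THb[3])

  dup <- meas; dup$repeat_idx <- c(1, 1, 2)
  expect_error(fit_batch(dup, k), class = "drsquant_integrity_error")

  bad <- meas
  bad$spectrum[[2]]$value[1] <- -1   # unfittable spectrum
  got <- fit_batch(bad, k)
  expect_false(got$converged[2])
  expect_true(is.na(got$SO2[2]))
  expect_true(all(got$converged[c(1, 3)]))
})
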