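test_that("scattering power law evaluates Eq-style A * lambda^-b", {
  expect_equal(mus_prime(c(500, 550, 600), A = 1, b = 0), c(1, 1, 1))
  expect_equal(mus_prime(500, A = 2, b = 1), 0.004)
  # log-domain oracle for a realistic amplitude
  expect_equal(mus_prime(550, A = 5e5, b = 1.2), exp(log(5e5) - 1.2 * log(550)))
  lam <- seq(450, 650, 10)
  expect_true(all(diff(mus_prime(lam, A = 2e4, b = 1.3)) < 0))
  expect_error(mus_prime(c(500, -1), A = 1, b = 1), class = "drsquant_domain_error")
  expect_error(mus_prime(500, A = 0, b = 1), class = "drsquant_domain_error")
})

test_that("packing factor has the analytic limit, closed form and monotonicity", {
  expect_identical(packing_factor(0, R_vessel = 10), 1)
  # dimensionless argument 2 * mua * R = 1: R = 10 um = 1e-3 cm -> mua = 500
  expect_equal(packing_factor(500, R_vessel = 10), 1 - exp(-1))
  mua <- c(0, 0.5, 5, 50, 500)
  vec <- packing_factor(mua, R_vessel = 25)
  expect_equal(vec, vapply(mua, packing_factor, numeric(1), R_vessel = 25))
  expect_true(all(vec > 0 & vec <= 1))
  expect_true(all(diff(vec) < 0))
  # tiny arguments stay at the limit, no 0/0
  expect_equal(packing_factor(1e-12, R_vessel = 10), 1, tolerance = 1e-9)
  expect_error(packing_factor(1, R_vessel = 0), class = "drsquant_domain_error")
  expect_error(packing_factor(-1, R_vessel = 10), class = "drsquant_domain_error")
})

test_that("total absorption combines hemoglobin, packing and baseline correctly", {
  ext <- load_extinction()
  lam <- analysis_grid()
  expect_equal(mua_total(lam, hemodynamic_state(THb = 0, SO2 = 0.5), ext),
               rep(0, length(lam)))

  # SO2 = 1 contains no deoxy contribution: swapping the extinction columns
  # maps it onto the SO2 = 0 case
  ext_swap <- ext
  ext_swap$eps_HbO2 <- ext$eps_dHb
  ext_swap$eps_dHb <- ext$eps_HbO2
  class(ext_swap) <- class(ext)
  expect_equal(mua_total(lam, hemodynamic_state(20, 1), ext),
               mua_total(lam, hemodynamic_state(20, 0), ext_swap))

  # vanishing vessel radius: independent Beer-Lambert oracle from the fixture
  e <- extinction_at(ext, lam)
  oracle <- log(10) * (e$eps_HbO2 * 0.5 + e$eps_dHb * 0.5) * 20e-6
  got <- mua_total(lam, hemodynamic_state(20, 0.5, R_vessel = 1e-4), ext)
  expect_equal(got, oracle, tolerance = 1e-6)

  expect_error(mua_total(c(400, 500), hemodynamic_state(20, 0.5), ext),
               class = "drsquant_range_error")
})

test_that("absorption is linear in THb without packing, subadditive with it", {
  ext <- load_extinction()
  lam <- analysis_grid()
  tiny <- function(thb) mua_total(lam, hemodynamic_state(thb, 0.6, R_vessel = 1e-4), ext)
  expect_equal(tiny(40), 2 * tiny(20), tolerance = 1e-6)
  packed <- function(thb) mua_total(lam, hemodynamic_state(thb, 0.6, R_vessel = 50), ext)
  expect_true(all(packed(40) < 2 * packed(20)))
})

test_that("sensitivity to SO2 follows the sign of the extinction difference", {
  ext <- load_extinction()
  lam <- analysis_grid()
  e <- extinction_at(ext, lam)
  lo <- mua_total(lam, hemodynamic_state(30, 0.40, R_vessel = 1e-4), ext)
  hi <- mua_total(lam, hemodynamic_state(30, 0.41, R_vessel = 1e-4), ext)
  expect_equal(sign(hi - lo), sign(e$eps_HbO2 - e$eps_dHb))
})

test_that("extinction fixture has the hemoglobin band structure and exact nodes", {
  ext <- load_extinction()
  expect_true(all(diff(ext$wavelength) > 0))
  expect_true(all(ext$eps_HbO2 > 0) && all(ext$eps_dHb > 0))
  # interpolation at a stored node reproduces the stored value exactly
  i <- which(ext$wavelength == 550)
  at <- extinction_at(ext, 550)
  expect_identical(at$eps_HbO2, ext$eps_HbO2[i])
  # visible band structure: two oxy maxima (beta/alpha), one deoxy maximum
  win <- ext$wavelength >= 500 & ext$wavelength <= 600
  expect_length(local_minima(-ext$eps_HbO2[win]), 2)
  expect_length(local_minima(-ext$eps_dHb[win]), 1)
  expect_error(extinction_at(ext, 120), class = "drsquant_range_error")
})
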