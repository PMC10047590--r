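test_that("balanced designs reduce to ordinary least squares", {
  set.seed(4)
  d <- data.frame(subject = rep(1:10, each = 5), repeat_idx = rep(1:5, 10))
  d$y <- 2 + 0.3 * d$repeat_idx + rnorm(50, 0, 0.5)
  f <- fit_lmm(d, "y", fixed = "repeat_idx")
  ols <- coef(lm(y ~ repeat_idx, d))
  expect_equal(unname(f$beta), unname(ols), tolerance = 1e-6)
})

test_that("mixed-model estimates agree with the nlme reference implementation", {
  skip_if_not_installed("nlme")
  tab <- add_group(as.data.frame(generate_cohort(cohort_config(seed = 42))$endpoints))
  f <- fit_lmm(tab, "SO2")
  m <- nlme::lme(SO2 ~ group + repeat_idx, random = ~ 1 | subject,
                 data = tab, method = "REML")
  tt <- summary(m)$tTable
  expect_equal(unname(f$beta), unname(tt[, "Value"]), tolerance = 1e-5)
  expect_equal(unname(f$se), unname(tt[, "Std.Error"]), tolerance = 1e-4)
  expect_equal(f$sigma_e, m$sigma, tolerance = 1e-4)
  expect_equal(f$sigma_u, as.numeric(nlme::VarCorr(m)["(Intercept)", "StdDev"]),
               tolerance = 1e-4)
})

test_that("duplicating every observation keeps estimates but shrinks errors", {
  tab <- generate_cohort(cohort_config(seed = 7))$endpoints
  tab2 <- rbind(tab, tab)
  f1 <- fit_lmm(tab, "SO2")
  f2 <- fit_lmm(tab2, "SO2")
  expect_equal(unname(f2$beta), unname(f1$beta), tolerance = 0.02)
  expect_true(all(f2$se < f1$se))
})

test_that("confounded designs raise an identifiability error naming the column", {
  d <- data.frame(subject = rep(1:6, each = 2), y = rnorm(12))
  d$a <- rep(c("x", "y"), 6)
  d$b <- d$a   # perfectly aliased
  err <- expect_error(fit_lmm(d, "y", fixed = c("a", "b")),
                      class = "drsquant_identifiability_error")
  expect_match(conditionMessage(err), "b")
})

test_that("the profiled REML optimum beats a grid scan of the variance ratio", {
  tab <- generate_cohort(cohort_config(seed = 13))$endpoints
  f <- fit_lmm(tab, "THb")
  grid <- c(0, 10^seq(-4, 4, length.out = 40))
  expect_true(all(f$criterion(f$gamma) <= vapply(grid, f$criterion, numeric(1)) + 1e-6))
})

test_that("the Wald test is close to nominal size on null data", {
  set.seed(21)
  p <- replicate(300, {
    d <- data.frame(subject = rep(1:16, each = 4),
                    g = rep(c("a", "b"), each = 32))
    d$y <- rnorm(16)[d$subject] * 0.7 + rnorm(64)
    fit_lmm(d, "y", fixed = "g")$p_values[["gb"]]
  })
  expect_gte(mean(p < 0.05), 0.02)
  expect_lte(mean(p < 0.05), 0.09)
})

test_that("permutation p-values are reproducible, uniform-ish under the null, and powerful", {
  tab <- generate_cohort(cohort_config(n_subjects = 8, n_cancer_subjects = 4,
                                       n_normal_subjects = 4, n_benign_subjects = 1,
                                       so2_mean = c(normal = 0.6, cancer = 0.6,
                                                    benign = 0.6), seed = 5))$endpoints
  p1 <- permutation_test(tab, "SO2", n_perm = 199, seed = 9)
  p2 <- permutation_test(tab, "SO2", n_perm = 199, seed = 9)
  expect_identical(as.numeric(p1), as.numeric(p2))
  expect_identical(attr(p1, "method"), "exact")   # choose(9, 4) = 126 < 199
  expect_gt(as.numeric(p1), 0.01)                 # no true effect generated

  strong <- generate_cohort(cohort_config(seed = 6))$endpoints
  ps <- permutation_test(strong, "SO2", n_perm = 199, seed = 10)
  expect_lte(as.numeric(ps), 0.01)
})

test_that("Wald and permutation tests agree in their rejection decisions", {
  agree <- vapply(1:10, function(i) {
    tab <- generate_cohort(cohort_config(
      seed = 300 + i,
      so2_mean = c(normal = 0.62, cancer = 0.52, benign = 0.62)
    ))$endpoints
    pw <- fit_lmm(tab, "SO2")$p_values[["groupcancer"]]
    pp <- as.numeric(permutation_test(tab, "SO2", n_perm = 399, seed = i))
    (pw < 0.05) == (pp < 0.05)
  }, logical(1))
  expect_gte(mean(agree), 0.9)
})

test_that("site-level ANOVA matches the pooled t-test oracle and handles edge cases", {
  # textbook two-group case: F equals the squared pooled-variance t statistic
  d <- data.frame(
    subject = sprintf("S%02d", 1:12),
    site_type = rep(c("cancer", "normal"), each = 6),
    repeat_idx = 1, y = c(5.1, 4.8, 5.6, 5.0, 4.7, 5.3, 6.0, 6.4, 5.9, 6.2, 6.6, 6.1)
  )
  got <- anova_groups(d, "y")
  tt <- t.test(y ~ site_type, d, var.equal = TRUE)
  expect_equal(got$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(got$p.value, tt$p.value, tolerance = 1e-10)

  same <- d; same$y <- rep(c(1, 2, 3), 4)
  out <- anova_groups(transform(same, y = rep(c(4, 5, 6, 4, 5, 6), 2)), "y")
  expect_equal(out$statistic, 0)
  expect_equal(out$p.value, 1)

  tiny <- d[c(1, 7), ]
  expect_error(anova_groups(tiny, "y"), class = "drsquant_df_error")
})
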