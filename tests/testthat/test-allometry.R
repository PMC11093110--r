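test_that("fit_power_law recovers exact power laws", {
  d <- data.frame(mass_g = c(1, 10, 100), y = c(2, 20, 200))
  fit <- fit_power_law(d, y)
  expect_equal(fit$b, 1, tolerance = 1e-12)
  expect_equal(fit$a, log10(2), tolerance = 1e-12)
  d2 <- data.frame(mass_g = exp(seq(0, 5, length.out = 12)))
  d2$y <- 3 * d2$mass_g^0.8
  fit2 <- fit_power_law(d2, y)
  expect_equal(fit2$b, 0.8, tolerance = 1e-12)
  expect_equal(fit2$r_squared, 1, tolerance = 1e-12)
})

test_that("fit_power_law agrees with the closed-form OLS oracle on noisy data", {
  set.seed(21)
  m <- 10^runif(40, 0, 2.3)
  y <- 10^(0.4 + 0.9 * log10(m) + rnorm(40, 0, 0.05))
  fit <- fit_power_law(data.frame(mass_g = m, y = y), y)
  oracle <- ols_oracle(log10(m), log10(y))
  expect_equal(fit$b, unname(oracle["slope"]), tolerance = 1e-12)
  expect_equal(fit$a, unname(oracle["intercept"]), tolerance = 1e-12)
  # CI contains the estimate; glance/tidy expose the same numbers
  expect_true(fit$ci95_b[1] < fit$b && fit$b < fit$ci95_b[2])
  expect_equal(glance(fit)$b, fit$b)
  expect_equal(tidy(fit)$estimate[2], fit$b)
})

test_that("fit_power_law rejects non-positive data naming the row", {
  d <- data.frame(mass_g = c(1, 2, 3), y = c(1, -1, 2))
  expect_error(fit_power_law(d, y), "row\\(s\\): 2")
  d2 <- data.frame(mass_g = c(1, 0, 3), y = c(1, 1, 2))
  expect_error(fit_power_law(d2, y), "mass at row")
  d3 <- data.frame(mass_g = c(1, 2), y = c(1, 2))
  expect_error(fit_power_law(d3, y), "at least 3")
})

test_that("temperature interaction equals the per-group slope difference", {
  set.seed(31)
  m <- 10^runif(40, 0, 2)
  d <- data.frame(
    mass_g = rep(m, 2),
    temperature_c = rep(c(15, 20), each = 40)
  )
  d$y <- 10^(0.2 + ifelse(d$temperature_c == 15, 0.97, 0.83) *
               log10(d$mass_g) + rnorm(80, 0, 0.05))
  res <- test_temperature_interaction(d, y)
  b15 <- fit_power_law(d[d$temperature_c == 15, ], y)$b
  b20 <- fit_power_law(d[d$temperature_c == 20, ], y)$b
  expect_equal(res$interaction_b, b20 - b15, tolerance = 1e-10)
  # identical generating line across groups: interaction collapses to zero
  d0 <- d
  d0$y <- 10^(0.2 + 0.9 * log10(d0$mass_g))
  res0 <- test_temperature_interaction(d0, y)
  expect_lt(abs(res0$interaction_b), 1e-10)
  # constant masses in one group make the design singular
  dsing <- d
  dsing$mass_g[dsing$temperature_c == 20] <- 5
  expect_error(test_temperature_interaction(dsing, y), "singular")
})

test_that("a true slope difference is detected with high power", {
  detected <- 0
  for (s in 1:25) {
    set.seed(s)
    m <- 10^runif(80, 0, 2)
    d <- data.frame(mass_g = m, temperature_c = rep(c(15, 20), each = 40))
    d$y <- 10^(0.2 + ifelse(d$temperature_c == 15, 0.97, 0.83) *
                 log10(d$mass_g) + rnorm(80, 0, 0.05))
    if (test_temperature_interaction(d, y)$p_value < 0.05) {
      detected <- detected + 1
    }
  }
  expect_gte(detected, 22)
})

test_that("scaling_difference reproduces b_S arithmetic and is antisymmetric", {
  expect_equal(scaling_difference(0.969, 0.872, "RMR")$b_s, 0.097,
               tolerance = 1e-12)
  expect_equal(scaling_difference(0.969, 0.943, "MMR")$b_s, 0.026,
               tolerance = 1e-12)
  expect_false(scaling_difference(0.969, 0.872)$gol_scenario2_consistent)
  expect_equal(scaling_difference(0.8, 0.8)$b_s, 0)
  set.seed(2)
  x <- rnorm(10); z <- rnorm(10)
  expect_equal(scaling_difference(x, z)$b_s, -scaling_difference(z, x)$b_s)
})

test_that("component slopes sum to the directly fitted GSA slope", {
  expect_equal(component_slope_sum(0.33, -0.33, 0.67), 0.67)
  cohort <- generate_cohort(cohort_config(n_per_temperature = 12, seed = 3),
                            scaling_truth("null"))
  sampled <- cohort[cohort$sampled & cohort$temperature_c == 15, ]
  d <- dplyr::transmute(
    sampled,
    mass_g = mass_g,
    total_filament_length_mm = lfil_true,
    lamellar_frequency_per_mm = nlam_true,
    mean_lamellar_area_mm2 = alam_true,
    gsa_mm2 = gsa_true
  )
  dec <- decompose_gsa_slope(d, temperature_c = 15)
  expect_equal(dec$b_sum, dec$b_gsa_direct, tolerance = 1e-10)
  # intercepts add too, by the same linearity
  a_sum <- fit_power_law(d, total_filament_length_mm)$a +
    fit_power_law(d, lamellar_frequency_per_mm)$a +
    fit_power_law(d, mean_lamellar_area_mm2)$a
  expect_equal(a_sum, fit_power_law(d, gsa_mm2)$a, tolerance = 1e-10)
  d$total_filament_length_mm[1] <- NA
  expect_error(decompose_gsa_slope(d), "same fish set")
})

test_that("mass correction rescales by the fitted exponent", {
  expect_equal(mass_correct(3.0, 24, 0.872), 3.0)
  expect_equal(mass_correct(3.0, 48, 0.872), 3.0 * 2^-0.872,
               tolerance = 1e-12)
  expect_equal(mass_correct(3.0, 48, 0), 3.0)
  expect_error(mass_correct(-1, 24, 0.9), "positive")
})

test_that("mass correction with the true slope removes the mass effect", {
  set.seed(14)
  m <- 10^runif(60, 0, 2.3)
  mr <- 10^(-0.6 + 0.87 * log10(m) + rnorm(60, 0, 0.05))
  fitted_b <- fit_power_law(data.frame(mass_g = m, mr = mr), mr)$b
  mc <- mass_correct(mr, m, fitted_b)
  resid_fit <- fit_power_law(data.frame(mass_g = m, mc = mc), mc)
  expect_true(resid_fit$ci95_b[1] <= 0 && 0 <= resid_fit$ci95_b[2])
  expect_lt(abs(resid_fit$b), 0.05)
})

test_that("q10 follows its defining arithmetic", {
  expect_equal(q10(2.5, 2.5, 15, 20), 1.0)
  expect_equal(q10(1, 2, 15, 25), 2.0)
  expect_equal(q10(1, 1.32, 15, 20), 1.32^2, tolerance = 1e-12)
  expect_error(q10(1, 2, 15, 15), "differ")
})

test_that("factorial aerobic scope is a guarded ratio", {
  expect_equal(factorial_aerobic_scope(6, 2), 3)
  expect_equal(factorial_aerobic_scope(2, 2), 1)
  expect_warning(factorial_aerobic_scope(1, 2), "below 1")
  expect_error(factorial_aerobic_scope(6, 0), "positive")
  # invariant to the correction reference when both metrics share b
  set.seed(6)
  m <- runif(10, 5, 100); rmr <- runif(10, 1, 3); mmr <- rmr * runif(10, 2, 5)
  b <- 0.9
  fas24 <- factorial_aerobic_scope(mass_correct(mmr, m, b, 24),
                                   mass_correct(rmr, m, b, 24))
  fas50 <- factorial_aerobic_scope(mass_correct(mmr, m, b, 50),
                                   mass_correct(rmr, m, b, 50))
  expect_equal(fas24, fas50, tolerance = 1e-12)
})
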