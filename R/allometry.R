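#' Fit a log10 power law of a trait against body mass
#'
#' Fits `log10(y) = a + b * log10(M)` by ordinary least squares, the standard
#' allometric model `y = a * M^b` on log axes. The slope `b` is the
#' allometric scaling exponent; `a` is the log10 intercept at 1 g. The 95%
#' confidence interval on `b` uses the t distribution with n - 2 degrees of
#' freedom.
#'
#' @param data Data frame holding the fish-level observations.
#' @param response Unquoted column of trait values (all > 0).
#' @param mass Unquoted column of body masses in grams (all > 0); default
#'   `mass_g`.
#' @param temperature_c Optional scalar temperature label carried on the fit.
#' @return An object of class `allom_fit` with fields `trait`,
#'   `temperature_c`, `a`, `b`, `se_b`, `ci95_b`, `r_squared`, `n` and the
#'   underlying `lm` fit. Use [tidy()], [glance()] or
#'   [ggplot2::autoplot()] on it.
#' @examples
#' d <- data.frame(mass_g = c(1, 10, 100), gsa = c(2, 20, 200))
#' fit_power_law(d, gsa) # b = 1, a = log10(2)
#' @export
fit_power_law <- function(data, response, mass = mass_g,
                          temperature_c = NA_real_) {
  y <- rlang::eval_tidy(rlang::enquo(response), data)
  m <- rlang::eval_tidy(rlang::enquo(mass), data)
  trait <- rlang::as_name(rlang::enquo(response))
  if (length(y) != length(m)) abort("`response` and `mass` lengths differ.")
  ok <- is.finite(y) & is.finite(m)
  if (any(y[ok] <= 0)) {
    abort(sprintf("Non-positive trait value(s) in `%s` at row(s): %s.",
                  trait, paste(utils::head(which(y <= 0), 5L), collapse = ", ")))
  }
  if (any(m[ok] <= 0)) {
    abort(sprintf("Non-positive mass at row(s): %s.",
                  paste(utils::head(which(m <= 0), 5L), collapse = ", ")))
  }
  y <- y[ok]; m <- m[ok]
  n <- length(y)
  if (n < 3L) abort("Need at least 3 observations for a power-law fit.")
  fit <- lm(log10(y) ~ log10(m))
  sm <- summary(fit)
  b <- unname(coef(fit)[2L])
  se_b <- sm$coefficients[2L, 2L]
  tcrit <- qt(0.975, df = n - 2L)
  structure(
    list(
      trait = trait,
      temperature_c = temperature_c,
      a = unname(coef(fit)[1L]),
      b = b,
      se_b = se_b,
      ci95_b = c(b - tcrit * se_b, b + tcrit * se_b),
      r_squared = sm$r.squared,
      n = n,
      model = fit,
      data = tibble(mass_g = m, value = y)
    ),
    class = "allom_fit"
  )
}

#' @export
print.allom_fit <- function(x, ...) {
  cat(sprintf(
    "Allometric fit: log10(%s) = %.4f + %.4f * log10(mass_g)\n", x$trait,
    x$a, x$b
  ))
  if (!is.na(x$temperature_c)) {
    cat(sprintf("  temperature: %g degC\n", x$temperature_c))
  }
  cat(sprintf("  b = %.4f  [95%% CI %.4f, %.4f]  R^2 = %.4f  n = %d\n",
              x$b, x$ci95_b[1L], x$ci95_b[2L], x$r_squared, x$n))
  invisible(x)
}

#' Tidy an allometric fit
#'
#' @param x An `allom_fit` object.
#' @param ... Unused.
#' @return A tibble with rows for the intercept `a` and slope `b`, each with
#'   estimate, standard error and 95% confidence limits.
#' @method tidy allom_fit
#' @export
tidy.allom_fit <- function(x, ...) {
  sm <- summary(x$model)$coefficients
  tcrit <- qt(0.975, df = x$n - 2L)
  tibble(
    term = c("a", "b"),
    estimate = c(x$a, x$b),
    std.error = sm[, 2L],
    statistic = sm[, 3L],
    p.value = sm[, 4L],
    conf.low = c(x$a - tcrit * sm[1L, 2L], x$ci95_b[1L]),
    conf.high = c(x$a + tcrit * sm[1L, 2L], x$ci95_b[2L])
  )
}

#' One-row summary of an allometric fit
#'
#' @inheritParams tidy.allom_fit
#' @return A one-row tibble: trait, temperature, a, b, se_b, ci bounds,
#'   r.squared, n.
#' @method glance allom_fit
#' @export
glance.allom_fit <- function(x, ...) {
  tibble(
    trait = x$trait,
    temperature_c = x$temperature_c,
    a = x$a,
    b = x$b,
    se_b = x$se_b,
    ci_low = x$ci95_b[1L],
    ci_high = x$ci95_b[2L],
    r.squared = x$r_squared,
    n = x$n
  )
}

#' Fit power laws for several traits by temperature group
#'
#' Convenience wrapper running [fit_power_law()] for each trait column within
#' each temperature treatment and binding the one-row summaries.
#'
#' @param data Per-fish data frame with `mass_g`, `temperature_c` and the
#'   trait columns.
#' @param traits Character vector of trait column names.
#' @return Tibble with one row per trait x temperature (columns as in
#'   [glance.allom_fit()]).
#' @export
fit_allometry <- function(data, traits) {
  assert_columns(data, c("mass_g", "temperature_c", traits), "data")
  purrr::map_dfr(sort(unique(data$temperature_c)), function(tc) {
    sub <- data[data$temperature_c == tc, , drop = FALSE]
    purrr::map_dfr(traits, function(tr) {
      fit <- fit_power_law(sub, !!rlang::sym(tr), temperature_c = tc)
      glance(fit)
    })
  })
}

#' Test for a temperature effect on allometric scaling
#'
#' Pools two temperature groups into one OLS fit of log10 trait on log10
#' mass, a temperature indicator and their interaction. The interaction
#' coefficient is exactly the difference between the per-group slopes; its
#' partial F test asks whether scaling differs between temperatures.
#'
#' @param data Per-fish data frame with `mass_g`, `temperature_c` and the
#'   trait column.
#' @param response Unquoted trait column.
#' @return One-row tibble: `trait`, `interaction_b` (slope difference,
#'   warm minus cold), `f_statistic`, `df1`, `df2`, `p_value`, and the
#'   temperature main-effect estimate `temperature_shift`.
#' @export
test_temperature_interaction <- function(data, response) {
  assert_columns(data, c("mass_g", "temperature_c"), "data")
  q <- rlang::enquo(response)
  y <- rlang::eval_tidy(q, data)
  trait <- rlang::as_name(q)
  temps <- sort(unique(data$temperature_c))
  if (length(temps) != 2L) {
    abort("Exactly two temperature groups are required.")
  }
  for (tc in temps) {
    sub <- data$temperature_c == tc
    if (sum(sub) < 3L) abort("Each temperature group needs n >= 3.")
    if (stats::var(log10(data$mass_g[sub])) == 0) {
      abort(sprintf("Masses constant within the %g degC group: singular design.",
                    tc))
    }
  }
  assert_positive(y, trait)
  assert_positive(data$mass_g, "mass_g")
  df <- tibble(
    ly = log10(y),
    lm_ = log10(data$mass_g),
    warm = as.integer(data$temperature_c == temps[2L])
  )
  full <- lm(ly ~ lm_ * warm, data = df)
  reduced <- lm(ly ~ lm_ + warm, data = df)
  an <- stats::anova(reduced, full)
  tibble(
    trait = trait,
    interaction_b = unname(coef(full)["lm_:warm"]),
    temperature_shift = unname(coef(full)["warm"]),
    f_statistic = an$F[2L],
    df1 = an$Df[2L],
    df2 = an$Res.Df[2L],
    p_value = an$`Pr(>F)`[2L]
  )
}

#' Scaling difference between gill surface area and metabolic rate
#'
#' The statistic `b_S = b_GSA - b_MR` compares the allometric slope of gill
#' surface area with that of a metabolic-rate metric at one temperature.
#' `b_S >= 0` means GSA scaling keeps pace with (or outpaces) metabolic
#' scaling — inconsistent with the GOL scenario in which gill area falls
#' progressively behind demand; `b_S < 0` is the signature of that scenario.
#'
#' @param b_gsa Allometric slope of gill surface area.
#' @param b_mr Allometric slope of the metabolic-rate metric.
#' @param mr_metric Label for the metric, e.g. `"RMR"` or `"MMR"`.
#' @return Tibble (vectorized over inputs): `b_gsa`, `b_mr`, `mr_metric`,
#'   `b_s`, `gol_scenario2_consistent` (TRUE when `b_s < 0`).
#' @examples
#' scaling_difference(0.969, 0.872, "RMR") # b_s = 0.097
#' @export
scaling_difference <- function(b_gsa, b_mr, mr_metric = "MR") {
  if (any(!is.finite(b_gsa)) || any(!is.finite(b_mr))) {
    abort("Slopes must be finite.")
  }
  tibble(
    b_gsa = b_gsa,
    b_mr = b_mr,
    mr_metric = mr_metric,
    b_s = b_gsa - b_mr,
    gol_scenario2_consistent = (b_gsa - b_mr) < 0
  )
}

#' Sum of gill-component allometric slopes
#'
#' Because GSA is the exact product of total filament length, lamellar
#' frequency and mean lamellar area, log10 GSA is the sum of the component
#' logs and (by OLS linearity) the fitted GSA slope is the sum of the fitted
#' component slopes. Geometric isometry predicts components of 0.33, -0.33
#' and 0.67, summing to 0.67.
#'
#' @param b_lfil,b_nlam,b_alam Component slopes.
#' @return Their sum, the implied GSA slope.
#' @examples
#' component_slope_sum(0.454, -0.036, 0.551) # 0.969
#' @export
component_slope_sum <- function(b_lfil, b_nlam, b_alam) {
  b_lfil + b_nlam + b_alam
}

#' Decompose the GSA scaling slope into its gill components
#'
#' Fits log10 power laws of total filament length, lamellar frequency and
#' mean lamellar area against mass on the same fish, and returns the
#' component slopes together with their sum, which equals the directly
#' fitted GSA slope up to floating-point error.
#'
#' @param data Per-fish data frame with `mass_g`,
#'   `total_filament_length_mm`, `lamellar_frequency_per_mm`,
#'   `mean_lamellar_area_mm2` and (optionally) `gsa_mm2`. Rows with any
#'   missing component are rejected: all components must be measured on the
#'   same fish set.
#' @param temperature_c Optional temperature label.
#' @return One-row tibble: `b_lfil`, `b_nlam`, `b_alam`, `b_sum`, and
#'   `b_gsa_direct` when `gsa_mm2` is present.
#' @export
decompose_gsa_slope <- function(data, temperature_c = NA_real_) {
  comp_cols <- c("total_filament_length_mm", "lamellar_frequency_per_mm",
                 "mean_lamellar_area_mm2")
  assert_columns(data, c("mass_g", comp_cols), "data")
  if (anyNA(data[comp_cols])) {
    abort("All gill components must be measured on the same fish set (no NAs).")
  }
  b_lfil <- fit_power_law(data, total_filament_length_mm)$b
  b_nlam <- fit_power_law(data, lamellar_frequency_per_mm)$b
  b_alam <- fit_power_law(data, mean_lamellar_area_mm2)$b
  out <- tibble(
    temperature_c = temperature_c,
    b_lfil = b_lfil, b_nlam = b_nlam, b_alam = b_alam,
    b_sum = component_slope_sum(b_lfil, b_nlam, b_alam)
  )
  if ("gsa_mm2" %in% names(data)) {
    out$b_gsa_direct <- fit_power_law(data, gsa_mm2)$b
  }
  out
}

#' Mass-correct a metabolic rate to a reference body mass
#'
#' Scales an absolute metabolic rate to what it would be at a common
#' reference mass (default the 24.0 g geometric mean of the study
#' population) using the allometric slope of that metric:
#' `MR_mc = MR * (M_ref / M)^b`. Temperature-specific slopes should be used
#' so the correction removes only the mass effect.
#'
#' @param mr Absolute metabolic rate(s), mg O2 per hour.
#' @param mass_g Body mass(es) in grams.
#' @param b Allometric slope of the metric (temperature-specific).
#' @param reference_mass_g Reference mass in grams (default 24.0).
#' @return Mass-corrected metabolic rate(s).
#' @examples
#' mass_correct(3.0, 48, b = 0.872) # 3 * 2^-0.872
#' @export
mass_correct <- function(mr, mass_g, b, reference_mass_g = 24.0) {
  assert_positive(mr, "mr")
  assert_positive(mass_g, "mass_g")
  assert_scalar_number(reference_mass_g, "reference_mass_g", positive = TRUE)
  if (any(!is.finite(b))) abort("`b` must be finite.")
  mr * (reference_mass_g / mass_g)^b
}

#' Temperature sensitivity (Q10)
#'
#' The factor by which a rate changes per 10 degC:
#' `Q10 = (R2 / R1)^(10 / (T2 - T1))`.
#'
#' @param r1,r2 Rates (> 0) at temperatures `t1_c` and `t2_c`.
#' @param t1_c,t2_c Temperatures in degrees Celsius; must differ.
#' @return Q10 (dimensionless).
#' @examples
#' q10(1, 2, 15, 25) # 2
#' @export
q10 <- function(r1, r2, t1_c, t2_c) {
  assert_positive(r1, "r1")
  assert_positive(r2, "r2")
  if (any(t1_c == t2_c)) abort("`t1_c` and `t2_c` must differ.")
  (r2 / r1)^(10 / (t2_c - t1_c))
}

#' Factorial aerobic scope
#'
#' Ratio of mass-corrected maximum to mass-corrected resting metabolic rate.
#' Values below 1 (MMR apparently under RMR) trigger a warning.
#'
#' @param mmr_mc,rmr_mc Mass-corrected MMR and RMR (> 0).
#' @return FAS (dimensionless).
#' @export
factorial_aerobic_scope <- function(mmr_mc, rmr_mc) {
  assert_positive(rmr_mc, "rmr_mc")
  assert_positive(mmr_mc, "mmr_mc")
  fas <- mmr_mc / rmr_mc
  if (any(fas < 1)) {
    warn("FAS below 1: mass-corrected MMR under mass-corrected RMR.")
  }
  fas
}
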