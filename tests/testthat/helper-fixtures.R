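# shared fixture builders -------------------------------------------------

# straight-line depletion trace at 1 Hz
linear_trace <- function(duration_s, slope, intercept = 100, t0 = 0) {
  t <- seq(t0, t0 + duration_s - 1)
  tibble::tibble(time_s = t, o2_percent_sat = intercept + slope * (t - t0))
}

# one synthetic fish record with latent traits, for trace generation
fixture_fish <- function(fish_id = "FX", mass_g = 24, temperature_c = 15,
                         rmr_true = 2, mmr_true = 8, pcrit_true = 25) {
  tibble::tibble(
    fish_id = fish_id, mass_g = mass_g, temperature_c = temperature_c,
    rmr_true = rmr_true, mmr_true = mmr_true, pcrit_true = pcrit_true,
    lfil_true = 600, nlam_true = 50, alam_true = 0.15
  )
}

# two-bin reference-hemibranch gill table used in the worked examples
fixture_gill_bins <- function() {
  tibble::tibble(
    fish_id = "FX",
    hemibranch_id = 4,
    bin_id = 1:2,
    filament_count = c(12, 10),
    median_filament_length_mm = c(5, 8),
    lamellar_freq_base_per_mm = c(25, 20),
    lamellar_freq_tip_per_mm = c(35, 20),
    lamellar_area_tip_mm2 = c(0.10, 0.20),
    lamellar_area_mid_mm2 = c(0.10, 0.20),
    lamellar_area_base_mm2 = c(0.10, 0.20)
  )
}

# closed-form OLS via the normal equations, kept independent of lm()
ols_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxx <- sum(x * x); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  c(intercept = intercept, slope = slope)
}
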