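test_that("generators are deterministic under a fixed seed", {
  cc <- cohort_config(n_per_temperature = 4, seed = 99)
  tt <- scaling_truth("null")
  c1 <- generate_cohort(cc, tt)
  c2 <- generate_cohort(cc, tt)
  expect_identical(c1, c2)
  f <- c1[c1$sampled, ][1, ]
  tc <- trace_config(n_cycles = 3, o2_noise_sd_percent_sat = 0.1, seed = 7)
  expect_identical(generate_trace(f, tc, "rmr"), generate_trace(f, tc, "rmr"))
  expect_identical(generate_gill_bins(f, noise = 0.05, seed = 7),
                   generate_gill_bins(f, noise = 0.05, seed = 7))
})

test_that("per-fish streams are independent of cohort subsetting", {
  tt <- scaling_truth("null")
  big <- generate_cohort(cohort_config(n_per_temperature = 6, seed = 5), tt)
  small <- generate_cohort(cohort_config(n_per_temperature = 4, seed = 5), tt)
  shared <- intersect(unique(big$fish_id), unique(small$fish_id))
  expect_equal(length(shared), 8L) # 4 per temperature
  expect_identical(big[big$fish_id %in% shared, ],
                   small[small$fish_id %in% shared, ])
})

test_that("identity scaling truth makes latent GSA equal body mass", {
  cc <- cohort_config(n_per_temperature = 3, trait_noise_sd_log10 = 0,
                      seed = 2)
  tt <- scaling_truth("null", b_gsa = 1, a_gsa = 0)
  cohort <- generate_cohort(cc, tt)
  expect_equal(cohort$gsa_true, cohort$mass_g, tolerance = 1e-12)
})

test_that("warm treatment ends lighter whenever a penalty is configured", {
  for (s in 1:10) {
    cohort <- generate_cohort(
      cohort_config(n_per_temperature = 40, sgr_temperature_penalty = 0.02,
                    seed = s),
      scaling_truth("null")
    )
    final <- cohort[cohort$timepoint_days == max(cohort$timepoint_days), ]
    m <- tapply(final$mass_g, final$temperature_c, mean)
    expect_lt(m[["20"]], m[["15"]])
  }
})

test_that("cohort masses grow over timepoints", {
  cohort <- generate_cohort(cohort_config(n_per_temperature = 5, seed = 3),
                            scaling_truth("null"))
  growth <- cohort |>
    dplyr::arrange(.data$fish_id, .data$timepoint_days) |>
    dplyr::group_by(.data$fish_id) |>
    dplyr::summarise(monotone = all(diff(mass_g) > 0))
  expect_true(all(growth$monotone))
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(n_per_temperature = 1), ">= 2")
  expect_error(cohort_config(temperatures_c = c(15, 15)), "distinct")
  expect_error(cohort_config(initial_mass_g_sd = -1), ">= 0")
  expect_error(cohort_config(sgr_base_percent_per_day = NaN), "finite")
  expect_error(scaling_truth("null", b_lfil = 0.5, b_nlam = 0.5,
                             b_alam = 0.5), "sum")
  expect_error(scaling_truth("gol_scenario2", b_rmr = 0.5), "ordering")
  expect_error(trace_config(flush_s = 0), "> 0")
  expect_error(generate_trace(fixture_fish(), trace_config(), "nope"))
})

test_that("gill bins respect the measurement layout", {
  f <- fixture_fish()
  bins <- generate_gill_bins(f, noise = 0.05, seed = 31)
  per_hemi <- table(bins$hemibranch_id)
  expect_equal(sort(unique(bins$hemibranch_id)), 1:8)
  expect_true(all(per_hemi >= 5 & per_hemi <= 7))
  expect_true(all(bins$filament_count >= 1))
  ref <- bins[bins$hemibranch_id == 4, ]
  expect_true(all(is.finite(ref$lamellar_freq_base_per_mm)))
  expect_true(all(is.na(
    bins$lamellar_freq_base_per_mm[bins$hemibranch_id != 4]
  )))
})

test_that("noisy gill bins still center on the latent components", {
  cohort <- generate_cohort(cohort_config(n_per_temperature = 30, seed = 17),
                            scaling_truth("null"))
  sampled <- cohort[cohort$sampled, ]
  bins <- generate_gill_bins(sampled, noise = 0.05, seed = 17)
  agg <- dplyr::inner_join(aggregate_gills(bins), sampled, by = "fish_id")
  rel <- log10(agg$gsa_mm2 / agg$gsa_true)
  expect_lt(abs(mean(rel)), 0.05)
  ft <- fit_power_law(agg, gsa_mm2)
  expect_true(ft$ci95_b[1] <= 0.97 && 0.97 <= ft$ci95_b[2])
})

test_that("noiseless resting traces have perfect measure-phase fits", {
  f <- fixture_fish()
  tc <- trace_config(n_cycles = 8, seed = 3)
  est <- fit_measure_slopes(generate_trace(f, tc, "rmr"),
                            cycle_phases(240, 60, 300), f$temperature_c,
                            tc$system_volume_l, f$mass_g)
  expect_equal(nrow(est), 8L)
  expect_true(all(abs(est$r_squared - 1) < 1e-9))
  expect_true(all(est$accepted))
  # the lowest-quartile estimator lands exactly on the latent RMR
  expect_equal(estimate_rmr(est), f$rmr_true, tolerance = 1e-9)
})

test_that("a planted MMR is recovered from the noiseless chase trace", {
  f <- fixture_fish(mmr_true = 9.4)
  tc <- trace_config(seed = 3)
  fit <- estimate_mmr(generate_trace(f, tc, "mmr_chase"), f$temperature_c,
                      tc$system_volume_l, f$mass_g)
  expect_equal(fit$mmr_mg_o2_per_h, 9.4, tolerance = 1e-6)
})

test_that("background respiration inflates traces and is recoverable", {
  f <- fixture_fish(rmr_true = 2)
  tc <- trace_config(n_cycles = 8, background_rate_start = 0.2,
                     background_rate_end = 0.2, seed = 3)
  est <- fit_measure_slopes(generate_trace(f, tc, "rmr"),
                            cycle_phases(240, 60, 300), f$temperature_c,
                            tc$system_volume_l, f$mass_g)
  raw <- estimate_rmr(est)
  expect_equal(raw, 2.2, tolerance = 1e-6)
  corrected <- estimate_rmr(
    subtract_background(est, 0.2, 0.2, 0, max(est$window_end_s))
  )
  expect_equal(corrected, 2, tolerance = 1e-6)
})

test_that("drawdown traces decline and embed the conformity breakpoint", {
  f <- fixture_fish(rmr_true = 2, pcrit_true = 30)
  tc <- trace_config(seed = 5)
  tr <- generate_trace(f, tc, "pcrit_drawdown")
  expect_true(all(diff(tr$o2_percent_sat) <= 0))
  expect_lte(min(tr$o2_percent_sat), tc$drawdown_floor_percent_sat + 0.5)
})
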