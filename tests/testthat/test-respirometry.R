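test_that("segment_cycles tiles exactly and drops partial cycles", {
  cyc <- cycle_phases(240, 60, 300)
  segs <- segment_cycles(linear_trace(6000, -0.005), cyc)
  expect_equal(dplyr::n_distinct(segs$cycle), 10L)
  expect_true(all(table(segs$cycle) == 300L))
  # trailing partial cycle dropped
  segs2 <- segment_cycles(linear_trace(6100, -0.005), cyc)
  expect_equal(dplyr::n_distinct(segs2$cycle), 10L)
  expect_warning(
    empty <- segment_cycles(linear_trace(400, -0.005), cyc),
    "shorter than one full cycle"
  )
  expect_equal(nrow(empty), 0L)
})

test_that("segment boundaries agree with a brute-force index scan", {
  set.seed(71)
  for (rep in 1:10) {
    fl <- sample(30:300, 1); wa <- sample(10:90, 1); me <- sample(60:400, 1)
    dur <- sample(1000:5000, 1)
    tr <- linear_trace(dur, -0.003)
    cyc <- cycle_phases(fl, wa, me)
    got <- segment_cycles(tr, cyc)
    # brute force: classify every sample by scanning cycles one at a time
    cl <- fl + wa + me
    n_cyc <- floor(dur / cl)
    keep <- logical(dur)
    cycle_id <- integer(dur)
    for (i in seq_len(dur)) {
      tt <- tr$time_s[i]
      c_i <- tt %/% cl
      off <- tt - c_i * cl
      if (c_i < n_cyc && off >= fl + wa) {
        keep[i] <- TRUE
        cycle_id[i] <- c_i + 1L
      }
    }
    expect_equal(got$time_s, tr$time_s[keep])
    expect_equal(got$cycle, cycle_id[keep])
  }
})

test_that("fit_segment_slope recovers exact lines and flags degeneracy", {
  seg <- linear_trace(300, -0.01)
  fit <- fit_segment_slope(seg)
  expect_equal(fit$slope_percent_sat_per_s, -0.01, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  flat <- tibble::tibble(time_s = 1:10, o2_percent_sat = rep(95, 10))
  dfit <- fit_segment_slope(flat)
  expect_equal(dfit$slope_percent_sat_per_s, 0)
  expect_true(is.na(dfit$r_squared))
  expect_error(
    fit_segment_slope(tibble::tibble(time_s = c(1, 1, 1),
                                     o2_percent_sat = c(1, 2, 3))),
    "strictly increasing|time variance"
  )
})

test_that("segment slopes match the closed-form normal equations", {
  set.seed(5)
  for (rep in 1:5) {
    seg <- linear_trace(120, -0.008)
    seg$o2_percent_sat <- seg$o2_percent_sat + rnorm(120, 0, 0.3)
    fit <- fit_segment_slope(seg)
    oracle <- ols_oracle(seg$time_s, seg$o2_percent_sat)
    expect_equal(fit$slope_percent_sat_per_s, unname(oracle["slope"]),
                 tolerance = 1e-12)
  }
})

test_that("estimate_rmr averages the lowest quartile with a ceiling rule", {
  expect_equal(estimate_rmr(1:8), 1.5)                # k = 2
  expect_equal(estimate_rmr(rep(5, 6)), 5)
  expect_equal(estimate_rmr(c(3, 1, 9, 4, 2)), 1.5)   # n=5 -> k=ceil(1.25)=2
  # permutation invariance and the quantile bound
  set.seed(9)
  v <- rexp(17) + 0.5
  expect_equal(estimate_rmr(v), estimate_rmr(sample(v)))
  expect_lte(estimate_rmr(v), median(v))
})

test_that("estimate_rmr honors the acceptance filter and rejects empties", {
  est <- tibble::tibble(
    mo2_mg_o2_per_h = c(1, 2, 100, 200),
    accepted = c(TRUE, TRUE, FALSE, FALSE),
    r_squared = c(0.99, 0.95, 0.3, 0.2)
  )
  expect_equal(estimate_rmr(est), 1)
  est$accepted <- FALSE
  expect_error(estimate_rmr(est), "R-squared")
})

test_that("rolling-regression MMR finds a planted steepest window", {
  # slope -0.02 for the first 120 s, then -0.005
  t <- 0:299
  o2 <- ifelse(t <= 120, 100 - 0.02 * t, 100 - 0.02 * 120 - 0.005 * (t - 120))
  tr <- tibble::tibble(time_s = t, o2_percent_sat = o2)
  fit <- estimate_mmr(tr, 15, 0.657, 0)
  expect_lte(fit$window_end_s, 120)
  expect_equal(fit$slope_percent_sat_per_s, -0.02, tolerance = 1e-10)
  # globally linear trace: every window identical
  lin <- linear_trace(300, -0.012)
  lfit <- estimate_mmr(lin, 15, 0.657, 0)
  expect_equal(lfit$mmr_mg_o2_per_h, compute_mo2(-0.012, 15, 0.657, 0),
               tolerance = 1e-10)
  expect_error(estimate_mmr(linear_trace(30, -0.01), 15, 0.657, 0),
               "shorter than")
})

test_that("rolling-regression MMR equals brute-force window search", {
  set.seed(33)
  for (rep in 1:10) {
    n <- 150
    tr <- tibble::tibble(
      time_s = 0:(n - 1),
      o2_percent_sat = 100 - cumsum(runif(n, 0, 0.05)) + rnorm(n, 0, 0.1)
    )
    fit <- estimate_mmr(tr, 15, 1, 0, window_s = 60)
    slopes <- vapply(1:(n - 60), function(i) {
      unname(coef(lm(o2_percent_sat ~ time_s, data = tr[i:(i + 60), ]))[2])
    }, numeric(1))
    expect_equal(fit$slope_percent_sat_per_s, min(slopes), tolerance = 1e-9)
  }
})

test_that("background subtraction interpolates linearly and clamps at zero", {
  est <- tibble::tibble(
    mo2_mg_o2_per_h = c(1, 1, 0.03),
    window_start_s = c(0, 46800, 93600),   # 0, 13, 26 h
    window_end_s = c(0, 46800, 93600),
    accepted = TRUE, r_squared = 1, background_subtracted = FALSE
  )
  expect_warning(
    out <- subtract_background(est, 0.02, 0.06, 0, 93600),
    "floored at 0"
  )
  expect_equal(out$background_mg_o2_per_h, c(0.02, 0.04, 0.06))
  expect_equal(out$mo2_mg_o2_per_h[2], 1 - 0.04)
  expect_equal(out$mo2_mg_o2_per_h[3], 0)
  # zero background is the identity
  out0 <- subtract_background(est, 0, 0, 0, 93600)
  expect_equal(out0$mo2_mg_o2_per_h, est$mo2_mg_o2_per_h)
  expect_true(all(out0$background_subtracted))
  # negative rates clamp with a warning
  expect_warning(subtract_background(est[1:2, ], -0.1, 0.0, 0, 93600),
                 "clamped")
  # correction never increases uptake
  expect_true(all(out$mo2_mg_o2_per_h <= est$mo2_mg_o2_per_h))
})

test_that("LLO P_crit handles step and exact conformers", {
  rmr <- 2
  # encode MO2(P) by time-warping a fixed P grid: the time spent crossing
  # each P step is what a closed chamber at that uptake would take
  warp_trace <- function(p, mo2) {
    dt <- -diff(p) / -gillscale:::mo2_to_slope_percent_sat(
      pmax(mo2[-1], 0.02), 15, 1, 0)
    tibble::tibble(time_s = cumsum(c(0, dt)), o2_percent_sat = p)
  }
  # step conformer: MO2 = RMR above P_c = 30, ~0 below -> crossing at P_c
  p <- seq(100, 2, by = -0.25)
  tr <- warp_trace(p, ifelse(p >= 30, rmr, 0))
  fit <- estimate_pcrit_llo(tr, rmr, 15, 1, 0)
  expect_true(fit$defined)
  expect_equal(fit$pcrit_percent_sat, 30, tolerance = 2)
  # conformer riding the reference line never drops strictly below it:
  # built per 2%-bin with constant within-bin slope at the bin midpoint
  # (tiny elevation keeps the degenerate case clear of float ties)
  rows <- list()
  t0 <- 0
  for (j in 49:1) {
    o2 <- seq(2 * j + 1.75, 2 * j, by = -0.25)
    sl <- gillscale:::mo2_to_slope_percent_sat(
      1.01 * rmr * (2 * j + 1) / 100, 15, 1, 0)
    times <- t0 + cumsum(rep(0.25 / abs(sl), length(o2)))
    t0 <- times[length(times)]
    rows[[length(rows) + 1L]] <- tibble::tibble(time_s = times,
                                                o2_percent_sat = o2)
  }
  trc <- dplyr::bind_rows(rows)
  fitc <- estimate_pcrit_llo(trc, rmr, 15, 1, 0)
  expect_false(fitc$defined)
})

test_that("MMR exceeds RMR on paired traces from the same synthetic fish", {
  f <- fixture_fish(rmr_true = 2, mmr_true = 7)
  tc <- trace_config(n_cycles = 6, seed = 2,
                     o2_noise_sd_percent_sat = 0.05)
  rmr_tr <- generate_trace(f, tc, "rmr")
  mmr_tr <- generate_trace(f, tc, "mmr_chase")
  est <- fit_measure_slopes(rmr_tr, cycle_phases(240, 60, 300), 15,
                            tc$system_volume_l, f$mass_g)
  rmr <- estimate_rmr(est)
  mmr <- estimate_mmr(mmr_tr, 15, tc$system_volume_l, f$mass_g)$mmr_mg_o2_per_h
  expect_gt(mmr, rmr)
})
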