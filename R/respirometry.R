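#' Intermittent-flow cycle definition
#'
#' Durations of the three phases of one intermittent-flow respirometry cycle.
#' During the flush the chamber is re-oxygenated; the wait phase absorbs the
#' mixing lag after the chamber reseals and is discarded; only the measure
#' phase carries a clean depletion slope.
#'
#' @param flush_s,wait_s,measure_s Phase durations in seconds, all > 0.
#' @return A `cycle_phases` list with the three durations and their total.
#' @export
cycle_phases <- function(flush_s = 240, wait_s = 60, measure_s = 300) {
  for (nm in c("flush_s", "wait_s", "measure_s")) {
    assert_scalar_number(get(nm), nm, positive = TRUE)
  }
  structure(
    list(flush_s = flush_s, wait_s = wait_s, measure_s = measure_s,
         cycle_s = flush_s + wait_s + measure_s),
    class = "cycle_phases"
  )
}

#' Extract measure-phase segments from an oxygen trace
#'
#' Tiles the trace into flush/wait/measure cycles starting at its first
#' timestamp and returns only the measure-phase samples, labelled by cycle.
#' The wait phase (non-linear mixing lag) and any trailing partial cycle are
#' dropped: the number of cycles is `floor(duration / cycle_length)`.
#'
#' @param trace Data frame with columns `time_s` (strictly increasing) and
#'   `o2_percent_sat`.
#' @param cycle A [cycle_phases()] object.
#' @return Tibble with columns `cycle`, `time_s`, `o2_percent_sat`. Empty
#'   (with a warning) if the trace is shorter than one full cycle.
#' @export
segment_cycles <- function(trace, cycle) {
  assert_columns(trace, c("time_s", "o2_percent_sat"), "trace")
  if (!inherits(cycle, "cycle_phases")) {
    cycle <- do.call(cycle_phases, cycle)
  }
  t <- trace$time_s
  if (is.unsorted(t, strictly = TRUE)) {
    abort("`trace$time_s` must be strictly increasing.")
  }
  dt <- if (length(t) > 1L) median(diff(t)) else 1
  duration <- t[length(t)] - t[1L] + dt
  n_cycles <- floor(duration / cycle$cycle_s)
  if (n_cycles < 1L) {
    warn("Trace shorter than one full cycle; no measure segments returned.")
    return(tibble(cycle = integer(), time_s = numeric(),
                  o2_percent_sat = numeric()))
  }
  rel <- t - t[1L]
  idx <- floor(rel / cycle$cycle_s)
  within <- rel - idx * cycle$cycle_s
  keep <- idx < n_cycles & within >= (cycle$flush_s + cycle$wait_s)
  tibble(
    cycle = as.integer(idx[keep]) + 1L,
    time_s = t[keep],
    o2_percent_sat = trace$o2_percent_sat[keep]
  )
}

#' Least-squares slope of one depletion segment
#'
#' Ordinary least squares of oxygen saturation on time, with R-squared taken
#' as the squared Pearson correlation. A segment with no oxygen variance gets
#' slope 0 and an undefined (NA) R-squared, which downstream filtering treats
#' as not accepted.
#'
#' @param segment Data frame with columns `time_s` and `o2_percent_sat`
#'   (>= 3 rows).
#' @return One-row tibble: `slope_percent_sat_per_s`, `r_squared`, `n`.
#' @export
fit_segment_slope <- function(segment) {
  assert_columns(segment, c("time_s", "o2_percent_sat"), "segment")
  t <- segment$time_s
  y <- segment$o2_percent_sat
  if (length(t) < 3L) abort("Segment needs at least 3 samples.")
  if (stats::var(t) == 0) abort("Segment has zero time variance.")
  if (stats::var(y) == 0) {
    return(tibble(slope_percent_sat_per_s = 0, r_squared = NA_real_,
                  n = length(t)))
  }
  fit <- lm(y ~ t)
  tibble(
    slope_percent_sat_per_s = unname(coef(fit)[2L]),
    r_squared = stats::cor(t, y)^2,
    n = length(t)
  )
}

#' Per-cycle oxygen uptake estimates from an intermittent-flow trace
#'
#' Segments a resting-phase trace into measure windows, fits each depletion
#' slope, applies the R-squared acceptance filter, and converts accepted
#' slopes to oxygen uptake in mg O2 per hour.
#'
#' @inheritParams segment_cycles
#' @inheritParams compute_mo2
#' @param r2_threshold Minimum R-squared for a depletion slope to be accepted
#'   (default 0.9). Segments with undefined R-squared are rejected.
#' @return Tibble with one row per cycle: window bounds, slope, R-squared,
#'   `mo2_mg_o2_per_h`, `accepted`, `background_subtracted` (FALSE here; see
#'   [subtract_background()]).
#' @export
fit_measure_slopes <- function(trace, cycle, temperature_c, system_volume_l,
                               fish_mass_g = 0, r2_threshold = 0.9) {
  segs <- segment_cycles(trace, cycle)
  if (nrow(segs) == 0L) {
    return(tibble(
      cycle = integer(), window_start_s = numeric(), window_end_s = numeric(),
      slope_percent_sat_per_s = numeric(), r_squared = numeric(),
      mo2_mg_o2_per_h = numeric(), accepted = logical(),
      background_subtracted = logical()
    ))
  }
  segs |>
    dplyr::group_by(.data$cycle) |>
    dplyr::group_modify(function(df, key) {
      fit <- fit_segment_slope(df)
      tibble(
        window_start_s = min(df$time_s),
        window_end_s = max(df$time_s),
        slope_percent_sat_per_s = fit$slope_percent_sat_per_s,
        r_squared = fit$r_squared
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      mo2_mg_o2_per_h = compute_mo2(
        .data$slope_percent_sat_per_s, temperature_c,
        system_volume_l, fish_mass_g
      ),
      accepted = !is.na(.data$r_squared) & .data$r_squared >= r2_threshold,
      background_subtracted = FALSE
    )
}

#' Resting metabolic rate: mean of the lowest quartile
#'
#' RMR is the mean of the `k = ceiling(0.25 * n)` smallest accepted oxygen
#' uptake estimates, which discards elevated rates (activity, digestion) that
#' do not reflect resting metabolism. The ceiling guarantees at least one
#' value enters the mean.
#'
#' @param mo2_estimates Either a numeric vector of accepted MO2 values or a
#'   tibble from [fit_measure_slopes()] (rows with `accepted == FALSE` are
#'   dropped first).
#' @param quantile_fraction Fraction of lowest estimates averaged
#'   (default 0.25).
#' @return RMR in mg O2 per hour.
#' @export
estimate_rmr <- function(mo2_estimates, quantile_fraction = 0.25) {
  if (is.data.frame(mo2_estimates)) {
    assert_columns(mo2_estimates, c("mo2_mg_o2_per_h", "accepted"),
                   "mo2_estimates")
    if (!any(mo2_estimates$accepted)) {
      diag <- if ("r_squared" %in% names(mo2_estimates)) {
        paste(sprintf("%.3f", mo2_estimates$r_squared), collapse = ", ")
      } else "no R-squared values available"
      abort(paste0(
        "No accepted MO2 estimates; per-segment R-squared: ", diag, "."
      ))
    }
    values <- mo2_estimates$mo2_mg_o2_per_h[mo2_estimates$accepted]
  } else {
    values <- mo2_estimates
  }
  if (length(values) < 1L || any(!is.finite(values))) {
    abort("Need at least one finite accepted MO2 estimate.")
  }
  k <- ceiling(quantile_fraction * length(values))
  mean(sort(values)[seq_len(k)])
}

#' Maximum metabolic rate by rolling regression
#'
#' Slides a fixed-width window (default 60 s) one sample at a time along the
#' closed post-chase trace, fits the OLS depletion slope in every window, and
#' converts the steepest (most negative) slope to MO2.
#'
#' @param trace Data frame with `time_s`, `o2_percent_sat`; closed-phase
#'   post-chase recording at least `window_s` long.
#' @param temperature_c,system_volume_l,fish_mass_g Chamber geometry, as in
#'   [compute_mo2()].
#' @param window_s Window width in seconds (default 60).
#' @return One-row tibble: `mmr_mg_o2_per_h`, `window_start_s`,
#'   `window_end_s`, `slope_percent_sat_per_s`, `r_squared`.
#' @export
estimate_mmr <- function(trace, temperature_c, system_volume_l,
                         fish_mass_g = 0, window_s = 60) {
  assert_columns(trace, c("time_s", "o2_percent_sat"), "trace")
  t <- trace$time_s
  y <- trace$o2_percent_sat
  n <- length(t)
  dt <- if (n > 1L) median(diff(t)) else 1
  w <- as.integer(round(window_s / dt)) + 1L
  if (n < w) abort("Trace shorter than the rolling-regression window.")
  # windowed OLS via cumulative sums: exact closed-form normal equations
  css <- function(x) c(0, cumsum(x))
  st <- css(t); sy <- css(y); stt <- css(t * t); sty <- css(t * y)
  i <- seq_len(n - w + 1L)
  j <- i + w - 1L
  S1 <- st[j + 1L] - st[i]
  S2 <- stt[j + 1L] - stt[i]
  Sy <- sy[j + 1L] - sy[i]
  Sty <- sty[j + 1L] - sty[i]
  denom <- w * S2 - S1^2
  slopes <- (w * Sty - S1 * Sy) / denom
  best <- which.min(slopes)
  seg <- trace[seq(i[best], j[best]), c("time_s", "o2_percent_sat")]
  r2 <- if (stats::var(seg$o2_percent_sat) > 0) {
    stats::cor(seg$time_s, seg$o2_percent_sat)^2
  } else NA_real_
  tibble(
    mmr_mg_o2_per_h = compute_mo2(slopes[best], temperature_c,
                                  system_volume_l, fish_mass_g),
    window_start_s = t[i[best]],
    window_end_s = t[j[best]],
    slope_percent_sat_per_s = slopes[best],
    r_squared = r2
  )
}

#' Subtract time-interpolated background respiration
#'
#' Microbial background respiration is measured in the empty chamber before
#' the maximum-metabolic-rate trial and again after the hypoxia trial; it is
#' modelled as changing linearly between those two anchors and subtracted
#' from each MO2 estimate at its window midpoint. Corrected values are
#' floored at zero (with a warning), as is a negative background rate.
#'
#' @param mo2_estimates Tibble from [fit_measure_slopes()] (needs
#'   `mo2_mg_o2_per_h`, `window_start_s`, `window_end_s`).
#' @param pre_rate,post_rate Background rates (mg O2 per h) at `t_pre_s` and
#'   `t_post_s`.
#' @param t_pre_s,t_post_s Times of the two background measurements, on the
#'   same clock as the estimate windows.
#' @return The input tibble with `mo2_mg_o2_per_h` corrected,
#'   `background_mg_o2_per_h` added and `background_subtracted = TRUE`.
#' @export
subtract_background <- function(mo2_estimates, pre_rate, post_rate,
                                t_pre_s, t_post_s) {
  assert_columns(mo2_estimates,
                 c("mo2_mg_o2_per_h", "window_start_s", "window_end_s"),
                 "mo2_estimates")
  if (pre_rate < 0 || post_rate < 0) {
    warn("Negative background rate(s) clamped to 0.")
    pre_rate <- max(pre_rate, 0)
    post_rate <- max(post_rate, 0)
  }
  if (t_post_s == t_pre_s) abort("Background anchor times must differ.")
  mid <- (mo2_estimates$window_start_s + mo2_estimates$window_end_s) / 2
  background <- pre_rate +
    (post_rate - pre_rate) * (mid - t_pre_s) / (t_post_s - t_pre_s)
  corrected <- mo2_estimates$mo2_mg_o2_per_h - background
  if (any(corrected < 0)) {
    warn(sprintf(
      "%d corrected MO2 value(s) below 0 floored at 0 (background exceeded uptake).",
      sum(corrected < 0)
    ))
    corrected <- pmax(corrected, 0)
  }
  mo2_estimates |>
    dplyr::mutate(
      background_mg_o2_per_h = background,
      mo2_mg_o2_per_h = corrected,
      background_subtracted = TRUE
    )
}

#' Critical oxygen tension by the LLO method
#'
#' The line-from-normoxia method projects RMR as a straight line from its
#' value at normoxia down to zero at anoxia, `L(P) = RMR * P / normoxia`.
#' MO2 is computed in consecutive PO2 bins along the closed-chamber drawdown;
#' P_crit is the (linearly interpolated) PO2 of the highest crossing at which
#' binned MO2 drops below the line and stays below it to the end of the
#' trace. If MO2 never falls below the line the result is undefined and is
#' reported, flagged, as below the lowest observed PO2.
#'
#' @param trace Closed-chamber drawdown with `time_s`, `o2_percent_sat`
#'   (monotonically declining oxygen).
#' @param rmr Resting metabolic rate in mg O2 per hour.
#' @param temperature_c,system_volume_l,fish_mass_g Chamber geometry.
#' @param normoxia_percent_sat Saturation taken as normoxia (default 100).
#' @param bin_width_percent_sat PO2 bin width for MO2 estimation (default 2).
#' @return One-row tibble: `pcrit_percent_sat`, `defined` (FALSE when no
#'   crossing exists), `n_bins`.
#' @export
estimate_pcrit_llo <- function(trace, rmr, temperature_c, system_volume_l,
                               fish_mass_g = 0, normoxia_percent_sat = 100,
                               bin_width_percent_sat = 2) {
  assert_columns(trace, c("time_s", "o2_percent_sat"), "trace")
  assert_scalar_number(rmr, "rmr", positive = TRUE)
  assert_scalar_number(bin_width_percent_sat, "bin_width_percent_sat",
                       positive = TRUE)
  y <- trace$o2_percent_sat
  if (y[1L] <= y[length(y)]) {
    abort("Drawdown trace must decline from start to end.")
  }
  if (any(diff(y) > 2)) {
    warn("Drawdown trace is not monotone (jumps > 2% sat); check for flushes.")
  }
  bw <- bin_width_percent_sat
  bin <- floor(y / bw)
  per_bin <- tibble(bin = bin, time_s = trace$time_s, o2 = y) |>
    dplyr::group_by(.data$bin) |>
    dplyr::filter(dplyr::n() >= 3L, stats::var(.data$o2) > 0) |>
    dplyr::summarise(
      p_mid = (.data$bin[1L] + 0.5) * bw,
      slope = {
        f <- stats::.lm.fit(cbind(1, .data$time_s), .data$o2)
        f$coefficients[2L]
      },
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$p_mid)) |>
    dplyr::mutate(
      mo2 = compute_mo2(.data$slope, temperature_c, system_volume_l,
                        fish_mass_g),
      line = rmr * .data$p_mid / normoxia_percent_sat,
      below = .data$mo2 < .data$line
    )
  if (nrow(per_bin) < 2L) abort("Too few PO2 bins to estimate P_crit.")
  # highest crossing below which MO2 stays under the line to the trace end
  stays_below <- rev(cumprod(rev(per_bin$below))) == 1
  if (!any(stays_below)) {
    return(tibble(pcrit_percent_sat = min(y), defined = FALSE,
                  n_bins = nrow(per_bin)))
  }
  k <- which(stays_below)[1L]
  if (k == 1L) {
    # below the line already in the highest bin: no interpolation anchor
    pcrit <- per_bin$p_mid[1L]
  } else {
    # interpolate where mo2 - line changes sign between bins k-1 and k
    d1 <- per_bin$mo2[k - 1L] - per_bin$line[k - 1L]
    d2 <- per_bin$mo2[k] - per_bin$line[k]
    pcrit <- per_bin$p_mid[k - 1L] +
      (per_bin$p_mid[k] - per_bin$p_mid[k - 1L]) * d1 / (d1 - d2)
  }
  tibble(pcrit_percent_sat = pcrit, defined = TRUE, n_bins = nrow(per_bin))
}
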