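#' Generate a synthetic oxygen trace for one fish
#'
#' Builds a 1 Hz (configurable) dissolved-oxygen time series whose depletion
#' slopes encode the fish's latent metabolic rates, so downstream estimators
#' can be validated against known truth:
#'
#' * `"rmr"`: a sawtooth of flush/wait/measure cycles. Each cycle's measure
#'   slope encodes latent RMR times `1 + diel(c)`, where `diel` is a
#'   rectified sinusoid over the cycles (amplitude `diel_amplitude`, zero in
#'   the trough half), so the lowest-quartile estimator targets latent RMR.
#' * `"mmr_chase"`: a closed post-chase recording. Uptake holds at latent
#'   MMR for `mmr_plateau_s`, then decays exponentially toward RMR, so a
#'   60 s rolling regression recovers the planted MMR.
#' * `"pcrit_drawdown"`: a closed drawdown from normoxia in which uptake is
#'   RMR above the latent P_crit and falls off as `RMR * (P / P_crit)^2`
#'   below it (forward-Euler integration at the sample rate).
#'
#' Background respiration (linear from `background_rate_start` to
#' `background_rate_end` across the trace) is added to the depletion in all
#' three kinds; Gaussian sensor noise is added per sample.
#'
#' @param fish One fish record (a single row carrying `fish_id`, `mass_g`,
#'   `temperature_c` and the latent rates the kind requires).
#' @param config A [trace_config()].
#' @param kind One of `"rmr"`, `"mmr_chase"`, `"pcrit_drawdown"`.
#' @return Tibble with `fish_id`, `time_s`, `o2_percent_sat`, `phase`.
#' @export
generate_trace <- function(fish, config,
                           kind = c("rmr", "mmr_chase", "pcrit_drawdown")) {
  kind <- match.arg(kind)
  if (!inherits(config, "trace_config")) {
    abort("`config` must be a trace_config().")
  }
  if (nrow(fish) != 1L) abort("`fish` must be a single record (one row).")
  assert_columns(fish, c("fish_id", "mass_g", "temperature_c"), "fish")
  needed <- switch(kind,
    rmr = "rmr_true",
    mmr_chase = c("rmr_true", "mmr_true"),
    pcrit_drawdown = c("rmr_true", "pcrit_true")
  )
  assert_columns(fish, needed, "fish")
  dt <- 1 / config$sample_rate_hz
  to_slope <- function(mo2) {
    mo2_to_slope_percent_sat(mo2, fish$temperature_c,
                             config$system_volume_l, fish$mass_g)
  }
  trace <- with_seed(
    derive_seed(config$seed, paste0(fish$fish_id, "/", kind)), {
      switch(kind,
        rmr = rmr_sawtooth(fish, config, dt, to_slope),
        mmr_chase = mmr_chase_trace(fish, config, dt, to_slope),
        pcrit_drawdown = pcrit_drawdown_trace(fish, config, dt, to_slope)
      )
    }
  )
  trace$fish_id <- fish$fish_id
  trace[, c("fish_id", "time_s", "o2_percent_sat", "phase")]
}

background_at <- function(config, t, t_end) {
  if (t_end <= 0) return(rep(config$background_rate_start, length(t)))
  config$background_rate_start +
    (config$background_rate_end - config$background_rate_start) * t / t_end
}

rmr_sawtooth <- function(fish, config, dt, to_slope) {
  cyc <- cycle_phases(config$flush_s, config$wait_s, config$measure_s)
  n_per_cycle <- round(cyc$cycle_s / dt)
  times <- seq(0, by = dt, length.out = config$n_cycles * n_per_cycle)
  t_end <- times[length(times)]
  idx <- floor(times / cyc$cycle_s)
  within <- times - idx * cyc$cycle_s
  phase <- ifelse(within < cyc$flush_s, "flush",
                  ifelse(within < cyc$flush_s + cyc$wait_s, "wait", "measure"))
  # per-cycle uptake: latent RMR elevated by a rectified diel sinusoid,
  # exactly at RMR through the trough half of the cycle sequence
  cycles <- seq_len(config$n_cycles)
  diel <- config$diel_amplitude *
    pmax(0, sin(2 * pi * (cycles - 1) / config$n_cycles))
  mid <- (cycles - 0.5) * cyc$cycle_s
  mo2 <- fish$rmr_true * (1 + diel) + background_at(config, mid, t_end)
  slope <- to_slope(mo2)[cycles]
  o2 <- numeric(length(times))
  for (c in cycles) {
    sel <- idx == (c - 1L)
    w <- within[sel]
    seal <- w - cyc$flush_s # time since chamber resealed
    # depletion from 100% over wait + measure at the cycle's slope
    closed <- 100 + slope[c] * seal
    start_o2 <- if (c == 1L) 100 else o2_prev_end
    flush_frac <- pmin(w / cyc$flush_s, 1)
    o2[sel] <- ifelse(w < cyc$flush_s,
                      start_o2 + (100 - start_o2) * flush_frac,
                      closed)
    o2_prev_end <- 100 + slope[c] * (cyc$cycle_s - cyc$flush_s)
  }
  o2 <- o2 + rnorm(length(o2), 0, config$o2_noise_sd_percent_sat)
  tibble(time_s = times, o2_percent_sat = o2, phase = phase)
}

mmr_chase_trace <- function(fish, config, dt, to_slope) {
  times <- seq(0, config$mmr_duration_s - dt, by = dt)
  t_end <- times[length(times)]
  mo2 <- ifelse(
    times < config$mmr_plateau_s,
    fish$mmr_true,
    fish$rmr_true + (fish$mmr_true - fish$rmr_true) *
      exp(-(times - config$mmr_plateau_s) / config$mmr_decay_tau_s)
  ) + background_at(config, times, t_end)
  slope <- to_slope(mo2)
  o2 <- 100 + c(0, cumsum(slope[-length(slope)] * dt))
  o2 <- o2 + rnorm(length(o2), 0, config$o2_noise_sd_percent_sat)
  tibble(time_s = times, o2_percent_sat = o2, phase = "measure")
}

pcrit_drawdown_trace <- function(fish, config, dt, to_slope, max_steps = 2e5) {
  pc <- fish$pcrit_true
  floor_sat <- config$drawdown_floor_percent_sat
  slope_per_mo2 <- to_slope(1) # %sat/s per (mg O2/h) of uptake
  bg <- config$background_rate_start
  rmr <- fish$rmr_true
  p <- numeric(max_steps)
  p[1L] <- 100
  i <- 1L
  while (p[i] > floor_sat && i < max_steps) {
    mo2 <- bg + rmr * if (p[i] >= pc) 1 else (p[i] / pc)^2
    p[i + 1L] <- p[i] + slope_per_mo2 * mo2 * dt
    i <- i + 1L
  }
  p <- p[seq_len(i)]
  p <- p + rnorm(length(p), 0, config$o2_noise_sd_percent_sat)
  tibble(
    time_s = seq(0, by = dt, length.out = length(p)),
    o2_percent_sat = p,
    phase = "drawdown"
  )
}
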