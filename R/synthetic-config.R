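#' Configuration for a synthetic two-temperature growth cohort
#'
#' Describes the rearing experiment the generator emulates: fish start at a
#' common size, grow exponentially with a specific growth rate (SGR) that
#' declines linearly with age and is reduced at warmer temperature, and are
#' lethally sampled (round-robin) at the listed time points.
#'
#' @param n_per_temperature Fish per temperature treatment (>= 2).
#' @param temperatures_c Distinct treatment temperatures in degC.
#' @param timepoints_days Integer days of the sampling time points.
#' @param initial_mass_g_mean,initial_mass_g_sd Initial mass distribution in
#'   grams.
#' @param sgr_base_percent_per_day SGR at age 0 at the reference temperature.
#' @param sgr_age_decay_per_day Linear fractional decline of SGR per day of
#'   age (SGR is floored at 0).
#' @param sgr_temperature_penalty Fractional SGR reduction per degC above the
#'   reference temperature.
#' @param reference_temperature_c Temperature at which `sgr_base` applies.
#' @param mass_noise_sd_log10 Log10 scatter of individual masses around the
#'   deterministic growth trajectory.
#' @param trait_noise_sd_log10 Log10 scatter of latent traits (gill
#'   components, RMR, MMR) around their allometric lines.
#' @param seed Integer seed; per-fish streams are derived from it by hashing
#'   fish ids, so subsetting a cohort never changes another fish's data.
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(n_per_temperature = 36,
                          temperatures_c = c(15, 20),
                          timepoints_days = c(14, 90, 180),
                          initial_mass_g_mean = 2.62,
                          initial_mass_g_sd = 0.80,
                          sgr_base_percent_per_day = 2.6,
                          sgr_age_decay_per_day = 0.0025,
                          sgr_temperature_penalty = 0.044,
                          reference_temperature_c = 15,
                          mass_noise_sd_log10 = 0.02,
                          trait_noise_sd_log10 = 0.05,
                          seed = 1L) {
  cfg <- list(
    n_per_temperature = n_per_temperature,
    temperatures_c = temperatures_c,
    timepoints_days = timepoints_days,
    initial_mass_g_mean = initial_mass_g_mean,
    initial_mass_g_sd = initial_mass_g_sd,
    sgr_base_percent_per_day = sgr_base_percent_per_day,
    sgr_age_decay_per_day = sgr_age_decay_per_day,
    sgr_temperature_penalty = sgr_temperature_penalty,
    reference_temperature_c = reference_temperature_c,
    mass_noise_sd_log10 = mass_noise_sd_log10,
    trait_noise_sd_log10 = trait_noise_sd_log10,
    seed = as.integer(seed)
  )
  nums <- unlist(cfg[setdiff(names(cfg), "seed")])
  if (any(!is.finite(nums))) abort("Cohort config values must be finite.")
  if (n_per_temperature < 2) abort("`n_per_temperature` must be >= 2.")
  if (anyDuplicated(temperatures_c)) abort("`temperatures_c` must be distinct.")
  if (initial_mass_g_sd < 0 || mass_noise_sd_log10 < 0 ||
      trait_noise_sd_log10 < 0) {
    abort("Standard deviations must be >= 0.")
  }
  if (initial_mass_g_mean <= 0) abort("`initial_mass_g_mean` must be > 0.")
  structure(cfg, class = "cohort_config")
}

#' True allometric scaling parameters for a synthetic cohort
#'
#' Ground truth for the simulation: slopes and log10 intercepts (at 1 g) of
#' gill surface area, RMR and MMR, plus the gill-component slopes, which are
#' constrained to sum exactly to the GSA slope (GSA being the product of its
#' components). Three scenario presets encode the competing hypotheses about
#' gill and metabolic scaling:
#'
#' * `"null"` (default, what the study observed): GSA scales at least as
#'   steeply as metabolic rate, `b_gsa >= b_mr`, so `b_S >= 0`.
#' * `"gol_scenario1"`: both GSA and metabolic rate scale with the same
#'   exponent below 1.
#' * `"gol_scenario2"`: metabolic rate outscales GSA (`b_mr > b_gsa`), so
#'   the GSA-to-demand ratio shrinks with size and `b_S < 0`.
#'
#' @param scenario One of `"null"`, `"gol_scenario1"`, `"gol_scenario2"`.
#' @param b_gsa,b_rmr,b_mmr True slopes (preset defaults per scenario).
#' @param a_gsa,a_rmr,a_mmr True log10 intercepts at 1 g.
#' @param b_lfil,b_nlam,b_alam Component slopes; `b_alam` defaults to
#'   `b_gsa - b_lfil - b_nlam` so the sum constraint holds exactly.
#' @return A validated `scaling_truth` list (includes derived component
#'   intercepts `a_lfil`, `a_nlam`, `a_alam` summing to `a_gsa`).
#' @export
scaling_truth <- function(scenario = c("null", "gol_scenario1",
                                       "gol_scenario2"),
                          b_gsa = NULL, b_rmr = NULL, b_mmr = NULL,
                          a_gsa = log10(250), a_rmr = log10(0.25),
                          a_mmr = log10(1.0),
                          b_lfil = NULL, b_nlam = NULL, b_alam = NULL) {
  scenario <- match.arg(scenario)
  preset <- switch(scenario,
    null = list(b_gsa = 0.97, b_rmr = 0.87, b_mmr = 0.94,
                b_lfil = 0.454, b_nlam = -0.036),
    gol_scenario1 = list(b_gsa = 0.80, b_rmr = 0.80, b_mmr = 0.80,
                         b_lfil = 0.33, b_nlam = -0.20),
    gol_scenario2 = list(b_gsa = 0.80, b_rmr = 0.95, b_mmr = 0.95,
                         b_lfil = 0.33, b_nlam = -0.20)
  )
  b_gsa <- b_gsa %||% preset$b_gsa
  b_rmr <- b_rmr %||% preset$b_rmr
  b_mmr <- b_mmr %||% preset$b_mmr
  b_lfil <- b_lfil %||% preset$b_lfil
  b_nlam <- b_nlam %||% preset$b_nlam
  b_alam <- b_alam %||% (b_gsa - b_lfil - b_nlam)
  vals <- c(b_gsa, b_rmr, b_mmr, a_gsa, a_rmr, a_mmr, b_lfil, b_nlam, b_alam)
  if (any(!is.finite(vals))) abort("Scaling truth values must be finite.")
  if (abs(b_lfil + b_nlam + b_alam - b_gsa) > 1e-12) {
    abort("Component slopes must sum to `b_gsa` (within 1e-12).")
  }
  ok <- switch(scenario,
    null = b_gsa >= b_rmr && b_gsa >= b_mmr,
    gol_scenario1 = b_gsa < 1 && abs(b_rmr - b_gsa) <= 0.05 &&
      abs(b_mmr - b_gsa) <= 0.05,
    gol_scenario2 = b_rmr > b_gsa && b_mmr > b_gsa
  )
  if (!ok) {
    abort(sprintf("Slopes violate the '%s' scenario ordering.", scenario))
  }
  # fixed realistic anchors for filament length and lamellar frequency at
  # 1 g; lamellar area takes the remainder so intercepts sum to a_gsa
  a_lfil <- log10(150)
  a_nlam <- log10(60)
  structure(
    list(scenario = scenario,
         b_gsa = b_gsa, b_rmr = b_rmr, b_mmr = b_mmr,
         a_gsa = a_gsa, a_rmr = a_rmr, a_mmr = a_mmr,
         b_lfil = b_lfil, b_nlam = b_nlam, b_alam = b_alam,
         a_lfil = a_lfil, a_nlam = a_nlam,
         a_alam = a_gsa - a_lfil - a_nlam),
    class = "scaling_truth"
  )
}

#' Configuration for synthetic respirometry traces
#'
#' @param sample_rate_hz Sampling rate (default 1 Hz).
#' @param flush_s,wait_s,measure_s Intermittent-flow phase durations (s).
#' @param n_cycles Number of flush/wait/measure cycles in a resting trace.
#' @param system_volume_l Total system volume in litres.
#' @param background_rate_start,background_rate_end Background (microbial)
#'   respiration in mg O2 per hour at the start and end of the trace,
#'   interpolated linearly in between.
#' @param o2_noise_sd_percent_sat Gaussian sensor noise on each sample.
#' @param diel_amplitude Peak fractional elevation of resting MO2 over the
#'   diel cycle (rectified sinusoid across the cycles; the trough half of
#'   the cycle sits exactly at the latent RMR).
#' @param mmr_plateau_s Seconds the post-chase uptake holds at latent MMR
#'   before recovery begins (must be >= the rolling window).
#' @param mmr_decay_tau_s Exponential recovery time constant toward RMR.
#' @param mmr_duration_s Length of the post-chase closed recording.
#' @param drawdown_floor_percent_sat Saturation at which the hypoxia
#'   drawdown stops.
#' @param seed Integer seed for sensor noise.
#' @return A validated `trace_config` list.
#' @export
trace_config <- function(sample_rate_hz = 1, flush_s = 240, wait_s = 60,
                         measure_s = 300, n_cycles = 12,
                         system_volume_l = 0.657,
                         background_rate_start = 0,
                         background_rate_end = 0,
                         o2_noise_sd_percent_sat = 0,
                         diel_amplitude = 0.3,
                         mmr_plateau_s = 90, mmr_decay_tau_s = 300,
                         mmr_duration_s = 600,
                         drawdown_floor_percent_sat = 2,
                         seed = 1L) {
  cfg <- list(
    sample_rate_hz = sample_rate_hz, flush_s = flush_s, wait_s = wait_s,
    measure_s = measure_s, n_cycles = n_cycles,
    system_volume_l = system_volume_l,
    background_rate_start = background_rate_start,
    background_rate_end = background_rate_end,
    o2_noise_sd_percent_sat = o2_noise_sd_percent_sat,
    diel_amplitude = diel_amplitude,
    mmr_plateau_s = mmr_plateau_s, mmr_decay_tau_s = mmr_decay_tau_s,
    mmr_duration_s = mmr_duration_s,
    drawdown_floor_percent_sat = drawdown_floor_percent_sat,
    seed = as.integer(seed)
  )
  nums <- unlist(cfg[setdiff(names(cfg), "seed")])
  if (any(!is.finite(nums))) abort("Trace config values must be finite.")
  for (nm in c("sample_rate_hz", "flush_s", "wait_s", "measure_s",
               "n_cycles", "system_volume_l", "mmr_plateau_s",
               "mmr_decay_tau_s", "mmr_duration_s")) {
    if (cfg[[nm]] <= 0) abort(sprintf("`%s` must be > 0.", nm))
  }
  if (o2_noise_sd_percent_sat < 0 || diel_amplitude < 0) {
    abort("Noise and diel amplitude must be >= 0.")
  }
  structure(cfg, class = "trace_config")
}
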