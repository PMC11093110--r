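# cumulative integral of the age-declining SGR, percent-days
cumulative_sgr <- function(t_days, sgr0, decay) {
  # sgr(s) = sgr0 * max(0, 1 - decay * s); integrate analytically
  t_star <- if (decay > 0) 1 / decay else Inf
  t_eff <- pmin(t_days, t_star)
  sgr0 * (t_eff - decay * t_eff^2 / 2)
}

#' Generate a synthetic fish cohort with latent ground truth
#'
#' Simulates the rearing experiment described by a [cohort_config()]: each
#' fish draws an initial mass, grows exponentially with an age-declining,
#' temperature-penalized SGR, and carries latent (true) gill components,
#' GSA, RMR and MMR sampled around the allometric lines of a
#' [scaling_truth()]. Latent GSA is the exact product of the latent
#' components. Each fish's random stream is derived from the global seed and
#' its id, so the same config always yields the same table and subsetting
#' the cohort leaves other fish unchanged.
#'
#' @param config A [cohort_config()].
#' @param truth A [scaling_truth()].
#' @return Tibble with one row per fish x time point (day 0 plus each
#'   configured time point): `fish_id`, `temperature_c`, `timepoint_days`,
#'   `mass_g`, `fork_length_mm`, `sampled` (TRUE at the fish's lethal
#'   sampling time point), latent `lfil_true`, `nlam_true`, `alam_true`,
#'   `gsa_true`, `rmr_true`, `mmr_true`, `pcrit_true`.
#' @export
generate_cohort <- function(config, truth) {
  if (!inherits(config, "cohort_config")) {
    abort("`config` must be a cohort_config().")
  }
  if (!inherits(truth, "scaling_truth")) {
    abort("`truth` must be a scaling_truth().")
  }
  days <- sort(unique(c(0, config$timepoints_days)))
  sample_days <- sort(config$timepoints_days)
  purrr::map_dfr(config$temperatures_c, function(tc) {
    f_t <- 1 - config$sgr_temperature_penalty *
      (tc - config$reference_temperature_c)
    purrr::map_dfr(seq_len(config$n_per_temperature), function(i) {
      fish_id <- sprintf("T%02d_F%03d", round(tc), i)
      lethal_day <- sample_days[(i - 1L) %% length(sample_days) + 1L]
      with_seed(derive_seed(config$seed, fish_id), {
        m0 <- max(0.2, rnorm(1, config$initial_mass_g_mean,
                             config$initial_mass_g_sd))
        growth <- cumulative_sgr(days, config$sgr_base_percent_per_day * f_t,
                                 config$sgr_age_decay_per_day)
        mass <- m0 * exp(growth / 100) *
          10^c(0, rnorm(length(days) - 1L, 0, config$mass_noise_sd_log10))
        lm10 <- log10(mass)
        eps <- matrix(rnorm(5L * length(days), 0,
                            config$trait_noise_sd_log10),
                      nrow = length(days))
        lfil <- 10^(truth$a_lfil + truth$b_lfil * lm10 + eps[, 1L])
        nlam <- 10^(truth$a_nlam + truth$b_nlam * lm10 + eps[, 2L])
        alam <- 10^(truth$a_alam + truth$b_alam * lm10 + eps[, 3L])
        rmr <- 10^(truth$a_rmr + truth$b_rmr * lm10 + eps[, 4L])
        mmr <- 10^(truth$a_mmr + truth$b_mmr * lm10 + eps[, 5L])
        k_true <- rnorm(1, 1.0, 0.05)
        tibble(
          fish_id = fish_id,
          temperature_c = tc,
          timepoint_days = days,
          mass_g = mass,
          fork_length_mm = 10 * (100 * mass / k_true)^(1 / 3.085),
          sampled = days == lethal_day,
          lfil_true = lfil,
          nlam_true = nlam,
          alam_true = alam,
          gsa_true = lfil * nlam * alam,
          rmr_true = rmr,
          mmr_true = pmax(mmr, 1.2 * rmr),
          pcrit_true = 25
        )
      })
    })
  })
}
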