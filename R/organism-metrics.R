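#' Specific growth rate
#'
#' Instantaneous (exponential) specific growth rate over an interval:
#' `SGR = 100 * (ln M2 - ln M1) / (t2 - t1)`, in percent body mass per day.
#'
#' @param m1_g,m2_g Body masses (g) at the start and end of the interval.
#' @param t1_days,t2_days Interval bounds in days (`t2 > t1`).
#' @return SGR in percent per day (vectorized).
#' @examples
#' specific_growth_rate(2.62, 203.43, 0, 240)
#' @export
specific_growth_rate <- function(m1_g, m2_g, t1_days, t2_days) {
  assert_positive(m1_g, "m1_g")
  assert_positive(m2_g, "m2_g")
  if (any(t2_days <= t1_days)) abort("`t2_days` must exceed `t1_days`.")
  100 * (log(m2_g) - log(m1_g)) / (t2_days - t1_days)
}

#' Per-fish growth intervals with SGR
#'
#' Orders each fish's records by time point and computes the specific growth
#' rate over every consecutive pair of measurements.
#'
#' @param fish Fish-record data frame with `fish_id`, `timepoint_days`,
#'   `mass_g` (and optionally `temperature_c`, carried through).
#' @return Tibble with one row per fish x interval: `fish_id`, `t1_days`,
#'   `t2_days`, `m1_g`, `m2_g`, `sgr_percent_per_day`.
#' @export
growth_intervals <- function(fish) {
  assert_columns(fish, c("fish_id", "timepoint_days", "mass_g"), "fish")
  carry <- intersect("temperature_c", names(fish))
  fish |>
    dplyr::arrange(.data$fish_id, .data$timepoint_days) |>
    dplyr::group_by(.data$fish_id) |>
    dplyr::reframe(
      dplyr::across(dplyr::all_of(carry), dplyr::first),
      t1_days = .data$timepoint_days[-dplyr::n()],
      t2_days = .data$timepoint_days[-1L],
      m1_g = .data$mass_g[-dplyr::n()],
      m2_g = .data$mass_g[-1L]
    ) |>
    dplyr::filter(.data$t2_days > .data$t1_days) |>
    dplyr::mutate(
      sgr_percent_per_day = specific_growth_rate(
        .data$m1_g, .data$m2_g, .data$t1_days, .data$t2_days
      )
    )
}

#' Relative condition factor
#'
#' `K = 100 * M / L^exponent`, with mass in grams and fork length in cm. The
#' default exponent 3.085 is the empirical length-mass regression exponent
#' for the study population; with exponent 3 this is Fulton's K.
#'
#' @param mass_g Body mass in grams (> 0).
#' @param fork_length_cm Fork length in cm (> 0).
#' @param exponent Length exponent (default 3.085).
#' @return Condition factor (vectorized).
#' @examples
#' condition_factor(10, 10) # 100 * 10 / 10^3.085
#' @export
condition_factor <- function(mass_g, fork_length_cm, exponent = 3.085) {
  assert_positive(mass_g, "mass_g")
  assert_positive(fork_length_cm, "fork_length_cm")
  100 * mass_g / fork_length_cm^exponent
}

#' Fold change in mean body mass
#'
#' @param final_mean_g,initial_mean_g Treatment mean masses (> 0).
#' @return `final / initial` (dimensionless).
#' @examples
#' fold_change(203.43, 2.62) # > 77
#' @export
fold_change <- function(final_mean_g, initial_mean_g) {
  assert_positive(final_mean_g, "final_mean_g")
  assert_positive(initial_mean_g, "initial_mean_g")
  final_mean_g / initial_mean_g
}

#' Treatment-level growth summaries
#'
#' Mean, standard deviation, standard error and n of body mass per
#' temperature treatment and time point.
#'
#' @param fish Fish-record data frame with `temperature_c`,
#'   `timepoint_days`, `mass_g`.
#' @return Tibble with one row per treatment x time point.
#' @export
summarize_growth <- function(fish) {
  assert_columns(fish, c("temperature_c", "timepoint_days", "mass_g"), "fish")
  fish |>
    dplyr::group_by(.data$temperature_c, .data$timepoint_days) |>
    dplyr::summarise(
      mean_mass_g = mean(.data$mass_g),
      sd_mass_g = sd(.data$mass_g),
      sem_mass_g = sd(.data$mass_g) / sqrt(dplyr::n()),
      n = dplyr::n(),
      .groups = "drop"
    )
}
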