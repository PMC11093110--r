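#' Total filament length from binned counts
#'
#' Filaments on the eight right-side hemibranchs are grouped into bins; the
#' median filament of each bin stands for all filaments in it. Total length
#' is the sum of `filament_count * median_filament_length_mm` over all bins,
#' doubled to account for the unmeasured left side of the head.
#'
#' @param bins Data frame of gill bins with `filament_count` and
#'   `median_filament_length_mm`.
#' @return Total filament length, L_fil, in mm (both sides of the head).
#' @examples
#' total_filament_length(data.frame(
#'   filament_count = c(12, 10), median_filament_length_mm = c(5, 8)
#' )) # 2 * (60 + 80) = 280
#' @export
total_filament_length <- function(bins) {
  assert_columns(bins, c("filament_count", "median_filament_length_mm"),
                 "bins")
  if (nrow(bins) == 0L) abort("`bins` is empty.")
  if (any(bins$filament_count < 1)) abort("Filament counts must be >= 1.")
  assert_positive(bins$median_filament_length_mm, "median_filament_length_mm")
  2 * sum(bins$filament_count * bins$median_filament_length_mm)
}

# per-bin intermediates on the reference hemibranch: filament length per bin,
# one-sided mean lamellar frequency, one-sided lamellae count per bin
reference_bin_stats <- function(bins, reference_hemibranch) {
  assert_columns(bins, c(
    "hemibranch_id", "filament_count", "median_filament_length_mm",
    "lamellar_freq_base_per_mm", "lamellar_freq_tip_per_mm"
  ), "bins")
  ref <- bins[bins$hemibranch_id == reference_hemibranch, , drop = FALSE]
  if (nrow(ref) == 0L) {
    abort(sprintf("No bins on reference hemibranch %s.", reference_hemibranch))
  }
  missing <- is.na(ref$lamellar_freq_base_per_mm) |
    is.na(ref$lamellar_freq_tip_per_mm)
  if (any(missing)) {
    warn(sprintf(
      "%d bin(s) on the reference hemibranch missing base or tip lamellar frequency; excluded.",
      sum(missing)
    ))
    ref <- ref[!missing, , drop = FALSE]
  }
  if (nrow(ref) == 0L) abort("No usable bins on the reference hemibranch.")
  ref |>
    dplyr::mutate(
      bin_filament_length_mm =
        .data$filament_count * .data$median_filament_length_mm,
      mean_freq_one_sided =
        (.data$lamellar_freq_base_per_mm + .data$lamellar_freq_tip_per_mm) / 2,
      lamellae_one_sided =
        .data$mean_freq_one_sided * .data$bin_filament_length_mm
    )
}

#' Lamellar frequency on the reference hemibranch
#'
#' Base and tip lamellar-frequency measurements on each bin's median filament
#' are averaged, weighted by the total filament length of the bin, and summed
#' over bins; dividing by the total filament length of the hemibranch gives
#' the mean one-sided frequency, which is doubled because lamellae sit on
#' both sides of a filament. Bins missing a base or tip measurement are
#' excluded with a warning.
#'
#' @param bins Data frame of gill bins (see [read_gill_bins()] schema).
#' @param reference_hemibranch Hemibranch carrying the lamellar measurements
#'   (default 4: the posterior hemibranch of the second gill arch).
#' @return Lamellar frequency, n_lam, in lamellae per mm (both sides of the
#'   filament).
#' @export
lamellar_frequency <- function(bins, reference_hemibranch = 4) {
  ref <- reference_bin_stats(bins, reference_hemibranch)
  2 * sum(ref$lamellae_one_sided) / sum(ref$bin_filament_length_mm)
}

#' Mean bilateral lamellar area on the reference hemibranch
#'
#' Per bin, the bilateral lamellar areas traced at the tip, middle and base
#' of the median filament are averaged; bin means are then weighted by the
#' number of lamellae in each bin (frequency times bin filament length) and
#' combined into a hemibranch-wide mean.
#'
#' @inheritParams lamellar_frequency
#' @return Mean bilateral lamellar area, A_lam, in mm^2.
#' @export
mean_lamellar_area <- function(bins, reference_hemibranch = 4) {
  assert_columns(bins, c(
    "lamellar_area_tip_mm2", "lamellar_area_mid_mm2", "lamellar_area_base_mm2"
  ), "bins")
  ref <- reference_bin_stats(bins, reference_hemibranch)
  area_mean <- (ref$lamellar_area_tip_mm2 + ref$lamellar_area_mid_mm2 +
                  ref$lamellar_area_base_mm2) / 3
  total_lamellae <- sum(ref$lamellae_one_sided)
  if (total_lamellae <= 0) {
    abort("Zero lamellae on the reference hemibranch.")
  }
  sum(area_mean * ref$lamellae_one_sided) / total_lamellae
}

#' Total gill surface area
#'
#' GSA is the product of total filament length (both sides of the head),
#' lamellar frequency (both sides of the filament) and mean bilateral
#' lamellar area. Because the relation is a pure product, log10 GSA is the
#' exact sum of the component logs, which is what makes fitted allometric
#' slopes of the components add up to the GSA slope.
#'
#' @param l_fil_mm Total filament length in mm.
#' @param n_lam_per_mm Lamellar frequency in mm^-1.
#' @param a_lam_mm2 Mean bilateral lamellar area in mm^2.
#' @return GSA in mm^2.
#' @export
gill_surface_area <- function(l_fil_mm, n_lam_per_mm, a_lam_mm2) {
  if (any(l_fil_mm <= 0) || any(n_lam_per_mm <= 0) || any(a_lam_mm2 <= 0)) {
    abort("All GSA components must be > 0.")
  }
  l_fil_mm * n_lam_per_mm * a_lam_mm2
}

#' Aggregate bin-level gill measurements per fish
#'
#' Runs the full morphometric aggregation for every fish in a bin-level
#' table: total filament length over all hemibranchs, lamellar frequency and
#' mean lamellar area on the reference hemibranch, and their product, GSA.
#'
#' @param bins Bin-level table with a `fish_id` column plus the gill-bin
#'   schema (see [read_gill_bins()]).
#' @param reference_hemibranch Hemibranch used for lamellar metrics
#'   (default 4).
#' @return Tibble with one row per fish: `fish_id`,
#'   `total_filament_length_mm`, `lamellar_frequency_per_mm`,
#'   `mean_lamellar_area_mm2`, `gsa_mm2`.
#' @export
aggregate_gills <- function(bins, reference_hemibranch = 4) {
  assert_columns(bins, "fish_id", "bins")
  bins |>
    dplyr::group_by(.data$fish_id) |>
    dplyr::group_modify(function(df, key) {
      l_fil <- total_filament_length(df)
      n_lam <- lamellar_frequency(df, reference_hemibranch)
      a_lam <- mean_lamellar_area(df, reference_hemibranch)
      tibble(
        total_filament_length_mm = l_fil,
        lamellar_frequency_per_mm = n_lam,
        mean_lamellar_area_mm2 = a_lam,
        gsa_mm2 = gill_surface_area(l_fil, n_lam, a_lam)
      )
    }) |>
    dplyr::ungroup()
}
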