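#' Generate bin-level gill measurements for synthetic fish
#'
#' Lays out the morphometric measurement scheme (8 hemibranchs on the right
#' side of the head, 5-7 bins per hemibranch, ~12 filaments per bin) and
#' fills it with measurements that, pushed back through
#' [aggregate_gills()], recover each fish's latent `lfil_true`,
#' `nlam_true` and `alam_true` exactly at zero noise and within the stated
#' measurement noise otherwise. Lamellar frequencies and areas are generated
#' only on the reference hemibranch, mirroring how gills are actually
#' measured; frequencies are stored one-sided, areas bilateral.
#'
#' @param fish Fish records (rows of [generate_cohort()] output) carrying
#'   `fish_id` and the latent gill components.
#' @param noise Log10 sd of multiplicative measurement noise applied to
#'   every length, frequency and area (default 0).
#' @param seed Integer seed (combined with each fish id).
#' @param reference_hemibranch Hemibranch carrying lamellar measurements
#'   (default 4).
#' @return Bin-level tibble in the [read_gill_bins()] schema.
#' @export
generate_gill_bins <- function(fish, noise = 0, seed = 1L,
                               reference_hemibranch = 4) {
  assert_columns(fish, c("fish_id", "lfil_true", "nlam_true", "alam_true"),
                 "fish")
  if (noise < 0) abort("`noise` must be >= 0.")
  jitter10 <- function(n) 10^rnorm(n, 0, noise)
  purrr::map_dfr(seq_len(nrow(fish)), function(r) {
    row <- fish[r, ]
    with_seed(derive_seed(seed, paste0(row$fish_id, "/gills")), {
      layout <- purrr::map_dfr(1:8, function(h) {
        n_bins <- sample(5:7, 1L)
        tibble(
          hemibranch_id = h,
          bin_id = seq_len(n_bins),
          filament_count = pmax(1L, pmin(18L, stats::rpois(n_bins, 12))),
          # filaments longest mid-hemibranch, scaled per hemibranch
          raw_len = runif(1, 0.8, 1.2) *
            (1 + 0.3 * sin(pi * (seq_len(n_bins) - 0.5) / n_bins))
        )
      })
      # scale lengths so the doubled sum reproduces latent L_fil, then noise
      s_len <- (row$lfil_true / 2) /
        sum(layout$filament_count * layout$raw_len)
      layout$median_filament_length_mm <-
        layout$raw_len * s_len * jitter10(nrow(layout))
      layout$bin_len <-
        layout$filament_count * layout$median_filament_length_mm

      ref <- layout$hemibranch_id == reference_hemibranch
      n_ref <- sum(ref)
      # one-sided frequencies: base slightly above tip, rescaled so the
      # length-weighted mean equals latent n_lam / 2
      base_raw <- runif(n_ref, 0.95, 1.05)
      tip_raw <- base_raw * runif(n_ref, 0.9, 1.0)
      wmean <- sum((base_raw + tip_raw) / 2 * layout$bin_len[ref]) /
        sum(layout$bin_len[ref])
      s_freq <- (row$nlam_true / 2) / wmean
      freq_base <- base_raw * s_freq * jitter10(n_ref)
      freq_tip <- tip_raw * s_freq * jitter10(n_ref)
      # bilateral areas at tip/mid/base, rescaled so the lamellae-weighted
      # mean of per-bin means equals latent A_lam
      mid_raw <- runif(n_ref, 0.9, 1.1)
      tip_a_raw <- mid_raw * runif(n_ref, 0.8, 1.0)
      base_a_raw <- mid_raw * runif(n_ref, 1.0, 1.2)
      lamellae <- (freq_base + freq_tip) / 2 * layout$bin_len[ref]
      wmean_a <- sum((tip_a_raw + mid_raw + base_a_raw) / 3 * lamellae) /
        sum(lamellae)
      s_area <- row$alam_true / wmean_a
      na_ref <- rep(NA_real_, nrow(layout))
      out <- tibble(
        fish_id = row$fish_id,
        hemibranch_id = layout$hemibranch_id,
        bin_id = layout$bin_id,
        filament_count = layout$filament_count,
        median_filament_length_mm = layout$median_filament_length_mm,
        lamellar_freq_base_per_mm = na_ref,
        lamellar_freq_tip_per_mm = na_ref,
        lamellar_area_tip_mm2 = na_ref,
        lamellar_area_mid_mm2 = na_ref,
        lamellar_area_base_mm2 = na_ref
      )
      out$lamellar_freq_base_per_mm[ref] <- freq_base
      out$lamellar_freq_tip_per_mm[ref] <- freq_tip
      out$lamellar_area_tip_mm2[ref] <- tip_a_raw * s_area * jitter10(n_ref)
      out$lamellar_area_mid_mm2[ref] <- mid_raw * s_area * jitter10(n_ref)
      out$lamellar_area_base_mm2[ref] <- base_a_raw * s_area * jitter10(n_ref)
      out
    })
  })
}
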