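# header normalization: trim whitespace, collapse internal runs, lowercase
normalize_headers <- function(df) {
  names(df) <- gsub("\\s+", "_", trimws(tolower(names(df))))
  df
}

read_validated_csv <- function(path, required, numeric_cols, what) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  df <- normalize_headers(df)
  assert_columns(df, required, what)
  for (col in intersect(numeric_cols, names(df))) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      parsed <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & is.na(parsed))
      if (length(bad) > 0L) {
        abort(sprintf("%s: non-numeric value(s) in `%s` at row(s): %s.",
                      what, col,
                      paste(utils::head(bad, 5L), collapse = ", ")))
      }
      df[[col]] <- parsed
    }
  }
  as_tibble(df)
}

#' Read fish records from CSV
#'
#' Expects columns `fish_id`, `temperature_c`, `timepoint_days`, `mass_g`
#' and optionally `fork_length_mm`. Headers are normalized (case,
#' whitespace). Rows with non-positive mass, and duplicated
#' `fish_id` x `timepoint_days` combinations, are rejected with row numbers.
#'
#' @param path CSV path (UTF-8, `.` decimal separator).
#' @return Validated tibble of fish records.
#' @export
read_fish_records <- function(path) {
  df <- read_validated_csv(
    path,
    required = c("fish_id", "temperature_c", "timepoint_days", "mass_g"),
    numeric_cols = c("temperature_c", "timepoint_days", "mass_g",
                     "fork_length_mm"),
    what = "fish records"
  )
  bad <- which(!is.finite(df$mass_g) | df$mass_g <= 0)
  if (length(bad) > 0L) {
    abort(sprintf("fish records: non-positive mass at row(s): %s.",
                  paste(utils::head(bad, 5L), collapse = ", ")))
  }
  dup <- duplicated(df[c("fish_id", "timepoint_days")])
  if (any(dup)) {
    abort(sprintf(
      "fish records: duplicate fish_id x timepoint at row(s): %s.",
      paste(utils::head(which(dup), 5L), collapse = ", ")
    ))
  }
  df
}

#' Read oxygen traces from CSV
#'
#' Long format with columns `fish_id`, `time_s`, `o2_percent_sat` and
#' optionally `phase`, `kind`, `chamber_id`. Time must be strictly
#' increasing within each fish (x kind).
#'
#' @param path CSV path.
#' @return Validated tibble of trace samples.
#' @export
read_oxygen_traces <- function(path) {
  df <- read_validated_csv(
    path,
    required = c("fish_id", "time_s", "o2_percent_sat"),
    numeric_cols = c("time_s", "o2_percent_sat"),
    what = "oxygen traces"
  )
  if (any(!is.finite(df$o2_percent_sat))) {
    abort("oxygen traces: non-finite saturation values present.")
  }
  key_cols <- intersect(c("fish_id", "kind"), names(df))
  ok <- df |>
    dplyr::group_by(dplyr::across(dplyr::all_of(key_cols))) |>
    dplyr::summarise(
      sorted = !is.unsorted(.data$time_s, strictly = TRUE),
      .groups = "drop"
    )
  if (!all(ok$sorted)) {
    abort("oxygen traces: time_s not strictly increasing within a trace.")
  }
  df
}

#' Read bin-level gill measurements from CSV
#'
#' Expects the gill-bin schema: `fish_id`, `hemibranch_id`, `bin_id`,
#' `filament_count`, `median_filament_length_mm`, and (on the reference
#' hemibranch) `lamellar_freq_base_per_mm`, `lamellar_freq_tip_per_mm`,
#' `lamellar_area_tip_mm2`, `lamellar_area_mid_mm2`,
#' `lamellar_area_base_mm2`. Frequencies are one-sided counts per mm; areas
#' are bilateral, in mm^2 (stated here to prevent double-doubling).
#'
#' @param path CSV path.
#' @return Validated tibble of gill bins.
#' @export
read_gill_bins <- function(path) {
  df <- read_validated_csv(
    path,
    required = c("fish_id", "hemibranch_id", "bin_id", "filament_count",
                 "median_filament_length_mm"),
    numeric_cols = c("hemibranch_id", "bin_id", "filament_count",
                     "median_filament_length_mm",
                     "lamellar_freq_base_per_mm", "lamellar_freq_tip_per_mm",
                     "lamellar_area_tip_mm2", "lamellar_area_mid_mm2",
                     "lamellar_area_base_mm2"),
    what = "gill bins"
  )
  bad <- which(df$filament_count < 1 | df$median_filament_length_mm <= 0)
  if (length(bad) > 0L) {
    abort(sprintf(
      "gill bins: invalid filament count or length at row(s): %s.",
      paste(utils::head(bad, 5L), collapse = ", ")
    ))
  }
  df
}

#' Write a tibble to CSV with 6 significant digits
#'
#' @param data Data frame to write.
#' @param path Destination path.
#' @return `data`, invisibly.
#' @export
write_result_csv <- function(data, path) {
  out <- dplyr::mutate(
    data,
    dplyr::across(dplyr::where(is.double), ~ signif(.x, 6))
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(data)
}

#' Read a pipeline run configuration from YAML
#'
#' The YAML mirrors [run_pipeline()]'s arguments: either a `simulate` block
#' (with optional `cohort`, `truth`, `trace` sub-blocks passed to
#' [cohort_config()], [scaling_truth()] and [trace_config()]) or a `paths`
#' block (`fish`, `gills`, `traces` CSVs), plus optional
#' `reference_hemibranch`, `reference_mass_g`, `r2_threshold`,
#' `mmr_window_s`, `chamber_volumes_l` (named by timepoint day), `seed` and
#' `output_dir`.
#'
#' @param path YAML file path.
#' @return A `run_config` list for [run_pipeline()].
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$simulate) && is.null(cfg$paths)) {
    abort("Config must contain a `simulate` block or a `paths` block.")
  }
  cfg
}
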