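#' Relative expression by the delta-Ct method
#'
#' Computes fold changes from qPCR cycle-threshold tables using the standard
#' delta-Ct method with a fixed amplification efficiency of 2: for each record
#' `dCt = ct_target - ct_reference`, and the fold change of a sample relative
#' to the calibrator is `2^-(dCt_sample - dCt_calibrator)`. When a sample x
#' target combination has technical replicates, delta-Ct values are averaged
#' before exponentiation.
#'
#' @param ct data frame with columns `sample_id`, `target_gene`,
#'   `reference_gene`, `ct_target`, `ct_reference` (cycles, all > 0).
#' @param calibrator `sample_id` of the calibrator sample (e.g. the untreated
#'   wild type).
#' @return tibble with one row per sample x target: `delta_ct`,
#'   `delta_delta_ct`, `fold_change`, `n_replicates`.
#' @export
relative_expression <- function(ct, calibrator) {
  assert_columns(ct, c("sample_id", "target_gene", "reference_gene",
                       "ct_target", "ct_reference"), "Ct table")
  if (any(ct$ct_target <= 0) || any(ct$ct_reference <= 0)) {
    pb_abort("Ct values must be positive cycle numbers", "pb_bad_ct")
  }
  if (!calibrator %in% ct$sample_id) {
    pb_abort("`calibrator` not found among sample_id values", "pb_missing_calibrator")
  }
  per_sample <- ct |>
    dplyr::mutate(delta_ct = .data$ct_target - .data$ct_reference) |>
    dplyr::group_by(.data$sample_id, .data$target_gene, .data$reference_gene) |>
    dplyr::summarise(delta_ct = mean(.data$delta_ct),
                     n_replicates = dplyr::n(), .groups = "drop")
  cal <- per_sample |>
    dplyr::filter(.data$sample_id == calibrator) |>
    dplyr::select("target_gene", "reference_gene", cal_delta_ct = "delta_ct")
  missing_cal <- dplyr::anti_join(per_sample, cal,
                                  by = c("target_gene", "reference_gene"))
  if (nrow(missing_cal) > 0) {
    pb_abort("calibrator lacks measurements for some target/reference pairs",
             "pb_missing_calibrator")
  }
  per_sample |>
    dplyr::inner_join(cal, by = c("target_gene", "reference_gene")) |>
    dplyr::mutate(
      delta_delta_ct = .data$delta_ct - .data$cal_delta_ct,
      fold_change = 2^(-.data$delta_delta_ct)
    ) |>
    dplyr::select("sample_id", "target_gene", "reference_gene", "delta_ct",
                  "delta_delta_ct", "fold_change", "n_replicates")
}

#' Marker-normalized fluorescence intensity
#'
#' Normalizes a signal channel (e.g. a GFP fusion) to a constitutive marker
#' channel measured in the same segmented object: the ratio of median signal
#' to median marker intensity. Objects with zero marker intensity are excluded
#' with a reason rather than producing infinite ratios.
#'
#' @param intensities data frame with columns `object_id`, `median_signal`,
#'   `median_marker` (arbitrary fluorescence units, >= 0); any extra columns
#'   (e.g. `compartment`) are carried through.
#' @return input tibble with `ratio`, `excluded`, `exclude_reason` columns.
#' @export
normalize_intensity <- function(intensities) {
  assert_columns(intensities, c("object_id", "median_signal", "median_marker"),
                 "intensity table")
  if (any(intensities$median_signal < 0) || any(intensities$median_marker < 0)) {
    pb_abort("intensities must be non-negative", "pb_bad_intensity")
  }
  intensities |>
    as_tibble() |>
    dplyr::mutate(
      excluded = .data$median_marker == 0,
      exclude_reason = dplyr::if_else(.data$excluded, "zero_marker", NA_character_),
      ratio = dplyr::if_else(.data$excluded, NA_real_,
                             .data$median_signal / .data$median_marker)
    )
}

#' Per-group replicate summaries with t-tests against a reference group
#'
#' @param data data frame of replicate measurements.
#' @param value column holding the measurement (tidy-eval).
#' @param group column defining the groups (tidy-eval).
#' @param reference value of `group` to test every other group against.
#' @param var_equal use the pooled-variance Student t-test (default) or the
#'   Welch variant.
#' @return tibble with one row per group: `mean`, `sd`, `n`, and `p_value`
#'   from a two-sided two-sample t-test against the reference (NA for the
#'   reference itself and for groups with fewer than 2 values, which are
#'   summarized but not tested).
#' @export
replicate_summary <- function(data, value, group, reference, var_equal = TRUE) {
  value <- rlang::enquo(value)
  group <- rlang::enquo(group)
  df <- data |>
    dplyr::transmute(group = !!group, value = !!value)
  if (!reference %in% df$group) {
    pb_abort("`reference` group not present in the data", "pb_missing_reference")
  }
  ref_values <- df$value[df$group == reference]
  df |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      mean = mean(.data$value),
      sd = stats::sd(.data$value),
      n = dplyr::n(),
      p_value = if (dplyr::cur_group()$group == reference ||
                    dplyr::n() < 2 || length(ref_values) < 2) {
        NA_real_
      } else {
        stats::t.test(.data$value, ref_values, var.equal = var_equal)$p.value
      },
      .groups = "drop"
    )
}
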