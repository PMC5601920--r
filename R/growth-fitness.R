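#' Area under the growth curve
#'
#' Converts OD600 time series into scalar fitness values by trapezoidal
#' integration of OD over time. This is the raw epsilon of the
#' growth-based fitness measure, in OD x hours.
#'
#' @param curves data frame with columns `strain_id`, `condition`,
#'   `replicate`, `time_h`, `od`. Within each curve times must be strictly
#'   increasing, ODs non-negative, and at least 2 points present.
#' @return tibble with one row per strain x condition x replicate:
#'   `epsilon_raw` (the AUC) and `t_max` (the final sampled time, used to
#'   guard against comparing integrals over unequal durations).
#' @examples
#' curves <- tibble::tibble(
#'   strain_id = "wt", condition = "untreated", replicate = 1L,
#'   time_h = 0:10, od = rep(0.5, 11)
#' )
#' growth_auc(curves) # epsilon_raw = 5
#' @export
growth_auc <- function(curves) {
  assert_columns(curves, c("strain_id", "condition", "replicate", "time_h", "od"),
                 "growth curves")
  if (any(curves$od < 0)) {
    pb_abort("OD values must be non-negative", "pb_bad_curve")
  }
  curves |>
    dplyr::group_by(.data$strain_id, .data$condition, .data$replicate) |>
    dplyr::summarise(
      epsilon_raw = {
        t <- .data$time_h
        y <- .data$od
        if (length(t) < 2) pb_abort("a growth curve needs >= 2 timepoints", "pb_bad_curve")
        if (any(diff(t) <= 0)) pb_abort("times must be strictly increasing", "pb_bad_curve")
        sum(diff(t) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
      },
      t_max = max(.data$time_h),
      .groups = "drop"
    )
}

#' Control-normalized relative fitness
#'
#' Normalizes each strain's AUC fitness to the mean AUC of the control strain
#' measured in the same condition, yielding the dimensionless relative epsilon
#' used by the genetic-interaction model.
#'
#' @param fitness tibble from [growth_auc()].
#' @param control `strain_id` of the control strain.
#' @return input rows (control included) with an `epsilon_rel` column.
#'   Curves of unequal duration within a condition are an error: integrals
#'   over different time windows are not comparable.
#' @export
relative_fitness <- function(fitness, control) {
  assert_columns(fitness, c("strain_id", "condition", "replicate",
                            "epsilon_raw"), "fitness table")
  if (!control %in% fitness$strain_id) {
    pb_abort("`control` strain not present in the fitness table",
             "pb_missing_control")
  }
  if ("t_max" %in% names(fitness)) {
    bad <- fitness |>
      dplyr::group_by(.data$condition) |>
      dplyr::summarise(mismatch = dplyr::n_distinct(.data$t_max) > 1,
                       .groups = "drop")
    if (any(bad$mismatch)) {
      pb_abort(
        sprintf("curves have unequal durations within condition(s): %s",
                paste(bad$condition[bad$mismatch], collapse = ", ")),
        "pb_duration_mismatch"
      )
    }
  }
  ctrl <- fitness |>
    dplyr::filter(.data$strain_id == control) |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(control_mean = mean(.data$epsilon_raw), .groups = "drop")
  if (any(ctrl$control_mean == 0)) {
    pb_abort("control mean AUC is zero in at least one condition",
             "pb_zero_control")
  }
  fitness |>
    dplyr::inner_join(ctrl, by = "condition") |>
    dplyr::mutate(epsilon_rel = .data$epsilon_raw / .data$control_mean) |>
    dplyr::select(-"control_mean")
}

#' Growth as a percentage of a reference
#'
#' @param mutant_rel,reference_rel relative fitness values measured in the
#'   same condition.
#' @return `100 * mutant_rel / reference_rel`.
#' @export
percent_growth <- function(mutant_rel, reference_rel) {
  if (any(reference_rel == 0)) {
    pb_abort("reference relative fitness is zero", "pb_zero_reference")
  }
  100 * mutant_rel / reference_rel
}
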