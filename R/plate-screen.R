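#' Collapse replicated colonies to one size per strain
#'
#' Colony arrays carry each double mutant as a small block of adjacent
#' colonies (typically 2x2 in the quadruplicated 1536 format). This collapses
#' each complete block to a single size; strains whose block is incomplete are
#' flagged rather than silently averaged.
#'
#' @param plate long-format plate data with columns `plate_id`, `condition`,
#'   `replicate`, `row`, `col`, `strain_id`, `size`.
#' @param group_shape integer vector `c(rows, cols)` of the replicate block,
#'   default `c(2, 2)`.
#' @param method `"mean"` (default) or `"median"` aggregation within a block.
#' @return tibble with one row per plate x strain: `size` (NA when
#'   incomplete), `n_colonies`, `incomplete`.
#' @export
collapse_replicate_colonies <- function(plate, group_shape = c(2, 2),
                                        method = c("mean", "median")) {
  method <- match.arg(method)
  assert_columns(plate, c("plate_id", "condition", "replicate", "row", "col",
                          "strain_id", "size"), "plate grid")
  if (any(plate$size < 0, na.rm = TRUE)) {
    pb_abort("colony sizes must be non-negative", "pb_bad_plate")
  }
  if (anyDuplicated(plate[, c("plate_id", "row", "col")]) > 0) {
    pb_abort("duplicate (plate, row, col) positions", "pb_bad_plate")
  }
  expected_n <- prod(group_shape)
  agg <- if (method == "mean") mean else stats::median
  plate |>
    dplyr::group_by(.data$plate_id, .data$condition, .data$replicate,
                    .data$strain_id) |>
    dplyr::summarise(
      n_colonies = sum(!is.na(.data$size)),
      spread_ok = (max(.data$row) - min(.data$row) + 1) <= group_shape[1] &&
        (max(.data$col) - min(.data$col) + 1) <= group_shape[2],
      size = agg(.data$size, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      incomplete = .data$n_colonies != expected_n,
      size = dplyr::if_else(.data$incomplete, NA_real_, .data$size)
    ) |>
    (\(df) {
      if (any(!df$spread_ok)) {
        pb_abort("strain block positions are not contiguous within group_shape",
                 "pb_layout_error")
      }
      dplyr::select(df, -"spread_ok")
    })()
}

#' Fitness in drug as a colony-size ratio
#'
#' Fitness of each strain is the ratio of its (collapsed) colony size on the
#' drug plate to its size on the paired drug-free plate.
#'
#' @param no_drug,drug collapsed plate tibbles from
#'   [collapse_replicate_colonies()] for the same replicate set; the two
#'   plates must carry the same strains.
#' @return tibble of fitness records: `strain_id`, `replicate`, `plate_id`
#'   (drug plate), `size_no_drug`, `size_drug`, `fitness`, `excluded`,
#'   `exclude_reason`. Zero or missing no-drug size excludes the record.
#' @export
compute_fitness <- function(no_drug, drug) {
  for (df in list(no_drug, drug)) {
    assert_columns(df, c("plate_id", "replicate", "strain_id", "size",
                         "incomplete"), "collapsed plate")
  }
  key <- c("strain_id", "replicate")
  if (!setequal(
    do.call(paste, no_drug[key]),
    do.call(paste, drug[key])
  )) {
    pb_abort("no-drug and drug plates do not share the same strain layout",
             "pb_pairing_error")
  }
  nd <- dplyr::select(no_drug, dplyr::all_of(key), size_no_drug = "size",
                      incomplete_no_drug = "incomplete")
  dr <- dplyr::select(drug, dplyr::all_of(key), plate_id = "plate_id",
                      size_drug = "size", incomplete_drug = "incomplete")
  dplyr::inner_join(nd, dr, by = key) |>
    dplyr::mutate(
      exclude_reason = dplyr::case_when(
        .data$incomplete_no_drug | .data$incomplete_drug ~ "incomplete_group",
        .data$size_no_drug == 0 ~ "zero_no_drug_colony",
        TRUE ~ NA_character_
      ),
      excluded = !is.na(.data$exclude_reason),
      fitness = dplyr::if_else(.data$excluded, NA_real_,
                               .data$size_drug / .data$size_no_drug)
    ) |>
    dplyr::select("strain_id", "replicate", "plate_id", "size_no_drug",
                  "size_drug", "fitness", "excluded", "exclude_reason")
}

#' Remove strains with small colonies in the absence of drug
#'
#' Strains that already grow poorly without drug have unreliable fitness
#' ratios and are excluded before normalization. The threshold is either a
#' fraction of the no-drug plate median (default 50%) or an absolute size.
#'
#' @param records fitness records from [compute_fitness()].
#' @param threshold_rule a list, either
#'   `list(type = "fraction_of_median", value = 0.5)` or
#'   `list(type = "absolute", value = <size>)`.
#' @return `records` with additional exclusions
#'   (`exclude_reason = "small_no_drug_colony"`); the number excluded by this
#'   filter is attached as the `n_small_excluded` attribute.
#' @export
filter_small_colonies <- function(records,
                                  threshold_rule = list(type = "fraction_of_median",
                                                        value = 0.5)) {
  assert_columns(records, c("strain_id", "replicate", "size_no_drug",
                            "excluded"), "fitness records")
  if (!threshold_rule$type %in% c("fraction_of_median", "absolute")) {
    pb_abort("threshold_rule$type must be 'fraction_of_median' or 'absolute'",
             "pb_bad_rule")
  }
  records <- records |>
    dplyr::group_by(.data$replicate) |>
    dplyr::mutate(
      threshold = if (threshold_rule$type == "fraction_of_median") {
        threshold_rule$value *
          stats::median(.data$size_no_drug[!.data$excluded], na.rm = TRUE)
      } else {
        threshold_rule$value
      }
    ) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      small = !.data$excluded & .data$size_no_drug < .data$threshold,
      exclude_reason = dplyr::if_else(.data$small, "small_no_drug_colony",
                                      .data$exclude_reason),
      excluded = .data$excluded | .data$small,
      fitness = dplyr::if_else(.data$excluded, NA_real_, .data$fitness)
    )
  n_small <- sum(records$small)
  records <- dplyr::select(records, -"small", -"threshold")
  attr(records, "n_small_excluded") <- n_small
  records
}

#' Per-plate Z-score normalization
#'
#' Within each plate, a strain's Z-score is its fitness minus the plate mean
#' fitness, divided by the plate's sample standard deviation. This removes
#' plate and pinning artefacts: the Z-scores are invariant to any affine
#' rescaling of a plate's fitness values. Plates with zero variance are
#' flagged degenerate and yield missing Z-scores with a warning.
#'
#' @param records fitness records (after exclusion filters).
#' @param value name of the column to normalize: `"fitness"` (default) or
#'   `"size_drug"` for raw colony size.
#' @return tibble of `strain_id`, `replicate`, `plate_id`, `z`, `degenerate`.
#'   Excluded records propagate as missing Z.
#' @examples
#' recs <- tibble::tibble(
#'   strain_id = c("a", "b", "c"), replicate = 1L, plate_id = "p1",
#'   fitness = c(1, 2, 3), excluded = FALSE
#' )
#' zscore_per_plate(recs)$z # -1, 0, 1
#' @export
zscore_per_plate <- function(records, value = "fitness") {
  assert_columns(records, c("strain_id", "replicate", "plate_id", value,
                            "excluded"), "fitness records")
  out <- records |>
    dplyr::group_by(.data$plate_id, .data$replicate) |>
    dplyr::mutate(
      n_ok = sum(!.data$excluded),
      plate_mean = mean(.data[[value]][!.data$excluded]),
      plate_sd = stats::sd(.data[[value]][!.data$excluded]),
      degenerate = .data$n_ok < 2 | (!is.na(.data$plate_sd) & .data$plate_sd == 0),
      z = dplyr::if_else(
        .data$excluded | .data$degenerate, NA_real_,
        (.data[[value]] - .data$plate_mean) / .data$plate_sd
      )
    ) |>
    dplyr::ungroup()
  if (any(out$degenerate)) {
    warn(sprintf("%d plate(s) are degenerate (zero variance or < 2 usable records)",
                 dplyr::n_distinct(out$plate_id[out$degenerate])))
  }
  dplyr::select(out, "strain_id", "replicate", "plate_id", "z", "degenerate")
}

#' Call suppressor and synthetic-sick hits from replicate Z-scores
#'
#' Averages each strain's Z-score over replicate plates and calls hits at a
#' symmetric threshold: suppressors at `mean_z >= +z_threshold`,
#' synthetic-sick at `mean_z <= -z_threshold` (the screen used +/-1 over
#' three replicates). Strains with fewer than `min_replicates` usable
#' Z-scores are reported but left uncalled.
#'
#' @param zscores tibble from [zscore_per_plate()].
#' @param min_replicates minimum usable replicates for a call (default 2).
#' @param z_threshold hit threshold on the replicate-averaged Z (default 1).
#' @return tibble of `strain_id`, `mean_z`, `n_replicates`, `call` with
#'   `call` in `"suppressor"`, `"synthetic_sick"`, `"none"`, `"uncallable"`.
#' @export
call_hits <- function(zscores, min_replicates = 2, z_threshold = 1) {
  assert_columns(zscores, c("strain_id", "replicate", "z"), "Z-score table")
  assert_scalar_number(z_threshold, "z_threshold", min = 0)
  zscores |>
    dplyr::group_by(.data$strain_id) |>
    dplyr::summarise(
      mean_z = mean(.data$z, na.rm = TRUE),
      n_replicates = sum(!is.na(.data$z)),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      mean_z = dplyr::if_else(.data$n_replicates == 0, NA_real_, .data$mean_z),
      call = dplyr::case_when(
        .data$n_replicates < min_replicates ~ "uncallable",
        .data$mean_z >= z_threshold ~ "suppressor",
        .data$mean_z <= -z_threshold ~ "synthetic_sick",
        TRUE ~ "none"
      )
    )
}

#' Intersect suppressor calls from two screens
#'
#' Individual suppressor screens have a substantial false-positive rate, so
#' the analysis is restricted to suppressors recovered in both genetic
#' backgrounds.
#'
#' @param hits_a,hits_b hit tables from [call_hits()] over the same strain
#'   namespace.
#' @return tibble of strains called `"suppressor"` in both screens; per-screen
#'   suppressor counts and the intersection size are attached as the `counts`
#'   attribute.
#' @export
intersect_screens <- function(hits_a, hits_b) {
  for (df in list(hits_a, hits_b)) {
    assert_columns(df, c("strain_id", "call"), "hit table")
  }
  supp_a <- hits_a$strain_id[hits_a$call == "suppressor"]
  supp_b <- hits_b$strain_id[hits_b$call == "suppressor"]
  shared <- sort(intersect(supp_a, supp_b))
  out <- tibble(strain_id = shared)
  attr(out, "counts") <- c(n_a = length(supp_a), n_b = length(supp_b),
                           n_both = length(shared))
  out
}

#' Score a colony-array suppressor screen end to end
#'
#' Runs the full screen-scoring chain: collapse replicate colony blocks,
#' compute fitness in drug, remove small no-drug colonies, Z-score per plate,
#' and call hits from replicate-averaged Z-scores.
#'
#' @param plates long-format plate data covering both conditions and all
#'   replicate plates (columns as in [collapse_replicate_colonies()];
#'   `condition` must be `"no_drug"` / `"drug"`).
#' @param group_shape replicate colony block, default `c(2, 2)`.
#' @param small_colony_rule see [filter_small_colonies()].
#' @param min_replicates,z_threshold see [call_hits()].
#' @param zscore_on `"fitness"` (default) or `"size_drug"`.
#' @param collapse_method `"mean"` or `"median"`.
#' @param exclude_border drop colonies in the outermost rows/columns before
#'   scoring (off by default).
#' @return object of class `pb_screen`: a list with `fitness`, `zscores`,
#'   `hits` tibbles and a `summary` list of counts. Has [tidy()], [glance()]
#'   and [ggplot2::autoplot()] methods.
#' @export
score_screen <- function(plates, group_shape = c(2, 2),
                         small_colony_rule = list(type = "fraction_of_median",
                                                  value = 0.5),
                         min_replicates = 2, z_threshold = 1,
                         zscore_on = c("fitness", "size_drug"),
                         collapse_method = c("mean", "median"),
                         exclude_border = FALSE) {
  zscore_on <- match.arg(zscore_on)
  collapse_method <- match.arg(collapse_method)
  assert_columns(plates, c("plate_id", "condition", "replicate", "row", "col",
                           "strain_id", "size"), "plate data")
  if (!all(plates$condition %in% c("no_drug", "drug"))) {
    pb_abort("condition must be 'no_drug' or 'drug'", "pb_bad_plate")
  }
  if (exclude_border) {
    plates <- plates |>
      dplyr::filter(.data$row > min(.data$row), .data$row < max(.data$row),
                    .data$col > min(.data$col), .data$col < max(.data$col))
  }
  collapsed <- collapse_replicate_colonies(plates, group_shape, collapse_method)
  fitness <- compute_fitness(
    dplyr::filter(collapsed, .data$condition == "no_drug"),
    dplyr::filter(collapsed, .data$condition == "drug")
  ) |>
    filter_small_colonies(small_colony_rule)
  zscores <- zscore_per_plate(fitness, value = zscore_on)
  hits <- call_hits(zscores, min_replicates, z_threshold)
  out <- list(
    fitness = fitness,
    zscores = zscores,
    hits = hits,
    summary = list(
      n_strains = dplyr::n_distinct(fitness$strain_id),
      n_excluded_small = attr(fitness, "n_small_excluded"),
      n_excluded_total = sum(fitness$excluded),
      n_degenerate_plates = dplyr::n_distinct(
        zscores$plate_id[zscores$degenerate]),
      n_suppressor = sum(hits$call == "suppressor"),
      n_synthetic_sick = sum(hits$call == "synthetic_sick"),
      n_uncallable = sum(hits$call == "uncallable"),
      z_threshold = z_threshold
    )
  )
  class(out) <- "pb_screen"
  out
}

#' @export
print.pb_screen <- function(x, ...) {
  s <- x$summary
  cat("<pb_screen>\n")
  cat(sprintf("  strains scored: %d (excluded: %d, of which small no-drug: %d)\n",
              s$n_strains, s$n_excluded_total, s$n_excluded_small))
  cat(sprintf("  hits at |Z| >= %g: %d suppressor, %d synthetic sick (%d uncallable)\n",
              s$z_threshold, s$n_suppressor, s$n_synthetic_sick, s$n_uncallable))
  invisible(x)
}
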