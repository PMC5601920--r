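#' Configuration for simulated colony-array screens
#'
#' Describes a simulated suppressor screen in the condensed colony-array
#' format: each strain occupies a block of adjacent replicate colonies
#' (quadruplicate by default, i.e. 2x2 blocks on a 32x48 = 1536-position
#' plate), each replicate plate exists in a paired no-drug/drug version, and a
#' chosen set of strains is planted as suppressors by inflating their
#' drug-plate colony sizes.
#'
#' Colony sizes are in arbitrary units. Noise is multiplicative log-normal
#' (colonies cannot be negative), parameterized by its coefficient of
#' variation. Plate effects are a per-plate log-normal multiplier and edge
#' effects a fixed multiplicative boost for border positions; both cancel out
#' of the fitness ratio / per-plate Z-score chain by construction, which is
#' exactly the artefact-removal property the screen normalization relies on.
#'
#' The suppressor boost is calibrated so that the expected fitness Z-score of
#' a planted suppressor equals `suppressor_effect`: the fitness coefficient of
#' variation after collapsing a block of `replicate_sets` colonies on each of
#' the two plates is `noise_cv * sqrt(2 / replicate_sets)`, and the drug-plate
#' sizes of suppressors are multiplied by `1 + suppressor_effect * cv`. With
#' `noise_cv = 0` that displacement would vanish, so a fixed 5% boost per unit
#' of `suppressor_effect` is used instead, keeping planted truth separable in
#' the noiseless closed loop.
#'
#' @param n_plates plate pairs per replicate (strain universe spans all).
#' @param grid_rows,grid_cols plate dimensions (default 32 x 48).
#' @param replicate_sets colonies per strain, a perfect square (default 4).
#' @param n_replicate_plates replicate plate pairs (default 3).
#' @param baseline_size mean no-drug colony size, arbitrary units.
#' @param plate_effect_sd sd of the per-plate log-normal multiplier.
#' @param edge_effect multiplicative boost for border rows/columns.
#' @param noise_cv coefficient of variation of colony size.
#' @param drug_fitness baseline drug/no-drug size ratio of non-suppressors.
#' @param suppressor_genes strain ids planted as suppressors (subset of the
#'   universe `strain_0001 ...`, or gene ids if `strain_ids` is supplied).
#' @param suppressor_effect target mean fitness Z-score of planted suppressors.
#' @param sick_fraction fraction of strains with small no-drug colonies.
#' @param sick_size_factor relative no-drug size of sick strains (default 0.2).
#' @param strain_ids optional explicit strain universe (length must match the
#'   grid capacity); defaults to `strain_0001 ...`.
#' @param seed integer seed; identical config + seed gives identical output.
#' @return a validated config object of class `pb_screen_sim_config`.
#' @export
screen_sim_config <- function(n_plates = 1, grid_rows = 32, grid_cols = 48,
                              replicate_sets = 4, n_replicate_plates = 3,
                              baseline_size = 500, plate_effect_sd = 0.1,
                              edge_effect = 1.1, noise_cv = 0.15,
                              drug_fitness = 0.5,
                              suppressor_genes = character(),
                              suppressor_effect = 2.5,
                              sick_fraction = 0, sick_size_factor = 0.2,
                              strain_ids = NULL, seed = 1) {
  assert_count(n_plates, "n_plates")
  assert_count(grid_rows, "grid_rows")
  assert_count(grid_cols, "grid_cols")
  assert_count(replicate_sets, "replicate_sets")
  assert_count(n_replicate_plates, "n_replicate_plates")
  assert_scalar_number(noise_cv, "noise_cv", min = 0)
  assert_scalar_number(sick_fraction, "sick_fraction", min = 0, max = 1 - 1e-12)
  assert_scalar_number(suppressor_effect, "suppressor_effect")
  side <- sqrt(replicate_sets)
  if (side != round(side)) {
    pb_abort("replicate_sets must be a perfect square (1, 4, 9, ...)",
             "pb_bad_config")
  }
  if (grid_rows %% side != 0 || grid_cols %% side != 0) {
    pb_abort("grid dimensions must be divisible by the replicate block side",
             "pb_sizing_error")
  }
  n_strains <- n_plates * grid_rows * grid_cols / replicate_sets
  if (is.null(strain_ids)) {
    strain_ids <- sprintf("strain_%04d", seq_len(n_strains))
  }
  if (length(strain_ids) != n_strains) {
    pb_abort(sprintf(
      "grid holds %d strains (%d plates x %d blocks) but %d strain ids given",
      n_strains, n_plates, grid_rows * grid_cols / replicate_sets,
      length(strain_ids)), "pb_sizing_error")
  }
  if (!all(suppressor_genes %in% strain_ids)) {
    pb_abort("suppressor_genes must be a subset of the strain universe",
             "pb_bad_config")
  }
  structure(
    list(n_plates = n_plates, grid_rows = grid_rows, grid_cols = grid_cols,
         replicate_sets = replicate_sets,
         n_replicate_plates = n_replicate_plates,
         baseline_size = baseline_size, plate_effect_sd = plate_effect_sd,
         edge_effect = edge_effect, noise_cv = noise_cv,
         drug_fitness = drug_fitness,
         suppressor_genes = unique(suppressor_genes),
         suppressor_effect = suppressor_effect,
         sick_fraction = sick_fraction, sick_size_factor = sick_size_factor,
         strain_ids = strain_ids, seed = seed),
    class = "pb_screen_sim_config"
  )
}

# multiplicative log-normal noise with coefficient of variation cv
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate a paired-plate suppressor screen with planted truth
#'
#' Generates the full set of no-drug/drug plate pairs across replicate plates
#' described by a [screen_sim_config()], with every planted effect recorded in
#' an exhaustive truth log.
#'
#' @param config a [screen_sim_config()].
#' @return list of class `pb_screen_sim` with `plates` (long-format tibble:
#'   `plate_id`, `condition`, `replicate`, `row`, `col`, `strain_id`, `size`)
#'   and `truth` (tibble: `strain_id`, `role`, `size_factor_no_drug`,
#'   `size_factor_drug`), plus the `config`.
#' @export
simulate_plate_set <- function(config) {
  stopifnot(inherits(config, "pb_screen_sim_config"))
  cf <- config
  side <- sqrt(cf$replicate_sets)
  blocks_per_plate <- cf$grid_rows * cf$grid_cols / cf$replicate_sets

  cv_fitness <- cf$noise_cv * sqrt(2 / cf$replicate_sets)
  boost <- if (cf$noise_cv > 0) {
    1 + cf$suppressor_effect * cv_fitness
  } else {
    1 + 0.05 * cf$suppressor_effect
  }

  with_seed(cf$seed, {
    sick <- if (cf$sick_fraction > 0) {
      eligible <- setdiff(cf$strain_ids, cf$suppressor_genes)
      sample(eligible, size = floor(cf$sick_fraction * length(cf$strain_ids)))
    } else {
      character()
    }
    truth <- tibble(
      strain_id = cf$strain_ids,
      role = dplyr::case_when(
        cf$strain_ids %in% cf$suppressor_genes ~ "suppressor",
        cf$strain_ids %in% sick ~ "sick",
        TRUE ~ "neutral"
      ),
      size_factor_no_drug = ifelse(cf$strain_ids %in% sick,
                                   cf$sick_size_factor, 1),
      size_factor_drug = ifelse(cf$strain_ids %in% cf$suppressor_genes,
                                cf$drug_fitness * boost, cf$drug_fitness) *
        ifelse(cf$strain_ids %in% sick, cf$sick_size_factor, 1)
    )

    # fixed layout shared by every plate pair and replicate: strain blocks
    # fill the plate row-block by row-block
    block_rows <- cf$grid_rows / side
    block_cols <- cf$grid_cols / side
    layout <- tidyr::expand_grid(
      plate = seq_len(cf$n_plates),
      block_r = seq_len(block_rows),
      block_c = seq_len(block_cols)
    ) |>
      dplyr::mutate(strain_id = cf$strain_ids[dplyr::row_number()]) |>
      tidyr::expand_grid(dr = seq_len(side), dc = seq_len(side)) |>
      dplyr::mutate(row = (.data$block_r - 1) * side + .data$dr,
                    col = (.data$block_c - 1) * side + .data$dc) |>
      dplyr::select("plate", "row", "col", "strain_id")

    plates <- tidyr::expand_grid(
      replicate = seq_len(cf$n_replicate_plates),
      condition = c("no_drug", "drug"),
      layout
    ) |>
      dplyr::mutate(plate_id = sprintf("p%d_%s_r%d", .data$plate,
                                       .data$condition, .data$replicate))

    # one multiplier per physical plate
    plate_mult <- plates |>
      dplyr::distinct(.data$plate_id) |>
      dplyr::mutate(mult = rlnorm_cv(dplyr::n(), cf$plate_effect_sd))

    plates <- plates |>
      dplyr::left_join(plate_mult, by = "plate_id") |>
      dplyr::left_join(
        dplyr::select(truth, "strain_id", "size_factor_no_drug",
                      "size_factor_drug"),
        by = "strain_id") |>
      dplyr::mutate(
        edge = .data$row == 1 | .data$row == cf$grid_rows |
          .data$col == 1 | .data$col == cf$grid_cols,
        strain_factor = dplyr::if_else(.data$condition == "drug",
                                       .data$size_factor_drug,
                                       .data$size_factor_no_drug),
        size = cf$baseline_size * .data$mult *
          dplyr::if_else(.data$edge, cf$edge_effect, 1) *
          .data$strain_factor * rlnorm_cv(dplyr::n(), cf$noise_cv)
      ) |>
      dplyr::select("plate_id", "condition", "replicate", "row", "col",
                    "strain_id", "size")

    structure(list(plates = plates, truth = truth, config = cf),
              class = "pb_screen_sim")
  })
}
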