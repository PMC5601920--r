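#' Configuration for simulated OD600 growth curves
#'
#' Curves follow a three-parameter logistic sampled at plate-reader cadence
#' (every 15 minutes by default). A strain's planted fitness in a condition
#' scales the logistic growth rate (curve shape) and the curve is then
#' rescaled so that its realized trapezoid area-under-curve fitness — AUC
#' relative to the control strain in the same condition — equals the planted
#' value exactly. Double mutants (`"geneA:geneB"`) are planted at the product
#' of their single fitness values plus the pair's interaction epsilon, so the
#' noiseless closed loop through AUC fitness and interaction scoring returns
#' planted epsilons to floating tolerance. Measurement noise is additive
#' Gaussian per timepoint, truncated at zero OD.
#'
#' @param carrying_capacity saturating OD600 (default 1.5).
#' @param growth_rate per-hour logistic rate of the control (default 0.35).
#' @param lag hours until half-maximal growth offset (default 2).
#' @param od0 inoculation OD600 (default 0.05).
#' @param sampling_interval hours between OD readings (default 0.25).
#' @param duration total assay hours (default 24).
#' @param noise_sd sd of additive OD noise (default 0.01; 0 = noiseless).
#' @param conditions condition labels (default `"untreated"`, `"HU"`).
#' @param single_fitness tibble `strain_id`, `condition`, `fitness` of planted
#'   single-mutant fitness values in `[0, 1.5]`; the control is implicit at 1.
#' @param interaction_eps tibble `gene_a`, `gene_b`, `condition`, `eps` of
#'   planted interaction deviations; every gene must appear in
#'   `single_fitness` for that condition.
#' @param control_id strain id of the control (default `"control"`).
#' @param seed integer seed.
#' @return config object of class `pb_growth_sim_config`.
#' @export
growth_sim_config <- function(carrying_capacity = 1.5, growth_rate = 0.35,
                              lag = 2, od0 = 0.05, sampling_interval = 0.25,
                              duration = 24, noise_sd = 0.01,
                              conditions = c("untreated", "HU"),
                              single_fitness = NULL, interaction_eps = NULL,
                              control_id = "control", seed = 1) {
  assert_scalar_number(carrying_capacity, "carrying_capacity", min = 1e-9)
  assert_scalar_number(duration, "duration", min = 1e-9)
  assert_scalar_number(sampling_interval, "sampling_interval", min = 1e-9)
  assert_scalar_number(noise_sd, "noise_sd", min = 0)
  if (is.null(single_fitness)) {
    single_fitness <- tibble(strain_id = character(), condition = character(),
                             fitness = numeric())
  }
  assert_columns(single_fitness, c("strain_id", "condition", "fitness"),
                 "single_fitness")
  if (any(single_fitness$fitness < 0 | single_fitness$fitness > 1.5)) {
    pb_abort("planted fitness values must lie in [0, 1.5]", "pb_bad_config")
  }
  if (!is.null(interaction_eps)) {
    assert_columns(interaction_eps, c("gene_a", "gene_b", "condition", "eps"),
                   "interaction_eps")
    known <- unique(single_fitness$strain_id)
    bad <- setdiff(c(interaction_eps$gene_a, interaction_eps$gene_b), known)
    if (length(bad) > 0) {
      pb_abort(sprintf("interaction_eps names unknown strain(s): %s",
                       paste(bad, collapse = ", ")), "pb_bad_config")
    }
  }
  structure(
    list(carrying_capacity = carrying_capacity, growth_rate = growth_rate,
         lag = lag, od0 = od0, sampling_interval = sampling_interval,
         duration = duration, noise_sd = noise_sd, conditions = conditions,
         single_fitness = single_fitness, interaction_eps = interaction_eps,
         control_id = control_id, seed = seed),
    class = "pb_growth_sim_config"
  )
}

logistic_od <- function(t, k, od0, r, lag) {
  k / (1 + ((k - od0) / od0) * exp(-r * (t - lag)))
}

# deterministic curve whose trapezoid AUC is exactly `target_fitness` times
# the baseline's: rate scaling sets the shape, amplitude scaling pins the AUC
planted_curve <- function(times, cf, target_fitness) {
  base <- logistic_od(times, cf$carrying_capacity, cf$od0, cf$growth_rate,
                      cf$lag)
  if (target_fitness == 1) return(base)
  if (target_fitness == 0) return(rep(0, length(times)))
  trap <- function(y) sum(diff(times) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  shaped <- logistic_od(times, cf$carrying_capacity, cf$od0,
                        cf$growth_rate * target_fitness, cf$lag)
  shaped * (target_fitness * trap(base)) / trap(shaped)
}

#' Simulate growth curves for control, single and double mutants
#'
#' @param config a [growth_sim_config()].
#' @param n_replicates replicate curves per strain x condition (default 3).
#' @return list of class `pb_growth_sim`: `curves` (tibble `strain_id`,
#'   `condition`, `replicate`, `time_h`, `od`) and `truth` (tibble
#'   `strain_id`, `condition`, `fitness`, `eps` — every planted effect; double
#'   mutants carry their planted pair epsilon), plus the `config`.
#' @export
simulate_growth_curves <- function(config, n_replicates = 3) {
  stopifnot(inherits(config, "pb_growth_sim_config"))
  cf <- config
  assert_count(n_replicates, "n_replicates")
  times <- seq(0, cf$duration, by = cf$sampling_interval)

  strains <- dplyr::bind_rows(
    tidyr::expand_grid(strain_id = cf$control_id, condition = cf$conditions) |>
      dplyr::mutate(fitness = 1, eps = NA_real_),
    cf$single_fitness |>
      dplyr::mutate(eps = NA_real_),
    if (!is.null(cf$interaction_eps)) {
      cf$interaction_eps |>
        dplyr::inner_join(
          dplyr::rename(cf$single_fitness, gene_a = "strain_id", f_a = "fitness"),
          by = c("gene_a", "condition")) |>
        dplyr::inner_join(
          dplyr::rename(cf$single_fitness, gene_b = "strain_id", f_b = "fitness"),
          by = c("gene_b", "condition")) |>
        dplyr::transmute(
          strain_id = paste(.data$gene_a, .data$gene_b, sep = ":"),
          condition = .data$condition,
          fitness = .data$f_a * .data$f_b + .data$eps,
          eps = .data$eps
        )
    }
  )
  if (any(strains$fitness < 0)) {
    pb_abort("a planted double-mutant fitness is negative; reduce |eps|",
             "pb_bad_config")
  }

  with_seed(cf$seed, {
    curves <- strains |>
      tidyr::expand_grid(replicate = seq_len(n_replicates)) |>
      dplyr::rowwise() |>
      dplyr::reframe(
        strain_id = .data$strain_id, condition = .data$condition,
        replicate = .data$replicate, time_h = times,
        od = pmax(0, planted_curve(times, cf, .data$fitness) +
                    stats::rnorm(length(times), 0, cf$noise_sd))
      )
    structure(list(curves = as_tibble(curves), truth = strains, config = cf),
              class = "pb_growth_sim")
  })
}

#' Simulate a two-drug concentration-grid growth experiment
#'
#' Generates growth curves for every cell of a complete two-drug grid (6x6 by
#' default: five non-zero concentrations per drug plus the no-drug control).
#' The planted fitness of a combination is the product of the two single-drug
#' fitness values plus the planted synergy deviation, realized exactly on the
#' AUC scale as in [simulate_growth_curves()].
#'
#' @param config a [growth_sim_config()] (its fitness/interaction fields are
#'   ignored here).
#' @param conc_a,conc_b concentration vectors including 0, ascending.
#' @param fitness_a,fitness_b planted single-drug fitness at each
#'   concentration (first element must be 1, the no-drug normalization).
#' @param synergy_truth matrix of planted deviations,
#'   `length(conc_a) x length(conc_b)`, zero margins (default all zero).
#' @param n_replicates replicate curves per well (default 3).
#' @return list of class `pb_synergy_sim`: `curves` (tibble `conc_a`,
#'   `conc_b`, `replicate`, `time_h`, `od`), `truth` (planted fitness grid as
#'   a long tibble), and the inputs.
#' @export
simulate_synergy_curves <- function(config,
                                    conc_a = c(0, 19.8, 29.6, 44.4, 66.7, 100),
                                    conc_b = c(0, 0.205, 0.256, 0.32, 0.4, 0.5),
                                    fitness_a = c(1, 0.95, 0.88, 0.78, 0.65, 0.5),
                                    fitness_b = c(1, 0.92, 0.84, 0.74, 0.62, 0.48),
                                    synergy_truth = NULL, n_replicates = 3) {
  stopifnot(inherits(config, "pb_growth_sim_config"))
  cf <- config
  if (conc_a[1] != 0 || conc_b[1] != 0 || fitness_a[1] != 1 || fitness_b[1] != 1) {
    pb_abort("grids must start at concentration 0 with fitness 1",
             "pb_bad_config")
  }
  if (length(fitness_a) != length(conc_a) || length(fitness_b) != length(conc_b)) {
    pb_abort("fitness vectors must match their concentration vectors",
             "pb_bad_config")
  }
  if (is.null(synergy_truth)) {
    synergy_truth <- matrix(0, length(conc_a), length(conc_b))
  }
  if (!all(dim(synergy_truth) == c(length(conc_a), length(conc_b)))) {
    pb_abort("synergy_truth must be a length(conc_a) x length(conc_b) matrix",
             "pb_bad_config")
  }
  if (any(synergy_truth[1, ] != 0) || any(synergy_truth[, 1] != 0)) {
    pb_abort("synergy_truth must be zero along the zero-concentration margins",
             "pb_bad_config")
  }
  times <- seq(0, cf$duration, by = cf$sampling_interval)
  grid <- tidyr::expand_grid(ia = seq_along(conc_a), ib = seq_along(conc_b)) |>
    dplyr::mutate(
      conc_a = conc_a[.data$ia], conc_b = conc_b[.data$ib],
      fitness = fitness_a[.data$ia] * fitness_b[.data$ib] +
        synergy_truth[cbind(.data$ia, .data$ib)]
    )
  if (any(grid$fitness < 0)) {
    pb_abort("planted combination fitness is negative; weaken the synergy",
             "pb_bad_config")
  }
  with_seed(cf$seed, {
    curves <- grid |>
      tidyr::expand_grid(replicate = seq_len(n_replicates)) |>
      dplyr::rowwise() |>
      dplyr::reframe(
        conc_a = .data$conc_a, conc_b = .data$conc_b,
        replicate = .data$replicate, time_h = times,
        od = pmax(0, planted_curve(times, cf, .data$fitness) +
                    stats::rnorm(length(times), 0, cf$noise_sd))
      )
    structure(
      list(curves = as_tibble(curves),
           truth = dplyr::select(grid, "conc_a", "conc_b", "fitness"),
           synergy_truth = synergy_truth,
           conc_a = conc_a, conc_b = conc_b,
           fitness_a = fitness_a, fitness_b = fitness_b,
           config = cf),
      class = "pb_synergy_sim"
    )
  })
}

#' Summarize a synergy-grid simulation into a synergy matrix
#'
#' Convenience chain from simulated (or measured) grid curves to a
#' [build_synergy_matrix()] result: AUC per well, normalization to the no-drug
#' well, replicate averaging, then Bliss-style scoring.
#'
#' @param curves tibble `conc_a`, `conc_b`, `replicate`, `time_h`, `od`.
#' @param drug_a,drug_b display names.
#' @return a `pb_synergy` object.
#' @export
synergy_from_curves <- function(curves, drug_a = "drug_a", drug_b = "drug_b") {
  assert_columns(curves, c("conc_a", "conc_b", "replicate", "time_h", "od"),
                 "synergy curves")
  auc <- curves |>
    dplyr::mutate(strain_id = "cells",
                  condition = paste(.data$conc_a, .data$conc_b)) |>
    growth_auc() |>
    tidyr::separate_wider_delim("condition", " ",
                                names = c("conc_a", "conc_b")) |>
    dplyr::mutate(conc_a = as.numeric(.data$conc_a),
                  conc_b = as.numeric(.data$conc_b))
  ref <- auc |>
    dplyr::filter(.data$conc_a == 0, .data$conc_b == 0) |>
    dplyr::pull(.data$epsilon_raw) |>
    mean()
  if (ref == 0) pb_abort("no-drug AUC is zero", "pb_zero_control")
  norm <- auc |>
    dplyr::group_by(.data$conc_a, .data$conc_b) |>
    dplyr::summarise(fitness = mean(.data$epsilon_raw) / ref, .groups = "drop")
  single_a <- norm |>
    dplyr::filter(.data$conc_b == 0) |>
    dplyr::select(conc = "conc_a", "fitness")
  single_b <- norm |>
    dplyr::filter(.data$conc_a == 0) |>
    dplyr::select(conc = "conc_b", "fitness")
  combos <- norm |>
    dplyr::filter(.data$conc_a > 0, .data$conc_b > 0)
  build_synergy_matrix(single_a, single_b, combos, drug_a, drug_b)
}
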