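#' Configuration for a full synthetic pipeline run
#'
#' Bundles the thresholds of the analysis chain (FDR alpha, Z hit threshold,
#' small-colony rule) with the planting parameters of every synthetic input.
#' The same gene universe is shared by the two screens, the expression table
#' and the interaction network, so planted suppressors can also be planted as
#' consecutively upregulated and the candidate funnel has a known truth.
#'
#' @param seed master integer seed; each stage derives its own stream from it.
#' @param alpha FDR / test significance threshold (default 0.05).
#' @param z_threshold screen hit threshold on mean Z (default 1).
#' @param small_colony_rule see [filter_small_colonies()].
#' @param min_replicates minimum replicates for a hit call (default 2).
#' @param grid_rows,grid_cols,replicate_sets,n_replicate_plates screen format
#'   (default quadruplicated 32 x 48).
#' @param noise_cv,plate_effect_sd,edge_effect screen noise model.
#' @param n_suppressors planted suppressors shared by both screens.
#' @param suppressor_effect planted mean fitness Z displacement.
#' @param sick_fraction strains planted with small no-drug colonies.
#' @param n_consecutive_up genes planted as consecutively upregulated in HU;
#'   `n_funnel_truth` of them are drawn from the planted suppressors so the
#'   candidate funnel has a non-empty planted intersection.
#' @param n_funnel_truth planted size of the suppressor x consecutive-up
#'   intersection.
#' @param de_fraction_up,de_fraction_down,null_log2_sd,de_p_shape expression
#'   noise model (see [expression_sim_config()]).
#' @param growth_noise_sd OD noise of the growth simulations.
#' @param n_growth_replicates replicate growth curves per strain x condition.
#' @param single_fitness,interaction_eps planted growth truth; defaults plant
#'   three single mutants and three pairs, one pair with a condition-dependent
#'   negative interaction.
#' @param synergy_truth planted 6 x 6 synergy deviation matrix; the default
#'   plants one synergic cell at -0.2.
#' @param network_density,network_enrichment_factor interaction-network
#'   planting (enriched set = the planted consecutive-up genes).
#' @return config object of class `pb_pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, alpha = 0.05, z_threshold = 1,
                            small_colony_rule = list(type = "fraction_of_median",
                                                     value = 0.5),
                            min_replicates = 2,
                            grid_rows = 32, grid_cols = 48,
                            replicate_sets = 4, n_replicate_plates = 3,
                            noise_cv = 0.15, plate_effect_sd = 0.1,
                            edge_effect = 1.1,
                            n_suppressors = 20, suppressor_effect = 2.5,
                            sick_fraction = 0.05,
                            n_consecutive_up = 30, n_funnel_truth = 10,
                            de_fraction_up = 0.05, de_fraction_down = 0.05,
                            null_log2_sd = 0.25, de_p_shape = 0.01,
                            growth_noise_sd = 0.01, n_growth_replicates = 5,
                            single_fitness = NULL, interaction_eps = NULL,
                            synergy_truth = NULL,
                            network_density = 0.01,
                            network_enrichment_factor = 4) {
  assert_scalar_number(alpha, "alpha", min = 1e-12, max = 1)
  assert_scalar_number(z_threshold, "z_threshold", min = 0)
  assert_count(seed, "seed", min = 0)
  if (is.null(single_fitness)) {
    single_fitness <- tibble(
      strain_id = rep(c("geneA", "geneB", "geneC"), each = 2),
      condition = rep(c("untreated", "HU"), 3),
      fitness = c(0.95, 0.85, 0.9, 0.8, 0.92, 0.75)
    )
  }
  if (is.null(interaction_eps)) {
    interaction_eps <- tibble(
      gene_a = c("geneA", "geneA", "geneA", "geneA", "geneB", "geneB"),
      gene_b = c("geneB", "geneB", "geneC", "geneC", "geneC", "geneC"),
      condition = rep(c("untreated", "HU"), 3),
      eps = c(0, -0.25, 0, 0, 0, 0)
    )
  }
  if (is.null(synergy_truth)) {
    synergy_truth <- matrix(0, 6, 6)
    synergy_truth[5, 5] <- -0.2
  }
  structure(
    list(seed = seed, alpha = alpha, z_threshold = z_threshold,
         small_colony_rule = small_colony_rule,
         min_replicates = min_replicates,
         grid_rows = grid_rows, grid_cols = grid_cols,
         replicate_sets = replicate_sets,
         n_replicate_plates = n_replicate_plates,
         noise_cv = noise_cv, plate_effect_sd = plate_effect_sd,
         edge_effect = edge_effect,
         n_suppressors = n_suppressors, suppressor_effect = suppressor_effect,
         sick_fraction = sick_fraction,
         n_consecutive_up = n_consecutive_up, n_funnel_truth = n_funnel_truth,
         de_fraction_up = de_fraction_up, de_fraction_down = de_fraction_down,
         null_log2_sd = null_log2_sd, de_p_shape = de_p_shape,
         growth_noise_sd = growth_noise_sd,
         n_growth_replicates = n_growth_replicates,
         single_fitness = single_fitness, interaction_eps = interaction_eps,
         synergy_truth = synergy_truth,
         network_density = network_density,
         network_enrichment_factor = network_enrichment_factor),
    class = "pb_pipeline_config"
  )
}

#' Run the full synthetic analysis pipeline
#'
#' Executes every stage in dependency order on synthetic inputs generated from
#' the config: two suppressor screens (shared planted suppressors), screen
#' scoring and dual-screen intersection; an expression table, DE calling,
#' drug-core construction and the candidate funnel; growth curves, AUC
#' fitness, interaction scoring with drug-exacerbation tests; a two-drug
#' synergy grid; and network enrichment of the planted gene module. When
#' `out_dir` is given, every stage table is written (TSV/CSV) together with a
#' JSON run manifest that fully determines a rerun.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory (created if missing).
#' @return list of class `pb_pipeline` with per-stage results, planted
#'   `truth`, and the run `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pb_pipeline_config"))
  cf <- config
  seeds <- list(screen_a = cf$seed + 101, screen_b = cf$seed + 202,
                expression = cf$seed + 303, growth = cf$seed + 404,
                synergy = cf$seed + 505, network = cf$seed + 606,
                planting = cf$seed + 707)

  n_strains <- cf$grid_rows * cf$grid_cols / cf$replicate_sets
  genes <- sprintf("g%04d", seq_len(n_strains))
  planted <- with_seed(seeds$planting, {
    suppressors <- sample(genes, cf$n_suppressors)
    consec_from_supp <- sample(suppressors, cf$n_funnel_truth)
    consec_extra <- sample(setdiff(genes, suppressors),
                           cf$n_consecutive_up - cf$n_funnel_truth)
    list(suppressors = suppressors,
         consecutive_up = c(consec_from_supp, consec_extra),
         funnel = consec_from_supp)
  })

  ## stage 1: paired suppressor screens
  screen_cfg <- function(seed) {
    screen_sim_config(
      grid_rows = cf$grid_rows, grid_cols = cf$grid_cols,
      replicate_sets = cf$replicate_sets,
      n_replicate_plates = cf$n_replicate_plates,
      plate_effect_sd = cf$plate_effect_sd, edge_effect = cf$edge_effect,
      noise_cv = cf$noise_cv, suppressor_genes = planted$suppressors,
      suppressor_effect = cf$suppressor_effect,
      sick_fraction = cf$sick_fraction, strain_ids = genes, seed = seed
    )
  }
  sim_a <- simulate_plate_set(screen_cfg(seeds$screen_a))
  sim_b <- simulate_plate_set(screen_cfg(seeds$screen_b))
  screen_a <- score_screen(sim_a$plates,
                           small_colony_rule = cf$small_colony_rule,
                           min_replicates = cf$min_replicates,
                           z_threshold = cf$z_threshold)
  screen_b <- score_screen(sim_b$plates,
                           small_colony_rule = cf$small_colony_rule,
                           min_replicates = cf$min_replicates,
                           z_threshold = cf$z_threshold)
  dual <- intersect_screens(screen_a$hits, screen_b$hits)

  ## stage 2: expression table, DE calls, core sets, candidate funnel
  expr_cfg <- expression_sim_config(
    n_genes = n_strains, de_fraction_up = cf$de_fraction_up,
    de_fraction_down = cf$de_fraction_down, null_log2_sd = cf$null_log2_sd,
    de_p_shape = cf$de_p_shape,
    consecutive_up_genes = planted$consecutive_up,
    gene_ids = genes, seed = seeds$expression
  )
  expr_sim <- simulate_expression_table(expr_cfg)
  calls <- call_differential(expr_sim$records, alpha = cf$alpha)
  core <- define_hu_core(calls, expr_cfg$hu_contrast, expr_cfg$hu_timepoints,
                         expr_cfg$untreated_contrast)
  consec_up <- consecutive_upregulation(calls, expr_cfg$hu_contrast,
                                        expr_cfg$hu_timepoints)
  funnel <- candidate_funnel(
    gene_set("dual_suppressors", dual$strain_id,
             sprintf("suppressor (mean Z >= %g) in both screens",
                     cf$z_threshold)),
    consec_up
  )

  ## stage 3: growth curves, interaction scoring
  growth_cfg <- growth_sim_config(
    noise_sd = cf$growth_noise_sd, single_fitness = cf$single_fitness,
    interaction_eps = cf$interaction_eps, seed = seeds$growth
  )
  growth_sim <- simulate_growth_curves(growth_cfg,
                                       n_replicates = cf$n_growth_replicates)
  fitness <- growth_sim$curves |>
    growth_auc() |>
    relative_fitness(control = growth_cfg$control_id)
  pairs <- dplyr::distinct(cf$interaction_eps, .data$gene_a, .data$gene_b)
  interactions <- score_interactions(fitness, pairs, alpha = cf$alpha)
  negatives <- count_condition_dependent_negatives(interactions, cf$alpha)

  ## stage 4: two-drug synergy grid
  synergy_cfg <- growth_sim_config(noise_sd = cf$growth_noise_sd,
                                   seed = seeds$synergy)
  synergy_sim <- simulate_synergy_curves(synergy_cfg,
                                         synergy_truth = cf$synergy_truth)
  synergy <- synergy_from_curves(synergy_sim$curves,
                                 drug_a = "HU", drug_b = "acetaldehyde")

  ## stage 5: network enrichment of the planted module
  network <- simulate_interaction_network(
    n_genes = n_strains, edge_density = cf$network_density,
    enriched_set = planted$consecutive_up,
    enrichment_factor = cf$network_enrichment_factor,
    gene_ids = genes, seed = seeds$network
  )
  enrichment <- interaction_enrichment(planted$consecutive_up, network$edges,
                                       network$universe,
                                       set_label = "planted_module")

  manifest <- list(
    package_version = as.character(utils::packageVersion("pbodyscreen")),
    seed = cf$seed, stage_seeds = seeds,
    thresholds = list(alpha = cf$alpha, z_threshold = cf$z_threshold,
                      small_colony_rule = cf$small_colony_rule,
                      min_replicates = cf$min_replicates),
    counts = list(
      strains = n_strains,
      screen_a = screen_a$summary, screen_b = screen_b$summary,
      dual_suppressors = nrow(dual),
      hu_core_up = length(core$up$members),
      hu_core_down = length(core$down$members),
      consecutive_up = length(consec_up$members),
      funnel = length(funnel$members),
      interactions_scored = nrow(pairs),
      condition_dependent_negatives = negatives$count,
      network_edges = nrow(network$edges)
    )
  )

  result <- structure(
    list(screen_a = screen_a, screen_b = screen_b, dual_suppressors = dual,
         expression_calls = calls, hu_core = core, consecutive_up = consec_up,
         funnel = funnel, fitness = fitness, interactions = interactions,
         condition_dependent_negatives = negatives, synergy = synergy,
         enrichment = enrichment,
         truth = list(screen_a = sim_a$truth, screen_b = sim_b$truth,
                      planted = planted, expression = expr_sim$truth,
                      growth = growth_sim$truth,
                      synergy = synergy_sim$synergy_truth),
         manifest = manifest, config = cf),
    class = "pb_pipeline"
  )

  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

# write every stage table plus the JSON manifest
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    readr::write_tsv(df, file.path(out_dir, paste0(name, ".tsv")))
  }
  w(result$screen_a$fitness, "screen_a_fitness")
  w(result$screen_a$zscores, "screen_a_zscores")
  w(result$screen_a$hits, "screen_a_hits")
  w(result$screen_b$hits, "screen_b_hits")
  w(result$dual_suppressors, "dual_suppressors")
  w(result$expression_calls, "expression_calls")
  w(tibble(gene_id = result$funnel$members), "candidate_funnel")
  w(result$fitness, "growth_fitness")
  w(as_tibble(result$interactions), "interactions")
  w(result$enrichment, "network_enrichment")
  for (grid in c("observed", "expected", "interaction")) {
    m <- result$synergy[[grid]]
    df <- as_tibble(m, .name_repair = ~ paste0("b_", result$synergy$conc_b))
    df <- dplyr::bind_cols(tibble(conc_a = result$synergy$conc_a), df)
    readr::write_csv(df, file.path(out_dir, paste0("synergy_", grid, ".csv")))
  }
  edges <- result$interactions |>
    dplyr::filter(.data$condition == attr(result$interactions, "conditions")[["untreated"]]) |>
    dplyr::select("gene_a", "gene_b", "edge_weight")
  w(edges, "interaction_network_edges")
  jsonlite::write_json(result$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.pb_pipeline <- function(x, ...) {
  m <- x$manifest$counts
  cat("<pb_pipeline>\n")
  cat(sprintf("  screens: %d + %d suppressors -> %d dual\n",
              m$screen_a$n_suppressor, m$screen_b$n_suppressor,
              m$dual_suppressors))
  cat(sprintf("  expression: %d consecutive-up, funnel %d\n",
              m$consecutive_up, m$funnel))
  cat(sprintf("  interactions: %d scored, %d condition-dependent negative\n",
              m$interactions_scored, m$condition_dependent_negatives))
  invisible(x)
}
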