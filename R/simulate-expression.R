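#' Configuration for simulated differential-expression tables
#'
#' Emulates processed RNA-seq summary tables: per gene, contrast and
#' timepoint, a log2 expression ratio with a p-value and a per-family
#' Benjamini-Hochberg q-value. Two contrasts are generated — an untreated
#' mutant-vs-wild-type comparison and a drug timecourse — and a chosen set of
#' genes is planted as upregulated at all drug timepoints (hence at >= 2
#' consecutive ones) while staying null untreated, mirroring the drug-core
#' construction the filters recover.
#'
#' Null genes draw `log2_ratio ~ N(0, null_log2_sd)` and `p ~ Uniform(0, 1)`;
#' planted genes draw a shifted ratio of the same spread and
#' `p ~ Beta(de_p_shape, 1)`, the standard one-parameter alternative. When
#' `null_log2_sd = 0` the table is noiseless: ratios are exactly 0 or the
#' planted effect and p-values are deterministic (1 for null, 1e-9 for
#' planted), so planted sets are recovered exactly.
#'
#' @param n_genes number of genes (universe `g0001 ...`, or `gene_ids`).
#' @param hu_timepoints ordered drug timepoints (default `"1h","2h","4h"`).
#' @param untreated_timepoint label of the untreated comparison's timepoint.
#' @param hu_contrast,untreated_contrast contrast labels.
#' @param de_fraction_up,de_fraction_down fractions of genes planted as
#'   scattered (single contrast x timepoint) up/down events.
#' @param effect_log2_mean planted absolute log2 effect size.
#' @param null_log2_sd spread of null log2 ratios (0 = noiseless mode).
#' @param de_p_shape `a` of the planted `Beta(a, 1)` p-value model.
#' @param consecutive_up_genes gene ids planted up at all drug timepoints and
#'   null untreated.
#' @param gene_ids optional explicit gene universe.
#' @param seed integer seed.
#' @return config object of class `pb_expression_sim_config`.
#' @export
expression_sim_config <- function(n_genes = 1000,
                                  hu_timepoints = c("1h", "2h", "4h"),
                                  untreated_timepoint = "0h",
                                  hu_contrast = "mutant_vs_wt_hu",
                                  untreated_contrast = "mutant_vs_wt_untreated",
                                  de_fraction_up = 0.05,
                                  de_fraction_down = 0.05,
                                  effect_log2_mean = 2,
                                  null_log2_sd = 0.25,
                                  de_p_shape = 0.01,
                                  consecutive_up_genes = character(),
                                  gene_ids = NULL, seed = 1) {
  assert_count(n_genes, "n_genes")
  assert_probability(de_fraction_up, "de_fraction_up")
  assert_probability(de_fraction_down, "de_fraction_down")
  if (de_fraction_up + de_fraction_down >= 1) {
    pb_abort("de fractions must sum to < 1", "pb_bad_config")
  }
  if (length(hu_timepoints) < 2 || anyDuplicated(hu_timepoints) > 0) {
    pb_abort("hu_timepoints must be >= 2 distinct ordered labels",
             "pb_bad_config")
  }
  if (is.null(gene_ids)) gene_ids <- sprintf("g%04d", seq_len(n_genes))
  if (length(gene_ids) != n_genes) {
    pb_abort("gene_ids length must equal n_genes", "pb_bad_config")
  }
  if (!all(consecutive_up_genes %in% gene_ids)) {
    pb_abort("consecutive_up_genes must be a subset of the gene universe",
             "pb_bad_config")
  }
  structure(
    list(n_genes = n_genes, hu_timepoints = hu_timepoints,
         untreated_timepoint = untreated_timepoint,
         hu_contrast = hu_contrast, untreated_contrast = untreated_contrast,
         de_fraction_up = de_fraction_up, de_fraction_down = de_fraction_down,
         effect_log2_mean = effect_log2_mean, null_log2_sd = null_log2_sd,
         de_p_shape = de_p_shape,
         consecutive_up_genes = unique(consecutive_up_genes),
         gene_ids = gene_ids, seed = seed),
    class = "pb_expression_sim_config"
  )
}

#' Simulate a differential-expression summary table with planted truth
#'
#' @param config an [expression_sim_config()].
#' @return list of class `pb_expression_sim`: `records` (tibble `gene_id`,
#'   `contrast`, `timepoint`, `log2_ratio`, `p_value`, `q_value`, with q
#'   computed per contrast x timepoint family), `truth` (tibble `gene_id`,
#'   `contrast`, `timepoint`, `direction` listing every planted effect), and
#'   the `config`.
#' @export
simulate_expression_table <- function(config) {
  stopifnot(inherits(config, "pb_expression_sim_config"))
  cf <- config
  noiseless <- cf$null_log2_sd == 0

  families <- dplyr::bind_rows(
    tibble(contrast = cf$untreated_contrast, timepoint = cf$untreated_timepoint),
    tibble(contrast = cf$hu_contrast, timepoint = cf$hu_timepoints)
  )

  with_seed(cf$seed, {
    # scattered DE events: per family, independent draws among the genes not
    # reserved for the consecutive-up set
    free_genes <- setdiff(cf$gene_ids, cf$consecutive_up_genes)
    scattered <- purrr::pmap(families, function(contrast, timepoint) {
      n_up <- round(cf$de_fraction_up * length(free_genes))
      n_down <- round(cf$de_fraction_down * length(free_genes))
      picked <- sample(free_genes, n_up + n_down)
      tibble(
        gene_id = picked,
        contrast = contrast,
        timepoint = timepoint,
        direction = rep(c("up", "down"), c(n_up, n_down))
      )
    }) |> purrr::list_rbind()

    consec <- tidyr::expand_grid(
      gene_id = cf$consecutive_up_genes,
      contrast = cf$hu_contrast,
      timepoint = cf$hu_timepoints
    ) |>
      dplyr::mutate(direction = "up")

    truth <- dplyr::bind_rows(scattered, consec)

    records <- tidyr::expand_grid(gene_id = cf$gene_ids, families) |>
      dplyr::left_join(truth, by = c("gene_id", "contrast", "timepoint")) |>
      dplyr::mutate(
        planted = !is.na(.data$direction),
        sign = dplyr::case_when(.data$direction == "down" ~ -1, TRUE ~ 1),
        log2_ratio = dplyr::if_else(
          .data$planted,
          .data$sign * (cf$effect_log2_mean +
                          stats::rnorm(dplyr::n(), 0, cf$null_log2_sd)),
          stats::rnorm(dplyr::n(), 0, cf$null_log2_sd)
        ),
        p_value = dplyr::if_else(
          .data$planted,
          if (noiseless) 1e-9 else stats::rbeta(dplyr::n(), cf$de_p_shape, 1),
          if (noiseless) 1 else stats::runif(dplyr::n())
        )
      ) |>
      dplyr::group_by(.data$contrast, .data$timepoint) |>
      dplyr::mutate(q_value = bh_adjust(.data$p_value)) |>
      dplyr::ungroup() |>
      dplyr::select("gene_id", "contrast", "timepoint", "log2_ratio",
                    "p_value", "q_value")

    structure(list(records = records, truth = truth, config = cf),
              class = "pb_expression_sim")
  })
}
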