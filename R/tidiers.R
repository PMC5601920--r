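#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy a scored screen into its hit table
#'
#' @param x a `pb_screen` from [score_screen()].
#' @param ... unused.
#' @return the hit tibble (`strain_id`, `mean_z`, `n_replicates`, `call`).
#' @method tidy pb_screen
#' @export
tidy.pb_screen <- function(x, ...) {
  x$hits
}

#' One-row summary of a scored screen
#'
#' @param x a `pb_screen`.
#' @param ... unused.
#' @return one-row tibble of scoring counts.
#' @method glance pb_screen
#' @export
glance.pb_screen <- function(x, ...) {
  as_tibble(x$summary)
}

#' Z-score distribution of a scored screen
#'
#' Histogram of replicate-averaged Z-scores with the hit thresholds marked.
#'
#' @param object a `pb_screen`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot pb_screen
#' @export
autoplot.pb_screen <- function(object, ...) {
  z <- object$summary$z_threshold
  hits <- dplyr::filter(object$hits, !is.na(.data$mean_z))
  ggplot2::ggplot(hits, ggplot2::aes(x = .data$mean_z)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = c(-z, z), linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(x = "mean fitness Z-score (replicate plates)",
                  y = "strains",
                  title = "Screen Z-score distribution",
                  subtitle = sprintf(
                    "suppressor >= +%g, synthetic sick <= -%g", z, z)) +
    ggplot2::theme_minimal()
}

#' Tidy a gene set
#'
#' @param x a `pb_geneset`.
#' @param ... unused.
#' @return tibble with `gene_id` and the set `label`.
#' @method tidy pb_geneset
#' @export
tidy.pb_geneset <- function(x, ...) {
  tibble(gene_id = x$members, label = x$label)
}

#' One-row summary of a gene set
#'
#' @param x a `pb_geneset`.
#' @param ... unused.
#' @return tibble with the set size and collapsed provenance.
#' @method glance pb_geneset
#' @export
glance.pb_geneset <- function(x, ...) {
  tibble(label = x$label, n_genes = length(x$members),
         provenance = paste(x$provenance, collapse = " | "))
}

#' Tidy a synergy matrix into a long table
#'
#' @param x a `pb_synergy` from [build_synergy_matrix()].
#' @param ... unused.
#' @return long tibble: `conc_a`, `conc_b`, `observed`, `expected`,
#'   `interaction`, `synergy` (TRUE where interaction < 0).
#' @method tidy pb_synergy
#' @export
tidy.pb_synergy <- function(x, ...) {
  tidyr::expand_grid(ia = seq_along(x$conc_a), ib = seq_along(x$conc_b)) |>
    dplyr::mutate(
      conc_a = x$conc_a[.data$ia], conc_b = x$conc_b[.data$ib],
      observed = x$observed[cbind(.data$ia, .data$ib)],
      expected = x$expected[cbind(.data$ia, .data$ib)],
      interaction = x$interaction[cbind(.data$ia, .data$ib)],
      synergy = .data$interaction < 0
    ) |>
    dplyr::select(-"ia", -"ib")
}

#' One-row summary of a synergy matrix
#'
#' @param x a `pb_synergy`.
#' @param ... unused.
#' @return tibble with grid size and extreme interaction scores.
#' @method glance pb_synergy
#' @export
glance.pb_synergy <- function(x, ...) {
  tibble(
    n_conc_a = length(x$conc_a), n_conc_b = length(x$conc_b),
    min_interaction = min(x$interaction),
    max_interaction = max(x$interaction),
    n_synergic = sum(x$interaction < 0)
  )
}

#' Heatmap of a two-drug synergy matrix
#'
#' Tile heatmap of the observed-minus-expected interaction scores; blue tiles
#' (negative) indicate synergy.
#'
#' @param object a `pb_synergy`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot pb_synergy
#' @export
autoplot.pb_synergy <- function(object, ...) {
  tidy(object) |>
    dplyr::mutate(conc_a = factor(.data$conc_a),
                  conc_b = factor(.data$conc_b)) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$conc_b, y = .data$conc_a,
                                 fill = .data$interaction)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f", .data$interaction)), size = 3) +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "indianred", midpoint = 0) +
    ggplot2::labs(x = object$drug_b, y = object$drug_a,
                  fill = "obs - exp",
                  title = "Drug interaction (negative = synergy)") +
    ggplot2::theme_minimal()
}

#' Epsilon dot plot of scored genetic interactions
#'
#' @param object a `pb_interactions` table from [score_interactions()].
#' @param ... unused.
#' @return a ggplot of interaction epsilons per pair and condition.
#' @method autoplot pb_interactions
#' @export
autoplot.pb_interactions <- function(object, ...) {
  df <- as_tibble(object) |>
    dplyr::mutate(pair = paste(.data$gene_a, .data$gene_b, sep = ":"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pair, y = .data$epsilon,
                                   colour = .data$condition)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "epsilon (observed - expected fitness)",
                  title = "Genetic interactions, multiplicative model") +
    ggplot2::theme_minimal()
}
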