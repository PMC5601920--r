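#' Simulate an interaction network with a planted enriched set
#'
#' Erdos-Renyi background: every unordered gene pair carries an edge
#' independently with probability `edge_density`, except pairs with both
#' endpoints in `enriched_set`, which are sampled at
#' `edge_density * enrichment_factor`. No self-edges, no duplicate edges.
#' With `enrichment_factor = 1` the network is a pure null and the binomial
#' enrichment test is calibrated; larger factors plant a within-set
#' interaction excess for power checks.
#'
#' @param n_genes number of genes (universe `g0001 ...`, or `gene_ids`).
#' @param edge_density background edge probability in `(0, 1)`.
#' @param enriched_set gene ids of the planted module (subset of universe).
#' @param enrichment_factor multiplier on the within-set edge probability;
#'   the product must stay <= 1.
#' @param gene_ids optional explicit gene universe.
#' @param seed integer seed.
#' @return list of class `pb_network_sim`: `edges` (tibble `gene_a`,
#'   `gene_b`), `universe`, and the planting parameters.
#' @export
simulate_interaction_network <- function(n_genes = 500, edge_density = 0.01,
                                         enriched_set = character(),
                                         enrichment_factor = 1,
                                         gene_ids = NULL, seed = 1) {
  assert_count(n_genes, "n_genes", min = 2)
  assert_scalar_number(edge_density, "edge_density", min = 0, max = 1 - 1e-12)
  assert_scalar_number(enrichment_factor, "enrichment_factor", min = 0)
  if (edge_density * enrichment_factor > 1) {
    pb_abort("edge_density * enrichment_factor exceeds 1", "pb_bad_config")
  }
  if (is.null(gene_ids)) gene_ids <- sprintf("g%04d", seq_len(n_genes))
  if (length(gene_ids) != n_genes) {
    pb_abort("gene_ids length must equal n_genes", "pb_bad_config")
  }
  if (!all(enriched_set %in% gene_ids)) {
    pb_abort("enriched_set must be a subset of the gene universe",
             "pb_bad_config")
  }
  with_seed(seed, {
    idx <- utils::combn(n_genes, 2)
    a <- gene_ids[idx[1, ]]
    b <- gene_ids[idx[2, ]]
    within <- a %in% enriched_set & b %in% enriched_set
    prob <- ifelse(within, edge_density * enrichment_factor, edge_density)
    keep <- stats::runif(length(prob)) < prob
    structure(
      list(edges = tibble(gene_a = a[keep], gene_b = b[keep]),
           universe = gene_ids,
           enriched_set = enriched_set,
           enrichment_factor = enrichment_factor,
           edge_density = edge_density, seed = seed),
      class = "pb_network_sim"
    )
  })
}
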