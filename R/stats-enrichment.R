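#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a vector of p-values. This is
#' the multiple-testing correction applied to every differential-expression
#' family (one contrast x timepoint table at a time) before hits are called
#' at `q < alpha`.
#'
#' @param p numeric vector of p-values, all in \[0, 1\].
#' @return numeric vector of q-values, same length and order as `p`. `q >= p`
#'   elementwise and adjusting already-adjusted values is idempotent.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_adjust <- function(p) {
  assert_probability(p, "p")
  stats::p.adjust(p, method = "BH")
}

new_enrichment_result <- function(set_label, observed_stat, expected_stat,
                                  p_value, test, extra = list()) {
  ratio <- if (expected_stat > 0) observed_stat / expected_stat else NA_real_
  out <- tibble(
    set_label = set_label,
    observed_stat = observed_stat,
    expected_stat = expected_stat,
    ratio = ratio,
    p_value = p_value,
    test = test
  )
  for (nm in names(extra)) out[[nm]] <- extra[[nm]]
  out
}

# drop self-edges and duplicate undirected edges; restrict to the universe
clean_edges <- function(edges, universe = NULL) {
  assert_columns(edges, c("gene_a", "gene_b"), "edge list")
  edges <- dplyr::filter(edges, .data$gene_a != .data$gene_b)
  if (!is.null(universe)) {
    edges <- dplyr::filter(edges, .data$gene_a %in% universe,
                           .data$gene_b %in% universe)
  }
  edges <- dplyr::mutate(edges,
    lo = pmin(.data$gene_a, .data$gene_b),
    hi = pmax(.data$gene_a, .data$gene_b)
  )
  edges <- dplyr::distinct(edges, .data$lo, .data$hi)
  dplyr::rename(edges, gene_a = "lo", gene_b = "hi")
}

#' Interaction-network enrichment of a gene set
#'
#' Tests whether the genes in a set interact with each other more often than
#' the background interaction density of the whole network predicts. The
#' observed statistic is interactions-per-gene within the set; the within-set
#' edge count is tested with an exact binomial upper-tail test, with the
#' number of trials equal to the number of unordered pairs that could carry an
#' edge and success probability equal to the overall network edge density.
#'
#' @param gene_set character vector of gene ids (at least 2), a subset of
#'   `universe`.
#' @param edges data frame with columns `gene_a`, `gene_b` (undirected edge
#'   list; self-edges and duplicates are dropped on load).
#' @param universe character vector of all gene ids the network is defined
#'   over.
#' @param mode `"both"` counts edges with both endpoints in the set (default);
#'   `"one"` counts edges with at least one endpoint in the set. The published
#'   description is ambiguous between the two, so both are available and the
#'   mode used is recorded in the result.
#' @param set_label label carried into the result row.
#' @return one-row tibble: `set_label`, `observed_stat` (edges per set gene),
#'   `expected_stat` (edges per gene network-wide), `ratio`, `p_value`,
#'   `test = "binomial"`, plus the counts that entered the test.
#' @export
interaction_enrichment <- function(gene_set, edges, universe,
                                   mode = c("both", "one"),
                                   set_label = "gene_set") {
  mode <- match.arg(mode)
  gene_set <- unique(as.character(gene_set))
  universe <- unique(as.character(universe))
  if (length(gene_set) < 2) {
    pb_abort("`gene_set` must contain at least 2 genes", "pb_bad_gene_set")
  }
  if (!all(gene_set %in% universe)) {
    pb_abort("`gene_set` must be a subset of `universe`", "pb_bad_gene_set")
  }
  edges <- clean_edges(edges, universe)
  n_edges <- nrow(edges)
  if (n_edges == 0) {
    pb_abort("edge list is empty after cleaning", "pb_empty_network")
  }
  n <- length(universe)
  s <- length(gene_set)
  density <- n_edges / choose(n, 2)

  in_a <- edges$gene_a %in% gene_set
  in_b <- edges$gene_b %in% gene_set
  if (mode == "both") {
    k <- sum(in_a & in_b)
    n_trials <- choose(s, 2)
  } else {
    k <- sum(in_a | in_b)
    n_trials <- choose(n, 2) - choose(n - s, 2)
  }
  # upper tail including the observed count
  p <- stats::pbinom(k - 1, size = n_trials, prob = density, lower.tail = FALSE)

  new_enrichment_result(
    set_label = set_label,
    observed_stat = k / s,
    expected_stat = n_edges / n,
    p_value = p,
    test = "binomial",
    extra = list(n_within = k, n_trials = n_trials,
                 edge_density = density, mode = mode)
  )
}

#' Hypergeometric test of gene-set overlap
#'
#' Upper-tail probability of observing at least the measured overlap between
#' two gene sets when one is drawn without replacement from the universe.
#'
#' @param set_a,set_b character vectors of gene ids, both subsets of
#'   `universe`.
#' @param universe character vector defining the sampling frame.
#' @param set_label label carried into the result row.
#' @return one-row tibble with the overlap count as `observed_stat`, the
#'   expected overlap `|A||B|/N` as `expected_stat`, and the hypergeometric
#'   upper-tail `p_value`.
#' @export
hypergeometric_overlap <- function(set_a, set_b, universe,
                                   set_label = "overlap") {
  set_a <- unique(as.character(set_a))
  set_b <- unique(as.character(set_b))
  universe <- unique(as.character(universe))
  if (!all(set_a %in% universe) || !all(set_b %in% universe)) {
    pb_abort("both sets must be subsets of `universe`", "pb_bad_gene_set")
  }
  n <- length(universe)
  k <- length(intersect(set_a, set_b))
  p <- stats::phyper(k - 1, m = length(set_a), n = n - length(set_a),
                     k = length(set_b), lower.tail = FALSE)
  new_enrichment_result(
    set_label = set_label,
    observed_stat = k,
    expected_stat = length(set_a) * length(set_b) / n,
    p_value = p,
    test = "hypergeometric",
    extra = list(n_a = length(set_a), n_b = length(set_b), n_universe = n)
  )
}

#' Two-sided rank-sum comparison of two samples
#'
#' Unpaired Wilcoxon / Mann-Whitney test. Small untied samples (both sizes
#' <= 10) are tested by exact enumeration of the rank-sum distribution;
#' otherwise the normal approximation with tie correction (and continuity
#' correction) is used.
#'
#' @param values_a,values_b numeric vectors, both non-empty.
#' @param mode `"auto"` (default), `"exact"`, or `"normal"`.
#' @return two-sided p-value (a single number).
#' @export
ranksum_compare <- function(values_a, values_b,
                            mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  if (length(values_a) == 0 || length(values_b) == 0) {
    pb_abort("both samples must be non-empty", "pb_empty_sample")
  }
  has_ties <- anyDuplicated(c(values_a, values_b)) > 0
  small <- length(values_a) <= 10 && length(values_b) <= 10
  use_exact <- switch(mode,
    auto = small && !has_ties,
    exact = TRUE,
    normal = FALSE
  )
  if (use_exact && has_ties) {
    warn("ties present; falling back to the normal approximation")
    use_exact <- FALSE
  }
  res <- suppressWarnings(stats::wilcox.test(
    values_a, values_b,
    alternative = "two.sided", exact = use_exact, correct = TRUE
  ))
  unname(res$p.value)
}
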