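#' Construct a gene set with provenance
#'
#' A lightweight container for a named set of gene ids together with the
#' filter chain that produced it, so every derived set documents how it was
#' made.
#'
#' @param label short name of the set.
#' @param members character vector of gene ids (de-duplicated, sorted).
#' @param provenance character vector describing the filter steps applied.
#' @return object of class `pb_geneset`.
#' @export
gene_set <- function(label, members, provenance = label) {
  if (length(provenance) == 0 || any(!nzchar(provenance))) {
    pb_abort("provenance must be non-empty", "pb_bad_geneset")
  }
  structure(
    list(label = label,
         members = sort(unique(as.character(members))),
         provenance = provenance),
    class = "pb_geneset"
  )
}

#' @export
print.pb_geneset <- function(x, ...) {
  cat(sprintf("<pb_geneset> %s: %d genes\n", x$label, length(x$members)))
  for (step in x$provenance) cat("  - ", step, "\n", sep = "")
  invisible(x)
}

as_members <- function(x) {
  if (inherits(x, "pb_geneset")) x$members else unique(as.character(x))
}

#' Call differentially expressed genes per contrast and timepoint
#'
#' Applies the study's differential-expression rule to a long-format DE
#' summary table: a gene is a hit when its Benjamini-Hochberg q-value is below
#' `alpha` within its contrast x timepoint family; direction is the sign of
#' the log2 ratio (genes with ratio exactly 0 are assigned to neither set).
#' Missing q-values are recomputed from p-values with [bh_adjust()] per
#' family.
#'
#' @param records data frame with columns `gene_id`, `contrast`, `timepoint`,
#'   `log2_ratio`, and `p_value` and/or `q_value`.
#' @param alpha FDR threshold, default 0.05.
#' @return tibble of the input plus `q_value` and
#'   `call` in `"up"`, `"down"`, `"none"`.
#' @export
call_differential <- function(records, alpha = 0.05) {
  assert_columns(records, c("gene_id", "contrast", "timepoint", "log2_ratio"),
                 "expression records")
  assert_scalar_number(alpha, "alpha", min = 0, max = 1)
  if (!"q_value" %in% names(records)) {
    if (!"p_value" %in% names(records)) {
      pb_abort("need `q_value` or `p_value` to call differential expression",
               "pb_missing_pvalues")
    }
    records <- records |>
      dplyr::group_by(.data$contrast, .data$timepoint) |>
      dplyr::mutate(q_value = bh_adjust(.data$p_value)) |>
      dplyr::ungroup()
  }
  assert_probability(records$q_value, "q_value")
  records |>
    as_tibble() |>
    dplyr::mutate(call = dplyr::case_when(
      .data$q_value < alpha & .data$log2_ratio > 0 ~ "up",
      .data$q_value < alpha & .data$log2_ratio < 0 ~ "down",
      TRUE ~ "none"
    ))
}

# genes called `direction` at >= 2 adjacent positions of the ordered timepoints
consecutive_genes <- function(calls, contrast, timepoints, direction) {
  calls <- dplyr::filter(calls, .data$contrast == !!contrast,
                         .data$timepoint %in% timepoints)
  hit <- calls |>
    dplyr::filter(.data$call == direction) |>
    dplyr::distinct(.data$gene_id, .data$timepoint)
  wide <- hit |>
    dplyr::mutate(pos = match(.data$timepoint, timepoints)) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(consec = any(diff(sort(.data$pos)) == 1), .groups = "drop")
  wide$gene_id[wide$consec]
}

#' Genes upregulated at two or more consecutive timepoints
#'
#' Selects the genes called up at two or more *adjacent* positions of the
#' ordered HU timepoint list (e.g. 1h & 2h or 2h & 4h qualify; 1h & 4h alone
#' does not).
#'
#' @param calls call table from [call_differential()].
#' @param hu_contrast contrast label of the drug-treatment comparison.
#' @param hu_timepoints character vector of HU timepoints in sampling order
#'   (at least 2).
#' @param direction `"up"` (default) or `"down"`.
#' @return [gene_set()] of qualifying genes.
#' @export
consecutive_upregulation <- function(calls, hu_contrast, hu_timepoints,
                                     direction = c("up", "down")) {
  direction <- match.arg(direction)
  if (length(hu_timepoints) < 2) {
    pb_abort("need at least 2 ordered HU timepoints", "pb_bad_timepoints")
  }
  members <- consecutive_genes(calls, hu_contrast, hu_timepoints, direction)
  gene_set(
    label = sprintf("consecutive_%s", direction),
    members = members,
    provenance = sprintf(
      "%s at >= 2 consecutive of timepoints [%s] in contrast '%s'",
      direction, paste(hu_timepoints, collapse = ", "), hu_contrast)
  )
}

#' Define the drug-core responsive gene sets
#'
#' The core set of HU-responsive genes: genes differentially expressed *only*
#' upon HU exposure and at two or more consecutive timepoints. A gene enters
#' the up-core when it is up at >= 2 adjacent HU timepoints and shows no
#' differential expression in the untreated contrast; the down-core is
#' symmetric.
#'
#' @inheritParams consecutive_upregulation
#' @param untreated_contrast contrast label of the untreated comparison.
#' @param mode `"strict"` excludes genes DE in the untreated contrast at any
#'   sampled timepoint (default); `"lenient"` only at the first untreated
#'   timepoint.
#' @return list with `up` and `down` [gene_set()]s.
#' @export
define_hu_core <- function(calls, hu_contrast, hu_timepoints,
                           untreated_contrast,
                           mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  untreated <- dplyr::filter(calls, .data$contrast == untreated_contrast)
  if (mode == "lenient" && nrow(untreated) > 0) {
    first_tp <- untreated$timepoint[order(untreated$timepoint)][1]
    untreated <- dplyr::filter(untreated, .data$timepoint == first_tp)
  }
  de_untreated <- unique(untreated$gene_id[untreated$call != "none"])
  build <- function(direction) {
    consec <- consecutive_genes(calls, hu_contrast, hu_timepoints, direction)
    gene_set(
      label = sprintf("hu_core_%s", direction),
      members = setdiff(consec, de_untreated),
      provenance = c(
        sprintf("%s at >= 2 consecutive HU timepoints [%s]",
                direction, paste(hu_timepoints, collapse = ", ")),
        sprintf("not differentially expressed in '%s' (%s mode)",
                untreated_contrast, mode)
      )
    )
  }
  list(up = build("up"), down = build("down"))
}

#' Remove an exclusion list from a gene set
#'
#' Set difference with provenance: used to strip general environmental-stress
#' response genes from the drug-core sets so that only replication-stress
#' specific regulation remains.
#'
#' @param set a [gene_set()] (or character vector).
#' @param exclusion genes to remove ([gene_set()] or character vector).
#' @param exclusion_label label recorded in the provenance.
#' @return [gene_set()]; the number of genes removed is recorded in the
#'   provenance and in the `n_removed` attribute.
#' @export
remove_gene_list <- function(set, exclusion, exclusion_label = "exclusion list") {
  members <- as_members(set)
  removed <- intersect(members, as_members(exclusion))
  out <- gene_set(
    label = if (inherits(set, "pb_geneset")) set$label else "filtered",
    members = setdiff(members, removed),
    provenance = c(
      if (inherits(set, "pb_geneset")) set$provenance,
      sprintf("removed %d gene(s) present in %s", length(removed),
              exclusion_label)
    )
  )
  attr(out, "n_removed") <- length(removed)
  out
}

#' Candidate-target funnel: dual-screen suppressors with consecutive upregulation
#'
#' Intersects the suppressors recovered in both screens with the genes showing
#' increased transcript abundance at two or more consecutive drug timepoints —
#' the final filter of the candidate P-body-target funnel.
#'
#' @param dual_suppressors [gene_set()] or character vector of suppressors
#'   called in both screens (see [intersect_screens()]).
#' @param consec_up [gene_set()] from [consecutive_upregulation()].
#' @return [gene_set()] of candidate genes with the combined provenance.
#' @export
candidate_funnel <- function(dual_suppressors, consec_up) {
  gene_set(
    label = "candidate_targets",
    members = intersect(as_members(dual_suppressors), as_members(consec_up)),
    provenance = c(
      if (inherits(dual_suppressors, "pb_geneset")) dual_suppressors$provenance
      else "suppressor in both screens",
      if (inherits(consec_up, "pb_geneset")) consec_up$provenance
      else "up at >= 2 consecutive drug timepoints"
    )
  )
}

#' Overlap of a gene set with an external condition
#'
#' Fraction of set A also present in set B, with a hypergeometric enrichment
#' p-value for the overlap (delegating to [hypergeometric_overlap()]).
#'
#' @param set_a,set_b gene sets ([gene_set()] or character vectors).
#' @param universe shared gene universe.
#' @return one-row tibble: `n_a`, `n_b`, `n_overlap`, `fraction`
#'   (`|A ∩ B| / |A|`), `p_value`.
#' @export
overlap_with_condition <- function(set_a, set_b, universe) {
  a <- as_members(set_a)
  b <- as_members(set_b)
  if (length(a) == 0) {
    pb_abort("set A is empty; overlap fraction undefined", "pb_empty_set")
  }
  enr <- hypergeometric_overlap(a, b, universe)
  tibble(
    n_a = length(a),
    n_b = length(b),
    n_overlap = enr$observed_stat,
    fraction = enr$observed_stat / length(a),
    p_value = enr$p_value
  )
}
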