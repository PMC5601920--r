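#' Expected double-mutant fitness under the multiplicative model
#'
#' The null expectation for a double mutant's fitness is the product of the
#' two single mutants' control-normalized fitness values; deviations from it
#' define genetic interactions.
#'
#' @param f_a,f_b non-negative relative fitness values (vectorized).
#' @return `f_a * f_b`, symmetric in its arguments.
#' @examples
#' expected_double_fitness(0.8, 0.9) # 0.72
#' @export
expected_double_fitness <- function(f_a, f_b) {
  if (any(f_a < 0) || any(f_b < 0)) {
    pb_abort("relative fitness values must be non-negative", "pb_bad_fitness")
  }
  f_a * f_b
}

#' Score one pairwise genetic interaction in one condition
#'
#' Compares the observed double-mutant fitness with the multiplicative
#' expectation formed from the two single mutants. Expected values are built
#' per replicate by pairing single-mutant replicates in index order (or by
#' all-pairs products), and epsilon is the mean observed minus mean expected
#' fitness. Significance is a two-sided Student t-test of observed doubles
#' against expected products; a negative interaction is called when
#' `epsilon < 0` and `p < alpha`.
#'
#' @param single_a,single_b,double numeric vectors of replicate relative
#'   fitness values in the same condition; the double needs >= 2 replicates.
#' @param alpha significance threshold for the negative-interaction call.
#' @param var_equal pooled-variance Student t-test (default) or Welch.
#' @param pairing `"index"` (default) pairs single replicates in order
#'   (requires equal lengths); `"cross"` uses all pairwise products.
#' @return one-row tibble: `expected`, `observed`, `epsilon`,
#'   `p_interaction`, `negative_call`, `n_double`.
#' @export
score_interaction <- function(single_a, single_b, double, alpha = 0.05,
                              var_equal = TRUE,
                              pairing = c("index", "cross")) {
  pairing <- match.arg(pairing)
  if (any(c(single_a, single_b, double) < 0)) {
    pb_abort("relative fitness values must be non-negative", "pb_bad_fitness")
  }
  if (length(double) < 2) {
    pb_abort("need >= 2 double-mutant replicates to score an interaction",
             "pb_insufficient_replicates")
  }
  expected <- if (pairing == "index") {
    if (length(single_a) != length(single_b)) {
      pb_abort("index pairing requires equal single-mutant replicate counts",
               "pb_pairing_error")
    }
    expected_double_fitness(single_a, single_b)
  } else {
    as.vector(outer(single_a, single_b))
  }
  eps <- mean(double) - mean(expected)
  p <- if (stats::sd(double) == 0 && stats::sd(expected) == 0) {
    # both samples constant: identical means give no evidence, differing means
    # are unambiguous
    if (isTRUE(all.equal(mean(double), mean(expected)))) 1 else 0
  } else {
    stats::t.test(double, expected, var.equal = var_equal)$p.value
  }
  tibble(
    expected = mean(expected),
    observed = mean(double),
    epsilon = eps,
    p_interaction = p,
    negative_call = eps < 0 & p < alpha,
    n_double = length(double)
  )
}

#' Test whether an interaction is exacerbated by drug
#'
#' One-sided Student t-test of whether a double mutant's control-normalized
#' fitness is lower in drug than untreated. The edge weight reported for
#' network display is the difference of condition means (untreated minus
#' drug).
#'
#' @param fitness_untreated,fitness_drug numeric vectors of replicate relative
#'   fitness values for the double mutant in each condition.
#' @param alpha significance threshold for the exacerbation flag.
#' @param var_equal pooled-variance Student t-test (default) or Welch.
#' @return one-row tibble: `edge_weight`, `p_exacerbation`,
#'   `exacerbated_by_drug`.
#' @export
test_exacerbation <- function(fitness_untreated, fitness_drug, alpha = 0.05,
                              var_equal = TRUE) {
  if (length(fitness_untreated) < 2 || length(fitness_drug) < 2) {
    pb_abort("need >= 2 replicates in both conditions", "pb_insufficient_replicates")
  }
  p <- if (stats::sd(fitness_drug) == 0 && stats::sd(fitness_untreated) == 0) {
    # noiseless replicates: a strictly lower constant is unambiguous, anything
    # else carries no evidence of exacerbation
    if (mean(fitness_drug) < mean(fitness_untreated)) 0 else 1
  } else {
    stats::t.test(fitness_drug, fitness_untreated, alternative = "less",
                  var.equal = var_equal)$p.value
  }
  tibble(
    edge_weight = mean(fitness_untreated) - mean(fitness_drug),
    p_exacerbation = p,
    exacerbated_by_drug = p < alpha
  )
}

#' Score a set of double mutants in both conditions
#'
#' Maps [score_interaction()] over a table of gene pairs and conditions and
#' joins the drug-exacerbation test for each pair, producing the full
#' interaction-result table used for condition-dependent negative-interaction
#' counting and network export.
#'
#' @param fitness tibble of replicate-level relative fitness with columns
#'   `strain_id`, `condition`, `replicate`, `epsilon_rel` (as produced by
#'   [relative_fitness()]). Double mutants are named `"geneA:geneB"`.
#' @param pairs tibble with columns `gene_a`, `gene_b`.
#' @param untreated,drug condition labels (defaults `"untreated"`, `"HU"`).
#' @param alpha,var_equal,pairing passed to the underlying tests.
#' @return tibble of class `pb_interactions`, one row per pair x condition,
#'   with exacerbation columns repeated within pair.
#' @export
score_interactions <- function(fitness, pairs, untreated = "untreated",
                               drug = "HU", alpha = 0.05, var_equal = TRUE,
                               pairing = c("index", "cross")) {
  pairing <- match.arg(pairing)
  assert_columns(fitness, c("strain_id", "condition", "replicate",
                            "epsilon_rel"), "fitness table")
  assert_columns(pairs, c("gene_a", "gene_b"), "pairs table")
  get_fit <- function(strain, cond) {
    fitness$epsilon_rel[fitness$strain_id == strain &
                          fitness$condition == cond]
  }
  rows <- purrr::pmap(pairs, function(gene_a, gene_b, ...) {
    dbl_name <- paste(gene_a, gene_b, sep = ":")
    if (!dbl_name %in% fitness$strain_id) {
      dbl_name <- paste(gene_b, gene_a, sep = ":")
    }
    per_cond <- purrr::map(c(untreated, drug), function(cond) {
      res <- score_interaction(get_fit(gene_a, cond), get_fit(gene_b, cond),
                               get_fit(dbl_name, cond), alpha = alpha,
                               var_equal = var_equal, pairing = pairing)
      dplyr::bind_cols(tibble(gene_a = gene_a, gene_b = gene_b,
                              condition = cond), res)
    }) |> purrr::list_rbind()
    exac <- test_exacerbation(get_fit(dbl_name, untreated),
                              get_fit(dbl_name, drug),
                              alpha = alpha, var_equal = var_equal)
    dplyr::bind_cols(per_cond, exac[rep(1, nrow(per_cond)), ])
  })
  out <- purrr::list_rbind(rows)
  class(out) <- c("pb_interactions", class(out))
  attr(out, "conditions") <- c(untreated = untreated, drug = drug)
  attr(out, "alpha") <- alpha
  out
}

#' Count condition-dependent negative genetic interactions
#'
#' A pair qualifies when it is called a negative interaction in the drug
#' condition and its fitness defect is significantly exacerbated by the drug.
#'
#' @param results `pb_interactions` table from [score_interactions()].
#' @param alpha significance threshold applied to both tests.
#' @return list with `count` and the qualifying `table`.
#' @export
count_condition_dependent_negatives <- function(results, alpha = 0.05) {
  assert_columns(results, c("gene_a", "gene_b", "condition", "epsilon",
                            "p_interaction", "p_exacerbation"),
                 "interaction results")
  conds <- attr(results, "conditions")
  drug <- if (!is.null(conds)) conds[["drug"]] else "HU"
  qual <- results |>
    dplyr::filter(.data$condition == drug,
                  .data$epsilon < 0,
                  .data$p_interaction < alpha,
                  .data$p_exacerbation < alpha)
  list(count = nrow(qual), table = qual)
}

#' Build a two-drug synergy matrix
#'
#' Bliss-style independence analysis of a complete two-drug concentration
#' grid: the expected fitness of each combination is the product of the two
#' single-drug fitness values at the corresponding concentrations, and the
#' interaction score is observed minus expected. Negative values indicate
#' synergy. All fitness values must be normalized to the no-drug condition, so
#' the zero-concentration row and column have interaction 0 by construction.
#'
#' @param single_a,single_b tibbles with columns `conc`, `fitness` for each
#'   drug alone, including the zero concentration with fitness 1.
#' @param combos tibble with columns `conc_a`, `conc_b`, `fitness` covering
#'   every pair of non-zero concentrations (replicates are averaged if a
#'   `replicate` column is present).
#' @param drug_a,drug_b display names for the two drugs.
#' @return object of class `pb_synergy`: concentration vectors plus
#'   `observed`, `expected` and `interaction` matrices (rows = drug A).
#'   Has [tidy()] and [ggplot2::autoplot()] methods.
#' @export
build_synergy_matrix <- function(single_a, single_b, combos,
                                 drug_a = "drug_a", drug_b = "drug_b") {
  assert_columns(single_a, c("conc", "fitness"), "single_a")
  assert_columns(single_b, c("conc", "fitness"), "single_b")
  assert_columns(combos, c("conc_a", "conc_b", "fitness"), "combos")
  single_a <- dplyr::arrange(single_a, .data$conc)
  single_b <- dplyr::arrange(single_b, .data$conc)
  for (s in list(single_a, single_b)) {
    if (s$conc[1] != 0) {
      pb_abort("single-drug series must include the zero concentration",
               "pb_bad_grid")
    }
  }
  if ("replicate" %in% names(combos)) {
    combos <- combos |>
      dplyr::group_by(.data$conc_a, .data$conc_b) |>
      dplyr::summarise(fitness = mean(.data$fitness), .groups = "drop")
  }
  ca <- single_a$conc
  cb <- single_b$conc
  fa <- single_a$fitness
  fb <- single_b$fitness
  observed <- outer(fa, fb) # margins from the single-drug series
  need <- expand.grid(conc_a = ca[-1], conc_b = cb[-1])
  have <- paste(combos$conc_a, combos$conc_b)
  missing <- need[!paste(need$conc_a, need$conc_b) %in% have, ]
  if (nrow(missing) > 0) {
    pb_abort(sprintf("missing combination cell(s): %s",
                     paste(sprintf("(%g, %g)", missing$conc_a, missing$conc_b),
                           collapse = ", ")),
             "pb_bad_grid")
  }
  for (i in seq_len(nrow(combos))) {
    ia <- match(combos$conc_a[i], ca)
    ib <- match(combos$conc_b[i], cb)
    if (is.na(ia) || is.na(ib)) {
      pb_abort(sprintf("combination (%g, %g) is off the concentration grid",
                       combos$conc_a[i], combos$conc_b[i]), "pb_bad_grid")
    }
    observed[ia, ib] <- combos$fitness[i]
  }
  expected <- outer(fa, fb)
  structure(
    list(drug_a = drug_a, drug_b = drug_b,
         conc_a = ca, conc_b = cb,
         observed = observed, expected = expected,
         interaction = observed - expected),
    class = "pb_synergy"
  )
}

#' @export
print.pb_synergy <- function(x, ...) {
  cat(sprintf("<pb_synergy> %s x %s (%d x %d grid)\n", x$drug_a, x$drug_b,
              length(x$conc_a), length(x$conc_b)))
  cat(sprintf("  strongest synergy: %.3f (negative = synergy)\n",
              min(x$interaction)))
  invisible(x)
}
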