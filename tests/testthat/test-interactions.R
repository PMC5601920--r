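test_that("multiplicative expectation is a symmetric product with a sign guard", {
  expect_equal(expected_double_fitness(1, 1), 1)
  expect_equal(expected_double_fitness(0.8, 0.9), 0.72)
  expect_equal(expected_double_fitness(0.37, 0), 0)
  expect_equal(expected_double_fitness(0.8, 0.9), expected_double_fitness(0.9, 0.8))
  expect_error(expected_double_fitness(-0.1, 1), class = "pb_bad_fitness")
})

test_that("interaction scoring matches the t-test oracle and calls negatives", {
  # observed equals expected: epsilon 0, p near 1, no call
  res0 <- score_interaction(c(0.8, 0.8, 0.8), c(0.9, 0.9, 0.9),
                            c(0.72, 0.72 + 1e-9, 0.72 - 1e-9))
  expect_equal(res0$epsilon, 0, tolerance = 1e-6)
  expect_false(res0$negative_call)

  # singles 0.8 / 0.9, doubles near 0.50: strong negative interaction
  set.seed(8)
  sa <- 0.8 + rnorm(5, 0, 0.01)
  sb <- 0.9 + rnorm(5, 0, 0.01)
  dbl <- 0.50 + rnorm(5, 0, 0.01)
  res <- score_interaction(sa, sb, dbl)
  expect_equal(res$epsilon, mean(dbl) - mean(sa * sb), tolerance = 1e-12)
  expect_lt(abs(res$epsilon - (-0.22)), 0.03)
  expect_true(res$negative_call)
  expect_equal(res$p_interaction, oracle_t_pooled(dbl, sa * sb),
               tolerance = 1e-9)
  # symmetric in the two singles
  expect_equal(score_interaction(sb, sa, dbl)$epsilon, res$epsilon)
  expect_error(score_interaction(sa, sb, 0.5),
               class = "pb_insufficient_replicates")
})

test_that("drug exacerbation is a one-sided t-test with mean-difference edge weight", {
  set.seed(9)
  untr <- rep(0.9, 5) + rnorm(5, 0, 0.02)
  drug <- rep(0.5, 5) + rnorm(5, 0, 0.02)
  res <- test_exacerbation(untr, drug)
  expect_true(res$exacerbated_by_drug)
  expect_lt(abs(res$edge_weight - 0.4), 0.05)
  expect_equal(res$p_exacerbation, oracle_t_pooled(drug, untr, "less"),
               tolerance = 1e-9)
  # identical distributions: p around 1/2, no call
  same <- rnorm(6, 0.8, 0.02)
  res2 <- test_exacerbation(same, same)
  expect_equal(res2$p_exacerbation, 0.5, tolerance = 1e-9)
  expect_false(res2$exacerbated_by_drug)
})

test_that("planted epsilons are recovered through the growth closed loop", {
  sf <- tibble::tibble(
    strain_id = rep(c("a", "b"), each = 2),
    condition = rep(c("untreated", "HU"), 2),
    fitness = c(0.9, 0.8, 0.85, 0.7))
  eps <- tibble::tibble(gene_a = "a", gene_b = "b",
                        condition = c("untreated", "HU"), eps = c(0, -0.25))
  # noiseless: epsilon equals planted value to 1e-6
  cfg0 <- growth_sim_config(noise_sd = 0, single_fitness = sf,
                            interaction_eps = eps, seed = 11)
  sim0 <- simulate_growth_curves(cfg0, n_replicates = 3)
  rel0 <- relative_fitness(growth_auc(sim0$curves), "control")
  ints0 <- score_interactions(rel0, tibble::tibble(gene_a = "a", gene_b = "b"))
  expect_equal(ints0$epsilon[ints0$condition == "untreated"], 0,
               tolerance = 1e-6)
  expect_equal(ints0$epsilon[ints0$condition == "HU"], -0.25,
               tolerance = 1e-6)

  # noisy Monte-Carlo: planted eps = -0.25 detected in >= 90% of seeds,
  # recovered within +/- 0.03
  hits <- sapply(1:20, function(s) {
    cfg <- growth_sim_config(noise_sd = 0.01, single_fitness = sf,
                             interaction_eps = eps, seed = s)
    rel <- relative_fitness(
      growth_auc(simulate_growth_curves(cfg, n_replicates = 5)$curves),
      "control")
    ints <- score_interactions(rel, tibble::tibble(gene_a = "a", gene_b = "b"))
    hu <- ints[ints$condition == "HU", ]
    c(called = hu$negative_call && hu$p_interaction < 0.05,
      err = abs(hu$epsilon + 0.25))
  })
  expect_gte(mean(hits["called", ]), 0.9)
  expect_lt(max(hits["err", ]), 0.03)
})

test_that("synergy matrices have Bliss semantics, zero margins, and exact closed loop", {
  single_a <- tibble::tibble(conc = c(0, 1, 2), fitness = c(1, 0.9, 0.7))
  single_b <- tibble::tibble(conc = c(0, 5, 10), fitness = c(1, 0.8, 0.6))
  combos <- tidyr::expand_grid(conc_a = c(1, 2), conc_b = c(5, 10)) |>
    dplyr::mutate(fitness = c(0.72, 0.54, 0.56, 0.42)) # = products: no synergy
  syn <- build_synergy_matrix(single_a, single_b, combos)
  expect_equal(syn$interaction, matrix(0, 3, 3), tolerance = 1e-12)
  expect_equal(syn$interaction[1, ], rep(0, 3)) # zero-concentration margins
  expect_equal(syn$interaction[, 1], rep(0, 3))

  # single cell: observed 0.5 against 0.9 x 0.8 expectation
  combos2 <- dplyr::mutate(combos,
                           fitness = ifelse(conc_a == 1 & conc_b == 5, 0.5, fitness))
  syn2 <- build_synergy_matrix(single_a, single_b, combos2)
  expect_equal(syn2$interaction[2, 2], 0.5 - 0.72, tolerance = 1e-12)
  expect_true(tidy(syn2)$synergy[tidy(syn2)$conc_a == 1 & tidy(syn2)$conc_b == 5])

  expect_error(build_synergy_matrix(single_a, single_b, combos[-1, ]),
               class = "pb_bad_grid")

  # noiseless grid simulation returns the planted truth exactly
  truth <- matrix(0, 6, 6); truth[3, 4] <- -0.15; truth[5, 5] <- -0.2
  cfg <- growth_sim_config(noise_sd = 0, seed = 13)
  sim <- simulate_synergy_curves(cfg, synergy_truth = truth)
  syn3 <- synergy_from_curves(sim$curves)
  expect_equal(syn3$interaction, truth, tolerance = 1e-9)
})

test_that("condition-dependent negative counting is threshold-monotone", {
  sf <- tibble::tibble(
    strain_id = rep(c("a", "b", "c"), each = 2),
    condition = rep(c("untreated", "HU"), 3),
    fitness = c(0.9, 0.8, 0.85, 0.7, 0.95, 0.9))
  eps <- tibble::tibble(
    gene_a = c("a", "a", "a", "a", "b", "b"),
    gene_b = c("b", "b", "c", "c", "c", "c"),
    condition = rep(c("untreated", "HU"), 3),
    eps = c(0, -0.3, 0, 0, 0, 0))
  cfg <- growth_sim_config(noise_sd = 0.005, single_fitness = sf,
                           interaction_eps = eps, seed = 17)
  rel <- relative_fitness(
    growth_auc(simulate_growth_curves(cfg, n_replicates = 5)$curves), "control")
  ints <- score_interactions(rel, dplyr::distinct(eps, gene_a, gene_b))
  n05 <- count_condition_dependent_negatives(ints, 0.05)
  n01 <- count_condition_dependent_negatives(ints, 0.01)
  expect_lte(n01$count, n05$count)
  expect_equal(n05$count, 1)
  expect_equal(n05$table$gene_a, "a")
  expect_equal(n05$table$gene_b, "b")
})
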