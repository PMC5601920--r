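make_calls <- function(...) {
  # build a calls table from gene -> list(contrast, timepoint, call) triples
  df <- tibble::tribble(...)
  df$log2_ratio <- ifelse(df$call == "up", 1, ifelse(df$call == "down", -1, 0))
  df$q_value <- ifelse(df$call == "none", 0.9, 0.01)
  df
}

test_that("differential calls follow the q < alpha rule with sign-based direction", {
  records <- tibble::tibble(
    gene_id = c("a", "b", "c", "d"),
    contrast = "hu", timepoint = "1h",
    log2_ratio = c(1.2, -0.8, 0.5, 0),
    q_value = c(0.049, 0.02, 1.0, 0.001)
  )
  calls <- call_differential(records, alpha = 0.05)
  expect_equal(calls$call, c("up", "down", "none", "none"))

  # q recomputed from p matches a brute-force BH oracle, family by family
  set.seed(5)
  toy <- tidyr::expand_grid(gene_id = sprintf("g%02d", 1:10),
                            contrast = c("c1", "c2"), timepoint = c("t1", "t2")) |>
    dplyr::mutate(log2_ratio = rnorm(dplyr::n()), p_value = runif(dplyr::n()))
  calls2 <- call_differential(toy, alpha = 0.05)
  oracle <- toy |>
    dplyr::group_by(contrast, timepoint) |>
    dplyr::mutate(q_oracle = oracle_bh(p_value)) |>
    dplyr::ungroup()
  expect_equal(calls2$q_value, oracle$q_oracle, tolerance = 1e-12)

  # monotone in alpha: stricter calls are a subset
  up01 <- calls2$gene_id[call_differential(toy, 0.2)$call == "up"]
  up05 <- calls2$gene_id[call_differential(toy, 0.5)$call == "up"]
  expect_true(all(up01 %in% up05))
  expect_error(call_differential(dplyr::select(toy, -p_value)),
               class = "pb_missing_pvalues")
})

test_that("consecutive upregulation requires adjacency in the ordered timepoints", {
  tps <- c("1h", "2h", "4h")
  calls <- make_calls(
    ~gene_id, ~contrast, ~timepoint, ~call,
    "adj12", "hu", "1h", "up",   "adj12", "hu", "2h", "up",
    "gap14", "hu", "1h", "up",   "gap14", "hu", "2h", "none",
    "gap14", "hu", "4h", "up",
    "all",   "hu", "1h", "up",   "all",   "hu", "2h", "up",
    "all",   "hu", "4h", "up",
    "adj24", "hu", "2h", "up",   "adj24", "hu", "4h", "up"
  )
  set <- consecutive_upregulation(calls, "hu", tps)
  expect_setequal(set$members, c("adj12", "all", "adj24"))
  expect_false("gap14" %in% set$members) # 1h & 4h are not adjacent
  expect_error(consecutive_upregulation(calls, "hu", "1h"),
               class = "pb_bad_timepoints")
})

test_that("the drug-core set excludes genes responding without drug", {
  tps <- c("1h", "2h", "4h")
  calls <- make_calls(
    ~gene_id, ~contrast, ~timepoint, ~call,
    "core",    "hu", "2h", "up",  "core",    "hu", "4h", "up",
    "core",    "untr", "0h", "none",
    "general", "hu", "2h", "up",  "general", "hu", "4h", "up",
    "general", "untr", "0h", "up",
    "coredn",  "hu", "1h", "down", "coredn", "hu", "2h", "down",
    "coredn",  "untr", "0h", "none"
  )
  core <- define_hu_core(calls, "hu", tps, "untr")
  expect_equal(core$up$members, "core")
  expect_equal(core$down$members, "coredn")
  # core sets are subsets of the consecutive sets for the same calls
  expect_true(all(core$up$members %in%
                    consecutive_upregulation(calls, "hu", tps)$members))
})

test_that("gene-list removal, funnel intersection and their commutation", {
  s <- gene_set("s", c("a", "b", "c"))
  expect_equal(remove_gene_list(s, "b")$members, c("a", "c"))
  expect_equal(remove_gene_list(s, character())$members, s$members)
  expect_equal(attr(remove_gene_list(s, c("a", "z")), "n_removed"), 1)

  # funnel is plain intersection with provenance
  funnel <- candidate_funnel(gene_set("dual", c("a", "b", "d")),
                             gene_set("consec", c("b", "d", "e")))
  expect_setequal(funnel$members, c("b", "d"))
  expect_equal(candidate_funnel(gene_set("dual", character(),
                                         provenance = "empty screen"),
                                gene_set("consec", c("x")))$members,
               character(0))
  expect_gt(length(funnel$provenance), 1)

  # remove-then-intersect equals intersect-then-remove
  excl <- c("b", "q")
  left <- candidate_funnel(remove_gene_list(gene_set("dual", c("a", "b", "d")), excl),
                           remove_gene_list(gene_set("consec", c("b", "d", "e")), excl))
  right <- remove_gene_list(funnel, excl)
  expect_setequal(left$members, right$members)
})

test_that("overlap fraction and enrichment p match brute force on a 20-gene universe", {
  uni <- sprintf("g%02d", 1:20)
  a <- uni[1:8]
  b <- uni[5:12]
  ov <- overlap_with_condition(a, b, uni)
  expect_equal(ov$fraction, 4 / 8)
  expect_equal(ov$p_value, oracle_hyper_enum(a, b, uni), tolerance = 1e-9)
  expect_equal(overlap_with_condition(a, a, uni)$fraction, 1)
  expect_equal(overlap_with_condition(a, uni[9:20], uni)$fraction, 0)
  expect_error(overlap_with_condition(character(), b, uni),
               class = "pb_empty_set")
})

test_that("planted expression truth is recovered exactly without noise", {
  planted <- sprintf("g%04d", c(3, 77, 500, 801))
  cfg <- expression_sim_config(n_genes = 1000, de_fraction_up = 0,
                               de_fraction_down = 0, null_log2_sd = 0,
                               consecutive_up_genes = planted, seed = 9)
  sim <- simulate_expression_table(cfg)
  calls <- call_differential(sim$records, 0.05)
  consec <- consecutive_upregulation(calls, cfg$hu_contrast, cfg$hu_timepoints)
  expect_setequal(consec$members, planted)
  core <- define_hu_core(calls, cfg$hu_contrast, cfg$hu_timepoints,
                         cfg$untreated_contrast)
  expect_setequal(core$up$members, planted)
  expect_equal(core$down$members, character(0))
})
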