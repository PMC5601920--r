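test_that("every generator is deterministic under a fixed seed", {
  supp <- sprintf("strain_%04d", 1:5)
  cfg <- screen_sim_config(grid_rows = 8, grid_cols = 12,
                           suppressor_genes = supp, sick_fraction = 0.1,
                           seed = 7)
  expect_identical(simulate_plate_set(cfg), simulate_plate_set(cfg))

  ecfg <- expression_sim_config(n_genes = 100,
                                consecutive_up_genes = c("g0001", "g0002"),
                                seed = 7)
  expect_identical(simulate_expression_table(ecfg),
                   simulate_expression_table(ecfg))

  gcfg <- growth_sim_config(
    single_fitness = tibble::tibble(strain_id = "m", condition = "untreated",
                                    fitness = 0.8),
    conditions = "untreated", seed = 7)
  expect_identical(simulate_growth_curves(gcfg, 2),
                   simulate_growth_curves(gcfg, 2))
  expect_identical(
    simulate_interaction_network(50, 0.05, seed = 7),
    simulate_interaction_network(50, 0.05, seed = 7))
  # generators restore the caller's RNG stream
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(simulate_plate_set(cfg)); after <- runif(1)
  expect_identical(before, after)
})

test_that("truth logs are exhaustive and match the planted configuration", {
  supp <- sprintf("strain_%04d", c(1, 5, 9))
  cfg <- screen_sim_config(grid_rows = 8, grid_cols = 12,
                           suppressor_genes = supp, sick_fraction = 0.25,
                           seed = 3)
  sim <- simulate_plate_set(cfg)
  expect_setequal(sim$truth$strain_id[sim$truth$role == "suppressor"], supp)
  expect_equal(sum(sim$truth$role == "sick"), floor(0.25 * 24))
  expect_setequal(sim$truth$strain_id, cfg$strain_ids)
  # suppressors are never also sick
  expect_false(any(sim$truth$role == "sick" &
                     sim$truth$strain_id %in% supp))

  ecfg <- expression_sim_config(n_genes = 200, de_fraction_up = 0.1,
                                de_fraction_down = 0.05,
                                consecutive_up_genes = c("g0010", "g0020"),
                                seed = 3)
  esim <- simulate_expression_table(ecfg)
  # every planted consecutive gene is logged at all HU timepoints
  consec_rows <- dplyr::filter(esim$truth, gene_id %in% c("g0010", "g0020"))
  expect_equal(nrow(consec_rows), 2 * length(ecfg$hu_timepoints))
  expect_true(all(consec_rows$direction == "up"))
  # and never in the untreated contrast
  expect_false(any(consec_rows$contrast == ecfg$untreated_contrast))
})

test_that("plate layout gives each strain one contiguous replicate block", {
  cfg <- screen_sim_config(grid_rows = 8, grid_cols = 12, seed = 2)
  sim <- simulate_plate_set(cfg)
  one <- dplyr::filter(sim$plates, plate_id == sim$plates$plate_id[1])
  counts <- dplyr::count(one, strain_id)
  expect_true(all(counts$n == 4))
  spans <- one |>
    dplyr::group_by(strain_id) |>
    dplyr::summarise(dr = max(row) - min(row), dc = max(col) - min(col))
  expect_true(all(spans$dr == 1 & spans$dc == 1))
  # grid too small for the strain universe
  expect_error(screen_sim_config(grid_rows = 8, grid_cols = 12,
                                 strain_ids = sprintf("s%03d", 1:999)),
               class = "pb_sizing_error")
})

test_that("the noiseless screen closed loop recovers planted roles exactly", {
  supp <- sprintf("strain_%04d", c(2, 11, 23))
  cfg <- screen_sim_config(grid_rows = 8, grid_cols = 12, noise_cv = 0,
                           plate_effect_sd = 0.1, sick_fraction = 0.2,
                           suppressor_genes = supp, seed = 5)
  sim <- simulate_plate_set(cfg)
  hits <- tidy(score_screen(sim$plates))
  expect_setequal(hits$strain_id[hits$call == "suppressor"], supp)
  # sick strains were removed by the small-colony filter, not called
  sick <- sim$truth$strain_id[sim$truth$role == "sick"]
  expect_true(all(hits$call[hits$strain_id %in% sick] == "uncallable"))
  # and all remaining strains are unremarkable
  neutral <- setdiff(hits$strain_id, c(supp, sick))
  expect_true(all(hits$call[hits$strain_id %in% neutral] == "none"))
})

test_that("planted suppressors are recovered with high recall and low FPR", {
  supp <- sprintf("strain_%04d", 1:20)
  stats <- sapply(1:10, function(s) {
    cfg <- screen_sim_config(suppressor_genes = supp, noise_cv = 0.15,
                             sick_fraction = 0, seed = s)
    hits <- tidy(score_screen(simulate_plate_set(cfg)$plates))
    called <- hits$strain_id[hits$call == "suppressor"]
    c(recall = mean(supp %in% called),
      fpr = mean(setdiff(hits$strain_id, supp) %in% called))
  })
  expect_gte(mean(stats["recall", ]), 0.9)
  expect_lte(mean(stats["fpr", ]), 0.05)
})

test_that("expression generator behaves at the null and recovers planted DE", {
  # null table: BH controls false discoveries near zero
  null_cfg <- expression_sim_config(n_genes = 500, de_fraction_up = 0,
                                    de_fraction_down = 0, seed = 21)
  null_calls <- call_differential(simulate_expression_table(null_cfg)$records)
  expect_lte(sum(null_calls$call != "none"), 5)

  # planted recovery across seeds (hu-core caller at q < 0.05)
  recalls <- sapply(1:10, function(s) {
    planted <- sprintf("g%04d", 1:50)
    cfg <- expression_sim_config(n_genes = 1000,
                                 consecutive_up_genes = planted, seed = s)
    sim <- simulate_expression_table(cfg)
    calls <- call_differential(sim$records, 0.05)
    core <- define_hu_core(calls, cfg$hu_contrast, cfg$hu_timepoints,
                           cfg$untreated_contrast)
    mean(planted %in% core$up$members)
  })
  expect_gte(mean(recalls), 0.85)
})

test_that("network generator respects density bounds and planted enrichment", {
  expect_equal(nrow(simulate_interaction_network(50, 0, seed = 1)$edges), 0)
  expect_error(simulate_interaction_network(50, 0.3, enrichment_factor = 5),
               class = "pb_bad_config")
  net <- simulate_interaction_network(100, 0.05, seed = 2)
  expect_false(any(net$edges$gene_a == net$edges$gene_b))
  expect_equal(anyDuplicated(paste(net$edges$gene_a, net$edges$gene_b)), 0L)
  # realized density close to nominal
  expect_lt(abs(nrow(net$edges) / choose(100, 2) - 0.05), 0.02)
})
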