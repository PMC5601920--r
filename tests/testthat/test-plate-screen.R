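test_that("replicate colony blocks collapse to means and incomplete blocks are flagged", {
  plate <- toy_plate_pair(list(a = c(100, 50), b = c(200, 100)))
  nd <- collapse_replicate_colonies(dplyr::filter(plate, condition == "no_drug"))
  expect_equal(nd$size[nd$strain_id == "a"], 100) # four identical colonies
  # non-identical quadruplicate: arithmetic mean
  plate2 <- toy_plate_pair(list(a = c(100, 50)))
  plate2$size[plate2$condition == "no_drug"] <- c(80, 120, 90, 110)
  nd2 <- collapse_replicate_colonies(dplyr::filter(plate2, condition == "no_drug"))
  expect_equal(nd2$size, 100)
  # a block missing one colony is flagged, not averaged
  incomplete <- dplyr::filter(plate, condition == "no_drug")[-1, ]
  ndi <- collapse_replicate_colonies(incomplete)
  expect_true(ndi$incomplete[ndi$strain_id == "a"])
  expect_true(is.na(ndi$size[ndi$strain_id == "a"]))
})

test_that("fitness is the drug/no-drug size ratio with zero-size exclusions", {
  plate <- toy_plate_pair(list(a = c(500, 500), b = c(400, 0), c = c(0, 100)))
  coll <- collapse_replicate_colonies(plate)
  fit <- compute_fitness(dplyr::filter(coll, condition == "no_drug"),
                         dplyr::filter(coll, condition == "drug"))
  expect_equal(fit$fitness[fit$strain_id == "a"], 1)
  expect_equal(fit$fitness[fit$strain_id == "b"], 0) # lethal in drug
  expect_true(fit$excluded[fit$strain_id == "c"])   # division by zero
  expect_equal(fit$exclude_reason[fit$strain_id == "c"], "zero_no_drug_colony")

  # 16-strain toy plate: elementwise ratios equal direct division
  sizes <- setNames(
    lapply(1:16, function(i) c(100 + 10 * i, 50 + 5 * i)),
    paste0("s", 1:16))
  coll16 <- collapse_replicate_colonies(toy_plate_pair(sizes))
  fit16 <- compute_fitness(dplyr::filter(coll16, condition == "no_drug"),
                           dplyr::filter(coll16, condition == "drug"))
  for (i in 1:16) {
    expect_equal(fit16$fitness[fit16$strain_id == paste0("s", i)],
                 (50 + 5 * i) / (100 + 10 * i))
  }
  # mismatched layouts are a pairing error
  expect_error(
    compute_fitness(dplyr::filter(coll, condition == "no_drug"),
                    dplyr::filter(coll16, condition == "drug")),
    class = "pb_pairing_error")
})

test_that("small no-drug colonies are excluded under fractional and absolute rules", {
  sizes <- c(list(tiny = c(40, 20)),
             setNames(lapply(1:8, function(i) c(400, 200)), paste0("s", 1:8)))
  coll <- collapse_replicate_colonies(toy_plate_pair(sizes))
  fit <- compute_fitness(dplyr::filter(coll, condition == "no_drug"),
                         dplyr::filter(coll, condition == "drug"))
  # 40 is 10% of the plate median (400): excluded at the 50% rule
  f1 <- filter_small_colonies(fit, list(type = "fraction_of_median", value = 0.5))
  expect_equal(f1$exclude_reason[f1$strain_id == "tiny"], "small_no_drug_colony")
  expect_equal(attr(f1, "n_small_excluded"), 1)
  # equal colonies: nothing excluded under a fractional rule < 1
  fit_eq <- dplyr::mutate(fit, size_no_drug = 400)
  f2 <- filter_small_colonies(fit_eq, list(type = "fraction_of_median", value = 0.9))
  expect_equal(attr(f2, "n_small_excluded"), 0)
  # absolute threshold 0 excludes nothing
  f3 <- filter_small_colonies(fit, list(type = "absolute", value = 0))
  expect_equal(attr(f3, "n_small_excluded"), 0)
})

test_that("per-plate Z-scores normalize, flag degenerate plates, and resist affine rescaling", {
  recs <- tibble::tibble(strain_id = c("a", "b", "c"), replicate = 1L,
                         plate_id = "p1", fitness = c(1, 2, 3),
                         excluded = FALSE)
  expect_equal(zscore_per_plate(recs)$z, c(-1, 0, 1))

  # zero-variance plate: degenerate, missing z, warning
  flat <- dplyr::mutate(recs, fitness = 2)
  expect_warning(zf <- zscore_per_plate(flat), "degenerate")
  expect_true(all(is.na(zf$z)))
  expect_true(all(zf$degenerate))

  # normalization property on a simulated 100-strain plate
  set.seed(1)
  big <- tibble::tibble(strain_id = sprintf("s%03d", 1:100), replicate = 1L,
                        plate_id = "p1", fitness = rlnorm(100, 0, 0.3),
                        excluded = FALSE)
  zb <- zscore_per_plate(big)$z
  expect_equal(mean(zb), 0, tolerance = 1e-9)
  expect_equal(sd(zb), 1, tolerance = 1e-9)

  # affine invariance (plate-effect removal) and idempotence
  shifted <- dplyr::mutate(big, fitness = 3.7 * fitness + 0.4)
  expect_equal(zscore_per_plate(shifted)$z, zb, tolerance = 1e-9)
  rescored <- tibble::tibble(strain_id = big$strain_id, replicate = 1L,
                             plate_id = "p1", fitness = zb, excluded = FALSE)
  expect_equal(zscore_per_plate(rescored)$z, zb, tolerance = 1e-9)
})

test_that("hit calls follow the +/-1 mean-Z thresholds and replicate minimum", {
  zs <- tibble::tibble(
    strain_id = rep(c("supp", "sick", "flat", "lonely"), each = 3),
    replicate = rep(1:3, 4),
    plate_id = "p",
    z = c(1.5, 0.5, 1.0,   -1.2, -0.8, -1.0,   0.1, -0.1, 0,   2, NA, NA)
  )
  hits <- call_hits(zs, min_replicates = 2)
  expect_equal(hits$call[hits$strain_id == "supp"], "suppressor")   # mean 1.0
  expect_equal(hits$call[hits$strain_id == "sick"], "synthetic_sick") # mean -1.0
  expect_equal(hits$call[hits$strain_id == "flat"], "none")
  expect_equal(hits$call[hits$strain_id == "lonely"], "uncallable")
  expect_equal(hits$n_replicates[hits$strain_id == "lonely"], 1)
  # the boundary is inclusive on both sides
  expect_true(all(hits$call[abs(hits$mean_z) >= 1 &
                              hits$n_replicates >= 2] != "none"))
})

test_that("hit calling is monotone in drug colony size", {
  set.seed(20)
  sizes <- setNames(lapply(1:9, function(i) c(400, runif(1, 100, 300))),
                    paste0("s", 1:9))
  base <- toy_plate_pair(sizes)
  score_one <- function(plates) {
    coll <- collapse_replicate_colonies(plates)
    fit <- compute_fitness(dplyr::filter(coll, condition == "no_drug"),
                           dplyr::filter(coll, condition == "drug"))
    call_hits(zscore_per_plate(fit), min_replicates = 1)
  }
  h0 <- score_one(base)
  raised <- dplyr::mutate(base, size = ifelse(
    condition == "drug" & strain_id == "s5", size * 1.5, size))
  h1 <- score_one(raised)
  expect_gte(h1$mean_z[h1$strain_id == "s5"], h0$mean_z[h0$strain_id == "s5"])
})

test_that("dual-screen intersection has set semantics and reports counts", {
  mk <- function(supp, none) tibble::tibble(
    strain_id = c(supp, none),
    call = rep(c("suppressor", "none"), c(length(supp), length(none))))
  both <- intersect_screens(mk(c("x", "y"), "z"), mk(c("y", "z"), "x"))
  expect_equal(both$strain_id, "y")
  expect_equal(attr(both, "counts"),
               c(n_a = 2, n_b = 2, n_both = 1))
  empty <- intersect_screens(mk("x", "y"), mk("y", "x"))
  expect_equal(nrow(empty), 0)
})

test_that("dual-screen intersection is a subset of each screen's hits on simulation", {
  supp <- sprintf("strain_%04d", 1:20)
  cfg_a <- screen_sim_config(grid_rows = 16, grid_cols = 24,
                             suppressor_genes = supp, seed = 31)
  cfg_b <- screen_sim_config(grid_rows = 16, grid_cols = 24,
                             suppressor_genes = supp, seed = 32)
  hits_a <- tidy(score_screen(simulate_plate_set(cfg_a)$plates))
  hits_b <- tidy(score_screen(simulate_plate_set(cfg_b)$plates))
  both <- intersect_screens(hits_a, hits_b)
  expect_true(all(both$strain_id %in%
                    hits_a$strain_id[hits_a$call == "suppressor"]))
  expect_true(all(both$strain_id %in%
                    hits_b$strain_id[hits_b$call == "suppressor"]))
})
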