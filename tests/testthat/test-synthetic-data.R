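test_that("parcellation has unique ids, positive distances, and is seed-deterministic", {
  p <- gen_parcellation(100, seed = 1)
  expect_equal(nrow(p), 100)
  expect_false(any(duplicated(p$parcel_id)))
  d <- parcel_dist(p)
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  expect_true(all(d[upper.tri(d)] > 0))
  expect_identical(p, gen_parcellation(100, seed = 1))
  expect_false(identical(p, gen_parcellation(100, seed = 2)))
  expect_error(gen_parcellation(5), "n_parcels")
})

test_that("null group time series carry no systematic ALFF difference", {
  p <- gen_parcellation(27, seed = 3)
  ts <- gen_group_timeseries(p, 40, 80, effect_size = 0, seed = 4)
  a1 <- t(sapply(ts$group1, alff_map, tr = ts$tr))
  a2 <- t(sapply(ts$group2, alff_map, tr = ts$tr))
  d <- (colMeans(a2) - colMeans(a1)) /
    sqrt((apply(a1, 2, var) + apply(a2, 2, var)) / 2)
  expect_lt(abs(mean(d)), 0.1)
})

test_that("planted effect parcels show the largest group ALFF differences", {
  p <- gen_parcellation(64, seed = 5)
  eff <- p$parcel_id[1:4]
  ts <- gen_group_timeseries(p, 30, 80, effect_parcels = eff,
                             effect_size = 1.5, seed = 6)
  a1 <- t(sapply(ts$group1, alff_map, tr = ts$tr))
  a2 <- t(sapply(ts$group2, alff_map, tr = ts$tr))
  diffs <- colMeans(a2) - colMeans(a1)
  expect_setequal(names(sort(diffs, decreasing = TRUE))[1:4], eff)
})

test_that("time-series generation is byte-identical under a fixed seed and validates inputs", {
  p <- gen_parcellation(12, seed = 7)
  t1 <- gen_group_timeseries(p, 3, 64, seed = 8)
  t2 <- gen_group_timeseries(p, 3, 64, seed = 8)
  expect_identical(t1$group1, t2$group1)
  expect_identical(t1$group2, t2$group2)
  expect_error(gen_group_timeseries(p, 3, 32, seed = 1), "n_timepoints")
  expect_error(gen_group_timeseries(p, 3, 64, effect_parcels = "nope"),
               "absent")
})

test_that("linked genes hit the target Spearman correlation on average", {
  p <- gen_parcellation(100, seed = 9)
  map <- make_smooth_map(p, seed = 10)
  ex <- gen_expression_matrix(p, 60, map, n_linked = 40, rho_target = 0.6,
                              seed = 11)
  rho <- vapply(1:40, function(g) {
    oracle_spearman(ex$expr[g, ], map)
  }, numeric(1))
  expect_lt(abs(mean(rho) - 0.6), 0.1)
  expect_true(all(ex$expr >= 0))
  # exact monotone limit
  ex1 <- gen_expression_matrix(p, 5, map, n_linked = 5, rho_target = 1,
                               noise_sd = 0, seed = 12)
  expect_equal(oracle_spearman(ex1$expr[1, ], map), 1)
  expect_error(gen_expression_matrix(p, 10, map, rho_target = 1.5),
               "rho_target")
  expect_identical(gen_expression_matrix(p, 10, map, seed = 1)$expr,
                   gen_expression_matrix(p, 10, map, seed = 1)$expr)
})

test_that("cell counts are non-negative integers with planted structure and markers", {
  cc <- gen_cell_counts(120, c("rA", "rB"), c("astro", "neuron"),
                        cells_per_group = 20, program_rank = 3, seed = 13)
  expect_true(all(cc$counts >= 0))
  expect_true(all(cc$counts == round(cc$counts)))
  gt <- cc$ground_truth
  expect_true(all(gt$program_gene_set %in% rownames(cc$counts)))
  expect_length(gt$region_markers, 2)
  # planted program cells express program genes more than other cells
  prog_cells <- cc$cells$region == gt$program_region &
    cc$cells$cell_type == gt$program_cell_type
  pg_mean_in <- mean(cc$counts[gt$program_gene_set, prog_cells])
  pg_mean_out <- mean(cc$counts[gt$program_gene_set, !prog_cells])
  expect_gt(pg_mean_in, 2 * pg_mean_out)
  expect_error(gen_cell_counts(50, character(), "a"), "non-empty")
  expect_error(gen_cell_counts(50, "rA", "a", program_cell_type = "zz"),
               "program_cell_type")
})

test_that("null program strength removes the cell-type activity signal", {
  pvals <- vapply(1:10, function(r) {
    cc <- gen_cell_counts(100, "rA", c("astro", "neuron", "oligo"),
                          cells_per_group = 30, program_rank = 3,
                          program_strength = 0, markers_per_region = 0,
                          background = "shared", seed = 100 + r)
    f <- fit_nmf(prepare_nmf_input(cc$counts), 3, seed = 200 + r)
    gt <- cc$ground_truth
    # score the factor carrying most of the (absent) program's gene mass
    w_mass <- colSums(f$w[gt$program_gene_set, ]) / colSums(f$w)
    sc <- score_cells(f, cc$cells$cell_type, which.max(w_mass))
    sc$comparison$p[sc$comparison$cell_type == gt$program_cell_type]
  }, numeric(1))
  expect_gte(mean(pvals > 0.05), 0.8)
})

test_that("mediation cohort follows the declared structural equations", {
  d0 <- gen_mediation_cohort(1000, a = 0, b = 0.8, c_prime = 0.2, seed = 14)
  expect_lt(abs(cor(d0$BMD, d0$ALFF)), 0.1)
  dn <- gen_mediation_cohort(50, a = 0.5, b = 0.8, c_prime = 0.2,
                             noise_sds = c(0, 0), seed = 15)
  expect_equal(dn$MoCA, 0.2 * dn$BMD + 0.8 * dn$ALFF, tolerance = 1e-12)
  expect_equal(dn$ALFF, 0.5 * dn$BMD, tolerance = 1e-12)
  expect_identical(gen_mediation_cohort(20, 1, 1, 0, seed = 16),
                   gen_mediation_cohort(20, 1, 1, 0, seed = 16))
  expect_error(gen_mediation_cohort(20, NA, 1, 0), "finite")
  expect_error(gen_mediation_cohort(5, 1, 1, 0), "n")
})

test_that("ground truth round-trips through JSON unchanged", {
  cc <- gen_cell_counts(40, "rA", c("a", "b"), cells_per_group = 5,
                        program_rank = 2, program_size = 10, seed = 17)
  path <- tempfile(fileext = ".json")
  write_ground_truth(cc$ground_truth, path)
  back <- read_ground_truth(path)
  expect_equal(unclass(back), unclass(cc$ground_truth))
})
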