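test_that("spatial Spearman handles monotone transforms, reversals, ties", {
  p <- gen_parcellation(10, seed = 1)
  map <- make_smooth_map(p, seed = 2)
  expr <- rbind(g1 = exp(map), g2 = -map, g3 = rep(1, 10))
  colnames(expr) <- names(map)
  rho <- spatial_spearman(map, expr)
  expect_equal(unname(rho["g1"]), 1)
  expect_equal(unname(rho["g2"]), -1)
  expect_true(is.na(rho["g3"]))
  expect_equal(attr(rho, "reason")[3], "constant_gene")
  # tied values against the counted-rank oracle
  set.seed(3)
  tied <- rbind(g1 = sample(c(1, 1, 2, 2, 3, 3, 4, 5, 6, 6)))
  colnames(tied) <- names(map)
  expect_equal(unname(spatial_spearman(map, tied)["g1"]),
               oracle_spearman(map, tied[1, ]), tolerance = 1e-12)
  expect_error(spatial_spearman(map[1:5], expr[, 1:5]), "8 parcels")
  expect_error(spatial_spearman(map, expr[, 10:1]), "identical ordered")
})

test_that("surrogates preserve the value multiset and are seed-deterministic", {
  p <- gen_parcellation(60, seed = 4)
  d <- parcel_dist(p)
  map <- make_smooth_map(p, seed = 5)
  ens <- build_surrogates(map, d, n = 100, seed = 6)
  expect_equal(ens$method, "variogram_matched")
  for (j in c(1, 50, 100)) {
    expect_equal(sort(unname(ens$surrogates[, j])), sort(unname(map)))
  }
  ens2 <- build_surrogates(map, d, n = 100, seed = 6)
  expect_identical(ens$surrogates, ens2$surrogates)
  ensp <- build_surrogates(map, d, n = 100, method = "value_permutation",
                           seed = 7)
  expect_equal(sort(unname(ensp$surrogates[, 1])), sort(unname(map)))
  expect_error(build_surrogates(map, d * 0, n = 100, seed = 1), "degenerate")
  expect_warning(build_surrogates(map, d, n = 50, seed = 1), "fewer than 100")
})

test_that("the target map's own variogram reproduces itself exactly", {
  p <- gen_parcellation(40, seed = 8)
  d <- parcel_dist(p)
  map <- make_smooth_map(p, seed = 9)
  vg <- empirical_variogram(map, d)
  vg2 <- empirical_variogram(map, d, breaks = attr(vg, "breaks"))
  expect_equal(vg$gamma, vg2$gamma, tolerance = 1e-12)
})

test_that("ensemble-mean variogram of surrogates tracks the target", {
  p <- gen_parcellation(100, seed = 10)
  d <- parcel_dist(p)
  map <- make_smooth_map(p, length_scale = 10, seed = 11)
  ens <- build_surrogates(map, d, n = 200, seed = 12)
  vg0 <- ens$target_variogram
  br <- attr(vg0, "breaks")
  gam <- sapply(seq_len(200), function(j) {
    empirical_variogram(ens$surrogates[, j], d, breaks = br)$gamma
  })
  rel <- abs(rowMeans(gam) - vg0$gamma) / vg0$gamma
  expect_gte(mean(rel <= 0.15), 0.8)
})

test_that("variogram-matched and permutation nulls coincide for white-noise maps", {
  p <- gen_parcellation(80, seed = 13)
  d <- parcel_dist(p)
  set.seed(14)
  map <- rnorm(80)
  names(map) <- p$parcel_id
  gene <- matrix(rnorm(80), 1, dimnames = list("g1", p$parcel_id))
  e1 <- build_surrogates(map, d, n = 1000, seed = 15)
  e2 <- build_surrogates(map, d, n = 1000, method = "value_permutation",
                         seed = 16)
  r1 <- suppressWarnings(cor(apply(e1$surrogates, 2, rank),
                             rank(gene[1, ])))
  r2 <- suppressWarnings(cor(apply(e2$surrogates, 2, rank),
                             rank(gene[1, ])))
  ks <- suppressWarnings(stats::ks.test(r1, r2)$statistic)
  expect_lt(unname(ks), 0.05)
})

test_that("empirical p has the add-one floor and decreases in |rho|", {
  p <- gen_parcellation(30, seed = 17)
  d <- parcel_dist(p)
  map <- make_smooth_map(p, seed = 18)
  expr <- rbind(g_top = exp(map), g_mid = map + rnorm(30, sd = 2))
  colnames(expr) <- names(map)
  rho <- spatial_spearman(map, expr)
  ens <- build_surrogates(map, d, n = 200, seed = 19)
  pp <- empirical_p(rho, ens, expr)
  expect_equal(unname(pp["g_top"]), 1 / 201)
  expect_gte(min(pp), 1 / 201)
  expect_lte(unname(pp["g_top"]), unname(pp["g_mid"]))
  expect_error(empirical_p(c(zz = 0.5), ens, expr), "missing")
})

test_that("empirical p agrees with exhaustive permutation on 6 parcels", {
  # tiny map: all 720 orderings enumerable
  p <- gen_parcellation(10, seed = 20)[1:6, ]
  d <- parcel_dist(p)
  map <- c(p001 = 0.3, p002 = -1.2, p003 = 0.8, p004 = 2.1, p005 = -0.4,
           p006 = 1.0)
  gene <- matrix(c(0.5, -0.9, 1.1, 1.8, -0.2, 0.4), 1,
                 dimnames = list("g1", names(map)))
  rho_obs <- oracle_spearman(map, gene[1, ])
  perms <- matrix(unlist(combinat_perms(6)), ncol = 6, byrow = TRUE)
  rho_all <- apply(perms, 1, function(ix) oracle_spearman(map[ix], gene[1, ]))
  p_exact <- mean(abs(rho_all) >= abs(rho_obs) - 1e-12)
  ens <- suppressWarnings(build_surrogates(
    map, d, n = 2000, method = "value_permutation", seed = 21))
  rho_v <- c(g1 = rho_obs)
  pp <- empirical_p(rho_v, ens, gene)
  expect_lt(abs(unname(pp["g1"]) - p_exact), 0.03)
})

test_that("dual threshold applies both arms with the genome-wide cutoff", {
  expect_equal(signif(bonferroni_cutoff(10185), 3), 4.91e-6)
  tab <- data.frame(
    gene = c("a", "b", "c"),
    rho = c(0.95, 0.40, -0.9),
    p_perm = c(0.001, 0.04, 0.2)
  )
  out <- dual_threshold(tab, n_parcels = 100, n_genes = 10185)
  # b: passes the empirical arm but its parametric p (~1e-4) fails Bonferroni
  expect_true(out$p_param[2] < 1e-3 && !out$p_bonf_pass[2])
  expect_false(out$significant[2])
  # a: passes both arms
  expect_true(out$significant[1])
  # c: fails the empirical arm despite a strong parametric p
  expect_false(out$significant[3])
  expect_equal(attr(out, "bonferroni_cut"), 0.05 / 10185)
  # all genes passing both arms -> all significant
  tab2 <- data.frame(gene = c("x", "y"), rho = c(0.99, -0.99),
                     p_perm = c(0.001, 0.001))
  out2 <- dual_threshold(tab2, n_parcels = 100, n_genes = 2)
  expect_true(all(out2$significant))
  expect_error(dual_threshold(tab[0, ], n_parcels = 100, n_genes = 0),
               "n_genes")
})

test_that("gene-set intersection is exact and order-stable", {
  expect_identical(intersect_gene_sets(c("A", "B"), c("C", "D")), character(0))
  expect_identical(intersect_gene_sets(c("B", "A"), c("A", "B")), c("A", "B"))
  expect_identical(intersect_gene_sets(c("A", "B", "C"), c("B", "C", "D")),
                   c("B", "C"))
})

test_that("variogram-matched nulls reject smooth unlinked genes less than naive permutation", {
  p <- gen_parcellation(100, seed = 22)
  d <- parcel_dist(p)
  map <- make_smooth_map(p, length_scale = 10, seed = 23)
  ex <- gen_expression_matrix(p, 150, map, n_linked = 0, seed = 24)
  rho <- spatial_spearman(map, ex$expr)
  e_vm <- build_surrogates(map, d, n = 500, seed = 25)
  e_pm <- build_surrogates(map, d, n = 500, method = "value_permutation",
                           seed = 26)
  rej_vm <- mean(empirical_p(rho, e_vm, ex$expr) < 0.05)
  rej_pm <- mean(empirical_p(rho, e_pm, ex$expr) < 0.05)
  expect_lt(rej_vm, rej_pm)
})
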