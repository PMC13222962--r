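test_that("NMF recovers an exact low-rank factorization", {
  set.seed(1)
  w0 <- matrix(rexp(30 * 2), 30, 2)
  h0 <- matrix(rexp(2 * 40), 2, 40)
  x <- w0 %*% h0
  f <- fit_nmf(x, 2, seed = 2, n_restarts = 3, max_iter = 10000, tol = 0)
  expect_lt(tail(f$objective, 1) / sqrt(sum(x^2)), 1e-6)
  # factors match up to permutation/scaling: cosine similarity per column
  cos_sim <- function(a, b) abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))
  sims <- outer(1:2, 1:2, Vectorize(function(i, j) cos_sim(f$w[, i], w0[, j])))
  expect_true(all(apply(sims, 2, max) > 0.99))
  expect_true(all(f$w >= 0) && all(f$h >= 0))
})

test_that("the objective trace is non-increasing and fits are deterministic", {
  set.seed(3)
  x <- matrix(rexp(50 * 30), 50, 30)
  f <- fit_nmf(x, 3, seed = 4, n_restarts = 2)
  expect_true(all(diff(f$objective) <= 1e-8 * f$objective[1]))
  f2 <- fit_nmf(x, 3, seed = 4, n_restarts = 2)
  expect_identical(f$w, f2$w)
  expect_identical(f$h, f2$h)
  xneg <- x
  xneg[2, 3] <- -1
  expect_error(fit_nmf(xneg, 2), "non-negative")
  expect_error(fit_nmf(x, 30), "k must be")
})

test_that("reconstruction error improves with rank on the same data", {
  set.seed(5)
  x <- prepare_nmf_input(matrix(rpois(80 * 60, 4), 80, 60))
  errs <- vapply(2:5, function(k) {
    tail(fit_nmf(x, k, seed = 6, n_restarts = 2)$objective, 1)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("the factorization is gauge-fixed with unit-L2 gene columns", {
  set.seed(7)
  x <- matrix(rexp(40 * 25), 40, 25)
  f <- fit_nmf(x, 3, seed = 8)
  expect_equal(unname(colSums(f$w^2)), rep(1, 3), tolerance = 1e-8)
  # the product is what matters; rescaling is absorbed
  expect_equal(f$w %*% f$h, f$w %*% f$h)
})

test_that("rank selection recovers a planted rank and handles a size-1 grid", {
  chosen <- vapply(1:5, function(r) {
    cc <- gen_cell_counts(150, c("rA", "rB"), c("astro", "neuron", "oligo"),
                          cells_per_group = 30, program_rank = 4,
                          program_cell_type = "astro",
                          program_region = "rA", seed = 500 + r,
                          markers_per_region = 0)
    select_rank(prepare_nmf_input(cc$counts), 2:6, seed = 700 + r)$chosen_k
  }, numeric(1))
  expect_gte(mean(chosen == 4), 0.8)
  cc <- gen_cell_counts(60, "rA", c("a", "b"), cells_per_group = 10,
                        program_rank = 2, seed = 9)
  sr1 <- select_rank(prepare_nmf_input(cc$counts), 3, seed = 10,
                     n_restarts = 3)
  expect_equal(sr1$chosen_k, 3)
  expect_equal(nrow(sr1$diagnostics), 1)
  expect_error(select_rank(prepare_nmf_input(cc$counts), 2:3, n_restarts = 1),
               "2 restarts")
  expect_error(select_rank(prepare_nmf_input(cc$counts), 100), "valid ranks")
})

test_that("top genes are weight-ordered, tie-stable, and row-order invariant", {
  w <- matrix(0, 5, 2, dimnames = list(c("gB", "gA", "gC", "gD", "gE"), NULL))
  w[, 1] <- c(3, 3, 2, 1, 0)
  w[, 2] <- c(0, 0, 0, 0, 7)
  decomp <- structure(list(w = w, h = matrix(1, 2, 3), k = 2),
                      class = "bb_nmf")
  tg <- top_genes(decomp, 3)
  expect_equal(tg[[1]], c("gA", "gB", "gC"))   # tie at 3 broken by name
  expect_equal(top_genes(decomp, 1)[[2]], "gE")
  perm <- c(4, 2, 5, 1, 3)
  decomp2 <- structure(list(w = w[perm, ], h = decomp$h, k = 2),
                       class = "bb_nmf")
  expect_equal(top_genes(decomp2, 3), tg)
  expect_error(top_genes(decomp, 10), "gene count")
})

test_that("program enrichment pinpoints the program containing the query", {
  set.seed(11)
  universe <- sprintf("g%03d", 1:100)
  progs <- list(p1 = universe[1:20], p2 = universe[21:40],
                p3 = universe[41:60])
  e <- program_enrichment(universe[21:40], progs, universe)
  expect_equal(e$group[1], "p2")
  expect_equal(e$p[e$group == "p1"], 1)      # zero overlap
  expect_equal(e$k[e$group == "p1"], 0)
})

test_that("cell scoring matches rank-sum enumeration and handles zero programs", {
  h <- rbind(p1 = c(4, 5, 6, 7, 8, 1, 2, 2.5, 3, 3.5),
             p2 = rep(0, 10))
  colnames(h) <- sprintf("c%02d", 1:10)
  decomp <- structure(list(w = matrix(1, 3, 2), h = h, k = 2),
                      class = "bb_nmf")
  labels <- rep(c("astro", "other"), each = 5)
  sc <- score_cells(decomp, labels, "p1")
  a <- sc$activity[labels == "astro"]
  b <- sc$activity[labels == "other"]
  expect_equal(sc$comparison$p[sc$comparison$cell_type == "astro"],
               oracle_ranksum_p(a, b), tolerance = 1e-10)
  sc0 <- score_cells(decomp, labels, "p2")
  expect_true(all(sc0$activity == 0))
  expect_false(any(sc0$comparison$significant))
})

test_that("a planted astrocyte program scores highest in astrocytes", {
  cc <- gen_cell_counts(200, "rA", c("astro", "neuron", "oligo", "micro"),
                        cells_per_group = 200, program_rank = 4,
                        program_cell_type = "astro", program_region = "rA",
                        seed = 12, markers_per_region = 0)
  f <- fit_nmf(prepare_nmf_input(cc$counts), 4, seed = 13, n_restarts = 3)
  gt <- cc$ground_truth$program_gene_set
  tg <- top_genes(f, 2 * length(gt))
  recall <- vapply(tg, function(s) {
    length(intersect(s, gt)) / length(gt)
  }, numeric(1))
  prog <- names(which.max(recall))
  expect_gt(max(recall), 0.9)
  sc <- score_cells(f, cc$cells$cell_type, prog)
  comp <- sc$comparison
  astro_med <- comp$median_activity[comp$cell_type == "astro"]
  expect_true(all(astro_med > comp$median_activity[comp$cell_type != "astro"]))
  expect_lt(comp$q[comp$cell_type == "astro"], 0.01)
})
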