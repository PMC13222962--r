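#' Prepare a non-negative NMF input matrix from counts
#'
#' Library-normalizes to counts-per-10,000 and applies log1p. With
#' `zscore_clip = TRUE`, genes are additionally scaled to unit variance and
#' negative values clipped at zero (a "standardized" variant that preserves
#' non-negativity).
#'
#' @param counts genes x cells count matrix.
#' @param zscore_clip logical; apply per-gene z-scoring with clipping.
#' @return non-negative genes x cells matrix.
#' @export
prepare_nmf_input <- function(counts, zscore_clip = FALSE) {
  x <- normalize_counts(counts)
  if (zscore_clip) {
    mu <- rowMeans(x)
    sdv <- apply(x, 1, sd)
    sdv[sdv == 0] <- 1
    x <- pmax((x - mu) / sdv, 0)
  }
  x
}

#' Non-negative matrix factorization by multiplicative updates
#'
#' Minimizes the Frobenius reconstruction error `||X - WH||_F` with
#' Lee-Seung multiplicative updates, best of `n_restarts` random
#' initializations. The gauge is fixed by scaling the columns of `W` to unit
#' L2 norm (with the inverse scale absorbed into `H`).
#'
#' @param x non-negative genes x cells matrix.
#' @param k factorization rank (`< min(dim(x))`).
#' @param seed integer seed; with `n_restarts > 1`, restart r uses a seed
#'   derived from `seed` and `r`.
#' @param n_restarts random restarts; the fit with the lowest final error is
#'   returned.
#' @param max_iter maximum update iterations per restart.
#' @param tol relative objective-change convergence tolerance.
#' @return list of class `bb_nmf`: `w` (genes x k), `h` (k x cells), `k`,
#'   `objective` (per-iteration error trace of the winning restart), `seed`,
#'   `restarts`.
#' @export
fit_nmf <- function(x, k, seed = 1L, n_restarts = 1L, max_iter = 500L,
                    tol = 1e-5) {
  x <- as.matrix(x)
  if (any(x < 0)) {
    bad <- which(x < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative entry at [%d, %d]: NMF input must be non-negative",
                 bad[1], bad[2]), call. = FALSE)
  }
  if (k >= min(dim(x))) stop("k must be < min(dim(x))", call. = FALSE)
  eps <- 1e-10
  run_one <- function(s) {
    set.seed(s)
    scale0 <- sqrt(mean(x) / k)
    w <- matrix(runif(nrow(x) * k, 0, 2 * scale0), nrow(x), k)
    h <- matrix(runif(k * ncol(x), 0, 2 * scale0), k, ncol(x))
    obj <- numeric(0)
    prev <- Inf
    for (it in seq_len(max_iter)) {
      h <- h * (crossprod(w, x) / (crossprod(w, w) %*% h + eps))
      w <- w * (tcrossprod(x, h) / (w %*% tcrossprod(h, h) + eps))
      err <- sqrt(sum((x - w %*% h)^2))
      obj <- c(obj, err)
      if (is.finite(prev) && prev - err < tol * max(prev, eps)) break
      prev <- err
    }
    list(w = w, h = h, objective = obj)
  }
  fits <- lapply(seq_len(n_restarts), function(r) {
    run_one(child_seed(seed, r))
  })
  final_err <- vapply(fits, function(f) tail(f$objective, 1), numeric(1))
  best <- fits[[which.min(final_err)]]
  # unit-L2 gauge on W columns
  nrm <- sqrt(colSums(best$w^2))
  nrm[nrm == 0] <- 1
  w <- sweep(best$w, 2, nrm, "/")
  h <- sweep(best$h, 1, nrm, "*")
  dimnames(w) <- list(rownames(x), sprintf("program_%d", seq_len(k)))
  dimnames(h) <- list(sprintf("program_%d", seq_len(k)), colnames(x))
  structure(list(w = w, h = h, k = k, objective = best$objective,
                 seed = as.integer(seed), restarts = n_restarts),
            class = "bb_nmf")
}

# dominant-program assignment per cell (ties to the first program)
.dominant_program <- function(h) apply(h, 2, which.max)

#' Rank selection by consensus cophenetic correlation and silhouette
#'
#' For each candidate rank, `n_restarts` factorizations are fitted, each on
#' a random subsample of the genes (`subsample_frac`), and cells are
#' clustered by their dominant program. The consensus matrix (fraction of
#' restarts co-clustering each cell pair) yields (i) the cophenetic
#' correlation between consensus distances and their average-linkage
#' hierarchical cophenetic distances, and (ii) the mean silhouette of the
#' k-cluster consensus partition under consensus distances. Both are near 1
#' only at the true rank: below it, which blocks merge depends on the gene
#' subsample; above it, the surplus split does. The chosen rank maximizes
#' the mean of the two stability scores (ties favor the smaller rank).
#'
#' @param x non-negative matrix.
#' @param k_grid candidate ranks.
#' @param seed integer seed.
#' @param n_restarts restarts per rank (>= 2; the consensus is undefined for
#'   a single restart).
#' @param subsample_frac fraction of genes drawn per restart.
#' @param max_iter,tol passed to [fit_nmf()].
#' @return list with `diagnostics` (data.frame: k, cophenetic, silhouette,
#'   stability) and `chosen_k`.
#' @export
select_rank <- function(x, k_grid, seed = 1L, n_restarts = 8L,
                        subsample_frac = 0.7, max_iter = 300L, tol = 1e-5) {
  if (any(k_grid >= min(dim(x)) | k_grid < 1)) {
    stop("k_grid outside valid ranks", call. = FALSE)
  }
  if (n_restarts < 2) {
    stop("consensus diagnostics require at least 2 restarts", call. = FALSE)
  }
  n_cells <- ncol(x)
  n_sub <- max(2L, round(subsample_frac * nrow(x)))
  diag_rows <- lapply(seq_along(k_grid), function(ki) {
    k <- k_grid[ki]
    assigns <- matrix(0L, n_restarts, n_cells)
    for (r in seq_len(n_restarts)) {
      set.seed(child_seed(seed, ki * 10000L + 2L * r))
      gi <- sample.int(nrow(x), n_sub)
      f <- fit_nmf(x[gi, , drop = FALSE], k,
                   seed = child_seed(seed, ki * 10000L + 2L * r + 1L),
                   n_restarts = 1L, max_iter = max_iter, tol = tol)
      assigns[r, ] <- .dominant_program(f$h)
    }
    consensus <- matrix(0, n_cells, n_cells)
    for (r in seq_len(n_restarts)) {
      consensus <- consensus + outer(assigns[r, ], assigns[r, ], "==")
    }
    consensus <- consensus / n_restarts
    dcons <- as.dist(1 - consensus)
    if (stats::sd(dcons) == 0) {
      coph <- 1
      part <- rep(1L, n_cells)
    } else {
      hc <- hclust(dcons, method = "average")
      coph <- suppressWarnings(cor(dcons, cophenetic(hc)))
      part <- stats::cutree(hc, k = k)
    }
    sil <- if (length(unique(part)) < 2) 1 else {
      mean(cluster::silhouette(part, dmatrix = 1 - consensus)[, 3])
    }
    data.frame(k = k, cophenetic = coph, silhouette = sil,
               stability = (coph + sil) / 2)
  })
  diagnostics <- do.call(rbind, diag_rows)
  chosen <- diagnostics$k[which.max(diagnostics$stability)]
  list(diagnostics = diagnostics, chosen_k = chosen)
}

#' Top-weight genes per program
#'
#' @param decomp `bb_nmf` object.
#' @param n genes per program (default 200); ties in weight are broken
#'   lexicographically by gene id for determinism.
#' @return named list of character vectors, one per program, ordered by
#'   descending weight.
#' @export
top_genes <- function(decomp, n = 200) {
  w <- decomp$w
  if (n > nrow(w)) stop("n exceeds the gene count", call. = FALSE)
  genes <- rownames(w) %||% as.character(seq_len(nrow(w)))
  out <- lapply(seq_len(ncol(w)), function(j) {
    genes[order(-w[, j], genes)][seq_len(n)]
  })
  names(out) <- colnames(w)
  out
}

#' Hypergeometric enrichment of a query set in program top-gene sets
#' @param query character gene set.
#' @param programs named list of per-program top-gene sets (see
#'   [top_genes()]).
#' @param universe gene universe.
#' @inheritParams hypergeom_enrich
#' @return data.frame as returned by [hypergeom_enrich()].
#' @export
program_enrichment <- function(query, programs, universe, fdr_q = 0.05) {
  hypergeom_enrich(query, programs, universe, fdr_q = fdr_q)
}

#' Per-cell program activity and cell-type comparison
#'
#' The activity of a program in a cell is its H entry divided by the cell's
#' total activity over all programs (relative activity). Each cell type is
#' compared against all other cells by a two-sided Wilcoxon rank-sum test,
#' with Benjamini-Hochberg correction across cell types; types with fewer
#' than 3 cells are excluded with a warning.
#'
#' @param decomp `bb_nmf` object.
#' @param cell_labels character vector of cell types aligned to cells.
#' @param program program index or name.
#' @return list with `activity` (named per-cell) and `comparison`
#'   (data.frame: cell_type, n, median_activity, p, q, significant).
#' @export
score_cells <- function(decomp, cell_labels, program) {
  h <- decomp$h
  if (length(cell_labels) != ncol(h)) {
    stop("cell_labels must align to cells", call. = FALSE)
  }
  tot <- colSums(h)
  tot[tot == 0] <- 1
  activity <- h[program, ] / tot
  names(activity) <- colnames(h)
  tab <- table(cell_labels)
  keep <- names(tab)[tab >= 3]
  if (length(keep) < length(tab)) {
    warning("excluding cell types with < 3 cells: ",
            paste(setdiff(names(tab), keep), collapse = ", "))
  }
  rows <- lapply(sort(keep), function(ct) {
    ing <- cell_labels == ct
    a1 <- activity[ing]
    a0 <- activity[!ing]
    p <- if (length(unique(c(a1, a0))) == 1) 1 else {
      suppressWarnings(wilcox.test(a1, a0)$p.value)
    }
    data.frame(cell_type = ct, n = sum(ing),
               median_activity = stats::median(a1), p = p,
               stringsAsFactors = FALSE)
  })
  comparison <- do.call(rbind, rows)
  comparison$q <- p.adjust(comparison$p, method = "BH")
  comparison$significant <- comparison$q < 0.05
  list(activity = activity, comparison = comparison)
}
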