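#' Spearman correlation of a contrast map with per-gene expression profiles
#'
#' @param map named numeric vector, one value per parcel.
#' @param expr genes x parcels matrix; column names must equal `names(map)`
#'   in the same order.
#' @return named numeric vector of Spearman rho per gene; genes with a
#'   constant profile (or a constant map) are `NA` with a `reason`
#'   attribute.
#' @export
spatial_spearman <- function(map, expr) {
  if (!identical(colnames(expr), names(map))) {
    stop("map and expression matrix must share an identical ordered parcel set",
         call. = FALSE)
  }
  p <- length(map)
  if (p < 8) stop("need at least 8 parcels", call. = FALSE)
  if (length(unique(map)) == 1) {
    rho <- rep(NA_real_, nrow(expr))
    names(rho) <- rownames(expr)
    attr(rho, "reason") <- rep("constant_map", nrow(expr))
    return(rho)
  }
  rmap <- rank(map, ties.method = "average")
  rexpr <- t(apply(expr, 1, rank, ties.method = "average"))
  const <- apply(expr, 1, function(v) length(unique(v)) == 1)
  rho <- suppressWarnings(drop(cor(rmap, t(rexpr))))
  rho[const] <- NA_real_
  names(rho) <- rownames(expr)
  reason <- rep(NA_character_, length(rho))
  reason[const] <- "constant_gene"
  attr(rho, "reason") <- reason
  rho
}

#' Binned empirical variogram of a parcellated map
#'
#' Half mean squared difference of values at parcel pairs, binned by
#' distance (equal-count bins unless `breaks` are supplied).
#'
#' @param values numeric vector over parcels.
#' @param distances symmetric distance matrix with zero diagonal.
#' @param n_bins number of distance bins.
#' @param breaks optional fixed bin breaks (for comparing maps on a common
#'   binning).
#' @return data.frame with bin midpoint `h` and semivariance `gamma`;
#'   attribute `breaks`.
#' @export
empirical_variogram <- function(values, distances, n_bins = 10,
                                breaks = NULL) {
  ut <- upper.tri(distances)
  d <- distances[ut]
  g <- 0.5 * (outer(values, values, "-")^2)[ut]
  if (is.null(breaks)) {
    breaks <- unique(quantile(d, probs = seq(0, 1, length.out = n_bins + 1)))
  }
  bin <- cut(d, breaks = breaks, include.lowest = TRUE)
  out <- data.frame(
    h = as.numeric(tapply(d, bin, mean)),
    gamma = as.numeric(tapply(g, bin, mean))
  )
  out <- out[is.finite(out$h), ]
  attr(out, "breaks") <- breaks
  out
}

# Fit gamma(h) = c0 + c1 (1 - exp(-h^2 / (2 L^2))) by grid search over L
# with non-negative linear coefficients.
.fit_variogram_model <- function(vg, distances) {
  h <- vg$h
  g <- vg$gamma
  l_grid <- exp(seq(log(max(min(distances[distances > 0]), 1e-6)),
                    log(max(distances)), length.out = 40))
  best <- NULL
  for (L in l_grid) {
    basis <- 1 - exp(-h^2 / (2 * L^2))
    fit <- tryCatch(stats::lm.fit(cbind(1, basis), g), error = function(e) NULL)
    if (is.null(fit)) next
    cf <- fit$coefficients
    c0 <- max(cf[1], 0)
    c1 <- max(cf[2], 0)
    if (cf[1] < 0 || cf[2] < 0) {
      # refit the other coefficient with the offending one clamped at zero
      if (cf[2] < 0) {
        c1 <- 0; c0 <- max(mean(g), 0)
      } else {
        c1 <- max(sum(basis * g) / sum(basis^2), 0); c0 <- 0
      }
    }
    sse <- sum((g - c0 - c1 * basis)^2)
    if (is.null(best) || sse < best$sse) {
      best <- list(c0 = c0, c1 = c1, length_scale = L, sse = sse)
    }
  }
  if (is.null(best) || best$c1 <= 0) {
    # no resolvable spatial structure; fall back to a white covariance
    best <- list(c0 = max(var(g) , 1e-12), c1 = 1e-12,
                 length_scale = max(distances), sse = NA_real_)
  }
  best
}

#' Build spatial-autocorrelation-preserving surrogate maps
#'
#' `variogram_matched` surrogates are Gaussian random fields whose covariance
#' is fitted to the map's binned empirical variogram (Gaussian-kernel model
#' with nugget), rank-remapped onto the original value multiset — so every
#' surrogate preserves both the values and (approximately) the spatial
#' autocorrelation. `value_permutation` surrogates are plain random
#' permutations (no autocorrelation preserved; flagged in metadata).
#'
#' @param map named numeric vector over parcels.
#' @param distances parcel distance matrix (symmetric, zero diagonal).
#' @param n number of surrogates.
#' @param method `"variogram_matched"` or `"value_permutation"`.
#' @param seed integer seed.
#' @param n_bins variogram bins.
#' @return object of class `bb_surrogates` with a parcels x n `surrogates`
#'   matrix, the target variogram, fitted model, method and seed.
#' @export
build_surrogates <- function(map, distances,
                             n = 1000,
                             method = c("variogram_matched",
                                        "value_permutation"),
                             seed = 1L, n_bins = 10) {
  method <- match.arg(method)
  p <- length(map)
  if (!isTRUE(all.equal(distances, t(distances))) ||
      any(diag(distances) != 0)) {
    stop("distance matrix must be symmetric with zero diagonal", call. = FALSE)
  }
  if (all(distances[upper.tri(distances)] == 0)) {
    stop("degenerate distance matrix", call. = FALSE)
  }
  if (n < 100) warning("fewer than 100 surrogates: empirical p floor is coarse")
  set.seed(as.integer(seed))
  sorted_vals <- sort(map)
  vg <- empirical_variogram(map, distances, n_bins = n_bins)
  model <- NULL
  if (method == "variogram_matched") {
    model <- .fit_variogram_model(vg, distances)
    C <- model$c1 * exp(-distances^2 / (2 * model$length_scale^2))
    diag(C) <- model$c0 + model$c1
    Lc <- kernel_chol(C / max(diag(C)), jitter = 1e-6)
    fields <- smooth_fields(Lc, n)
    surr <- apply(fields, 2, function(f) sorted_vals[rank(f, ties.method = "first")])
  } else {
    surr <- vapply(seq_len(n), function(i) map[sample.int(p)], numeric(p))
  }
  rownames(surr) <- names(map)
  structure(list(
    surrogates = surr, n = n, method = method, seed = as.integer(seed),
    target_variogram = vg, model = model
  ), class = "bb_surrogates")
}

#' Variogram agreement of surrogates with their target map
#'
#' For each surrogate, the fraction of variogram bins (computed on the
#' target's binning) whose semivariance is within `tol` relative error of
#' the target's.
#'
#' @param ensemble a `bb_surrogates` object.
#' @param distances the distance matrix used to build it.
#' @param tol relative tolerance per bin.
#' @return numeric vector, one fraction per surrogate.
#' @export
variogram_match <- function(ensemble, distances, tol = 0.15) {
  vg0 <- ensemble$target_variogram
  breaks <- attr(vg0, "breaks")
  apply(ensemble$surrogates, 2, function(s) {
    vg <- empirical_variogram(s, distances, breaks = breaks)
    rel <- abs(vg$gamma - vg0$gamma) / vg0$gamma
    mean(rel <= tol)
  })
}

#' Empirical two-sided permutation p-values for map-gene correlations
#'
#' `p = (1 + #\{|rho_surr| >= |rho_obs|\}) / (n_surrogates + 1)` per gene,
#' where surrogate correlations are Spearman correlations of each surrogate
#' map with the gene's profile.
#'
#' @param rho_obs named vector of observed Spearman rho per gene.
#' @param ensemble `bb_surrogates` built from the same map.
#' @param expr genes x parcels expression matrix (same parcel order).
#' @return named numeric vector of empirical p per gene (`NA` where
#'   `rho_obs` is `NA`).
#' @export
empirical_p <- function(rho_obs, ensemble, expr) {
  if (!all(names(rho_obs) %in% rownames(expr))) {
    stop("genes in rho_obs missing from expression matrix", call. = FALSE)
  }
  expr <- expr[names(rho_obs), , drop = FALSE]
  rexpr <- apply(expr, 1, rank, ties.method = "average")   # parcels x genes
  rsurr <- apply(ensemble$surrogates, 2, rank, ties.method = "average")
  rho_surr <- suppressWarnings(cor(rsurr, rexpr))          # n_surr x genes
  n <- ensemble$n
  p <- vapply(seq_along(rho_obs), function(g) {
    if (is.na(rho_obs[g])) return(NA_real_)
    (1 + sum(abs(rho_surr[, g]) >= abs(rho_obs[g]))) / (n + 1)
  }, numeric(1))
  names(p) <- names(rho_obs)
  p
}

#' Genome-wide Bonferroni cutoff
#' @param n_genes number of genes tested.
#' @param alpha_fwe family-wise alpha.
#' @return `alpha_fwe / n_genes`.
#' @export
bonferroni_cutoff <- function(n_genes, alpha_fwe = 0.05) {
  if (n_genes <= 0) stop("n_genes must be positive", call. = FALSE)
  alpha_fwe / n_genes
}

#' Dual-threshold significance call for map-gene associations
#'
#' A gene is significant when its surrogate-null empirical p is below
#' `p_perm_alpha` and its parametric Spearman p (t approximation) clears the
#' genome-wide Bonferroni cutoff `alpha_fwe / n_genes`.
#'
#' @param table data.frame with columns `gene`, `rho`, `p_perm`.
#' @param n_parcels number of parcels the correlations were computed over.
#' @param n_genes number of genes in the Bonferroni family (defaults to
#'   `nrow(table)`).
#' @param alpha_fwe family-wise alpha for the Bonferroni arm.
#' @param p_perm_alpha threshold for the empirical-p arm.
#' @return the table with added columns `p_param`, `p_bonf_pass`,
#'   `significant`; attribute `bonferroni_cut`.
#' @export
dual_threshold <- function(table, n_parcels, n_genes = nrow(table),
                           alpha_fwe = 0.05, p_perm_alpha = 0.05) {
  if (n_genes == 0) stop("n_genes must be positive", call. = FALSE)
  rho <- table$rho
  tstat <- rho * sqrt((n_parcels - 2) / pmax(1 - rho^2, 1e-300))
  p_param <- 2 * pt(-abs(tstat), df = n_parcels - 2)
  cut <- bonferroni_cutoff(n_genes, alpha_fwe)
  table$p_param <- p_param
  table$p_bonf_pass <- !is.na(p_param) & p_param <= cut
  table$significant <- !is.na(table$p_perm) & table$p_perm < p_perm_alpha &
    table$p_bonf_pass
  attr(table, "bonferroni_cut") <- cut
  table
}

#' Intersection of two significant gene sets
#' @param set_alff,set_reho character vectors of gene ids.
#' @return lexicographically sorted intersection.
#' @export
intersect_gene_sets <- function(set_alff, set_reho) {
  sort(intersect(set_alff, set_reho))
}

#' End-to-end map-gene association with surrogate nulls and dual threshold
#'
#' @param map named contrast map over parcels.
#' @param expr genes x parcels expression matrix.
#' @param distances parcel distance matrix.
#' @param n_surr number of surrogate maps.
#' @param method surrogate method (see [build_surrogates()]).
#' @param seed integer seed.
#' @param alpha_fwe Bonferroni family-wise alpha.
#' @return association data.frame (gene, rho, p_perm, p_param, p_bonf_pass,
#'   significant) with attributes `bonferroni_cut` and `surrogate_method`.
#' @export
gene_association <- function(map, expr, distances, n_surr = 1000,
                             method = "variogram_matched", seed = 1L,
                             alpha_fwe = 0.05) {
  rho <- spatial_spearman(map, expr)
  ens <- build_surrogates(map, distances, n = n_surr, method = method,
                          seed = seed)
  pp <- empirical_p(rho, ens, expr)
  tab <- data.frame(gene = names(rho), rho = as.numeric(rho),
                    p_perm = as.numeric(pp), stringsAsFactors = FALSE)
  tab <- dual_threshold(tab, n_parcels = length(map))
  attr(tab, "surrogate_method") <- method
  tab
}
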