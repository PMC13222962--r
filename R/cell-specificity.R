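#' Library-size normalization: counts per 10,000 then log1p
#' @param counts genes x cells non-negative count matrix.
#' @param scale_factor counts-per-cell target (default 1e4).
#' @return normalized matrix of the same shape.
#' @export
normalize_counts <- function(counts, scale_factor = 1e4) {
  lib <- colSums(counts)
  if (any(lib <= 0)) stop("cells with zero library size", call. = FALSE)
  log1p(sweep(counts, 2, lib / scale_factor, "/"))
}

#' Component specificity metrics per gene per group
#'
#' From library-normalized expression and group labels (regions or cell
#' types), computes three per-gene, per-group metrics: `det`, the Welch
#' t-statistic of the group versus all other groups; `ep`, the expression
#' proportion (group mean divided by the sum of group means); and `ges`, the
#' fold enrichment of the group mean over the rest mean. Groups with fewer
#' than 3 observations are excluded with a warning.
#'
#' @param counts genes x cells count matrix.
#' @param group_labels character vector, one label per cell.
#' @return list of class `bb_metrics` with matrices `det`, `ges`, `ep`
#'   (genes x groups), `group_means`, and `groups`.
#' @export
compute_metrics <- function(counts, group_labels) {
  if (ncol(counts) != length(group_labels)) {
    stop("group_labels must align to columns of counts", call. = FALSE)
  }
  tab <- table(group_labels)
  keep <- names(tab)[tab >= 3]
  if (length(keep) < length(tab)) {
    warning("excluding groups with < 3 observations: ",
            paste(setdiff(names(tab), keep), collapse = ", "))
  }
  if (length(keep) < 2) stop("need at least 2 groups", call. = FALSE)
  sel <- group_labels %in% keep
  counts <- counts[, sel, drop = FALSE]
  group_labels <- group_labels[sel]
  x <- normalize_counts(counts)

  groups <- sort(keep)
  g_n <- vapply(groups, function(g) sum(group_labels == g), numeric(1))
  g_mean <- vapply(groups, function(g) {
    rowMeans(x[, group_labels == g, drop = FALSE])
  }, numeric(nrow(x)))
  g_var <- vapply(groups, function(g) {
    m <- x[, group_labels == g, drop = FALSE]
    rowSums((m - rowMeans(m))^2) / (ncol(m) - 1)
  }, numeric(nrow(x)))

  n_tot <- ncol(x)
  sum_all <- rowSums(x)
  sumsq_all <- rowSums(x^2)

  det <- ges <- ep <- matrix(
    0, nrow(x), length(groups), dimnames = list(rownames(x), groups))
  mean_sum <- rowSums(g_mean)
  for (j in seq_along(groups)) {
    n1 <- g_n[j]
    n0 <- n_tot - n1
    m1 <- g_mean[, j]
    s1 <- g_var[, j]
    m0 <- (sum_all - n1 * m1) / n0
    ss0 <- sumsq_all - (s1 * (n1 - 1) + n1 * m1^2)
    s0 <- pmax(ss0 - n0 * m0^2, 0) / (n0 - 1)
    se <- sqrt(s1 / n1 + s0 / n0)
    det[, j] <- ifelse(se > 0, (m1 - m0) / se, 0)
    ges[, j] <- (m1 + 1e-9) / (m0 + 1e-9)
    ep[, j] <- ifelse(mean_sum > 0, m1 / mean_sum, 0)
  }
  structure(list(det = det, ges = ges, ep = ep, group_means = g_mean,
                 groups = groups, n_per_group = g_n),
            class = "bb_metrics")
}

# Rank-based min-max rescale of one gene's metric values across groups;
# constant vectors (full ties) collapse to zero specificity.
.rank_minmax <- function(v) {
  r <- rank(v, ties.method = "min")
  rng <- max(r) - min(r)
  if (rng == 0) return(rep(0, length(v)))
  (r - min(r)) / rng
}

#' Combine component metrics into the ESmu specificity score
#'
#' Each metric is rescaled per gene to \[0, 1\] by rank-based min-max over
#' groups, and ESmu is the mean of the rescaled metrics. Three sparsity
#' gates keep noise genes out: a gene's score in a group is zeroed unless
#' (i) its expression proportion there exceeds the uniform share
#' `1 / n_groups`, (ii) its differential-expression statistic clears a
#' one-sided significance gate (`det_gate`, a z-scale cutoff), and (iii) its
#' fold enrichment over the remaining groups exceeds `fc_gate` — so a gene
#' whose between-group differences are within sampling noise carries no
#' specificity anywhere. Genes undetected everywhere get zero in all
#' groups.
#'
#' @param metrics a `bb_metrics` object from [compute_metrics()].
#' @param det_gate minimum Welch t (z scale) for a nonzero score; default
#'   the one-sided 5% normal cutoff.
#' @param fc_gate minimum group-vs-rest fold enrichment for a nonzero
#'   score; a gene within `fc_gate` of flat expression carries no
#'   specificity.
#' @return object of class `bb_specificity` with `es_mu` (genes x groups in
#'   \[0, 1\]) and the rescaled component matrices.
#' @export
combine_esmu <- function(metrics, det_gate = stats::qnorm(0.95),
                         fc_gate = 1.1) {
  ep <- metrics$ep
  m <- ncol(ep)
  if (all(metrics$group_means == 0)) {
    warning("all-zero expression matrix: ESmu is all zero")
  }
  rescale <- function(mat) t(apply(mat, 1, .rank_minmax))
  comp <- lapply(metrics[c("det", "ges", "ep")], rescale)
  es <- Reduce(`+`, comp) / length(comp)
  # specificity only where the gene is expressed above its uniform share and
  # the group-vs-rest contrast is not attributable to sampling noise
  es[ep <= 1 / m | metrics$det < det_gate | metrics$ges < fc_gate] <- 0
  es[rowSums(metrics$group_means) == 0, ] <- 0
  dimnames(es) <- dimnames(ep)
  structure(list(es_mu = es, components = comp, groups = metrics$groups),
            class = "bb_specificity")
}

#' Per-group gene sets from a specificity matrix
#' @param spec `bb_specificity` object.
#' @param cutoff minimum ESmu for membership (exclusive).
#' @return named list of character gene sets.
#' @export
specificity_sets <- function(spec, cutoff = 0) {
  es <- spec$es_mu
  sets <- lapply(colnames(es), function(g) rownames(es)[es[, g] > cutoff])
  names(sets) <- colnames(es)
  sets
}

#' Hypergeometric enrichment of a query gene set in per-group gene sets
#'
#' Upper-tail hypergeometric test `P[X >= k]` of the overlap between the
#' query and each group's set within a common universe, with
#' Benjamini-Hochberg correction across groups.
#'
#' @param query character vector of gene ids (restricted to the universe).
#' @param group_sets named list of character gene sets.
#' @param universe character vector defining the tested gene universe.
#' @param fdr_q FDR threshold for the `enriched` flag.
#' @return data.frame with `group`, `k`, `K`, `n`, `N`, `p`, `q`,
#'   `enriched`, ordered by `p`.
#' @export
hypergeom_enrich <- function(query, group_sets, universe, fdr_q = 0.05) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  query <- unique(intersect(query, universe))
  rows <- lapply(names(group_sets), function(g) {
    set <- unique(intersect(group_sets[[g]], universe))
    k <- length(intersect(query, set))
    data.frame(group = g, k = k, K = length(set), n = length(query),
               N = length(universe),
               p = phyper(k - 1, length(set), length(universe) - length(set),
                          length(query), lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, method = "BH")
  out$enriched <- out$q < fdr_q
  out[order(out$p, out$group), ]
}

#' Specificity-index (pSI) tissue-specific gene sets and query enrichment
#'
#' For each gene and tissue the specificity statistic is the log expression
#' in the tissue minus the mean log expression over the remaining tissues.
#' Its p-value (the pSI) is empirical against a pooled null built by
#' shuffling tissue labels within each gene `n_perm` times. A gene joins a
#' tissue's set at threshold tau iff pSI < tau; an optional query set is
#' tested per tissue per threshold with [hypergeom_enrich()].
#'
#' @param mean_expr genes x tissues non-negative mean expression matrix
#'   (>= 3 tissues).
#' @param thresholds pSI thresholds, each in (0, 1).
#' @param query optional character vector of query genes.
#' @param n_perm label permutations per gene for the pooled null.
#' @param seed integer seed.
#' @return list of class `bb_psi` with `psi` (genes x tissues p-values),
#'   `stat`, `sets` (per threshold, per tissue), and `enrichment` (when a
#'   query is given; data.frame with a `threshold` column).
#' @export
compute_psi <- function(mean_expr,
                        thresholds = c(0.05, 0.01, 0.001, 0.0001),
                        query = NULL, n_perm = 100, seed = 1L) {
  x <- as.matrix(mean_expr)
  m <- ncol(x)
  if (m < 3) stop("need at least 3 tissues", call. = FALSE)
  if (any(thresholds <= 0 | thresholds >= 1)) {
    stop("thresholds must lie in (0, 1)", call. = FALSE)
  }
  set.seed(as.integer(seed))
  lx <- log(x + 1e-9)
  stat_of <- function(mat) mat - (rowSums(mat) - mat) / (m - 1)
  stat <- stat_of(lx)

  null_vals <- numeric(0)
  for (b in seq_len(n_perm)) {
    perm <- t(apply(lx, 1, sample))
    null_vals <- c(null_vals, as.numeric(stat_of(perm)))
  }
  # robust-parametric tail on the pooled permutation null: median/MAD are
  # insensitive to the few extreme values contributed by genuinely specific
  # genes, and the continuous tail reaches below the empirical floor of the
  # pool so membership at the tightest thresholds is resolvable
  mu0 <- stats::median(null_vals)
  s0 <- stats::mad(null_vals)
  if (s0 <= 0) s0 <- max(stats::sd(null_vals), 1e-12)
  psi <- matrix(stats::pnorm(stat, mean = mu0, sd = s0, lower.tail = FALSE),
                nrow(x), m, dimnames = dimnames(x))

  thresholds <- sort(thresholds, decreasing = TRUE)
  sets <- lapply(thresholds, function(tau) {
    s <- lapply(colnames(x), function(tis) rownames(x)[psi[, tis] < tau])
    names(s) <- colnames(x)
    s
  })
  names(sets) <- as.character(thresholds)

  enrichment <- NULL
  if (!is.null(query)) {
    enrichment <- do.call(rbind, lapply(as.character(thresholds), function(tau) {
      e <- hypergeom_enrich(query, sets[[tau]], rownames(x))
      e$threshold <- as.numeric(tau)
      e
    }))
  }
  structure(list(psi = psi, stat = stat, thresholds = thresholds,
                 sets = sets, enrichment = enrichment,
                 seed = as.integer(seed)),
            class = "bb_psi")
}
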