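#' Amplitude of low-frequency fluctuations (ALFF)
#'
#' Mean spectral amplitude (square root of periodogram power, scaled so a
#' pure sinusoid of amplitude A yields A at its bin) across frequency bins in
#' `band`, after removing the series mean.
#'
#' @param series numeric time series.
#' @param tr repetition time in seconds.
#' @param band low/high frequency bounds in Hz; must lie inside
#'   (0, Nyquist].
#' @return non-negative scalar.
#' @export
compute_alff <- function(series, tr, band = c(0.01, 0.08)) {
  if (!all(is.finite(series))) stop("series contains non-finite values",
                                    call. = FALSE)
  nyquist <- 1 / (2 * tr)
  if (band[1] <= 0 || band[2] > nyquist || band[1] >= band[2]) {
    stop("band must lie within (0, Nyquist] with band[1] < band[2]",
         call. = FALSE)
  }
  n <- length(series)
  if (n < 2 / ((band[2] - band[1]) * tr)) {
    stop("series too short to resolve the requested band", call. = FALSE)
  }
  x <- series - mean(series)
  xf <- fft(x)
  k <- seq_len(floor(n / 2))                      # positive-frequency bins
  freqs <- k / (n * tr)
  amp <- 2 * Mod(xf[k + 1L]) / n
  sel <- freqs >= band[1] & freqs <= band[2]
  if (!any(sel)) stop("no frequency bins fall inside band", call. = FALSE)
  mean(amp[sel])
}

#' Regional homogeneity: Kendall's coefficient of concordance
#'
#' Kendall's W over `m` time series (columns), with tie correction:
#' `W = 12 S / (m^2 (n^3 - n) - m T)` where `S` is the sum of squared
#' deviations of the per-timepoint rank sums and `T` the tie correction
#' summed over series.
#'
#' @param neighborhood_series numeric matrix, time points x series
#'   (n >= 3 rows, m >= 2 columns).
#' @return W in \[0, 1\], or `NA` (with a warning) when the tie-corrected
#'   denominator vanishes (all series constant).
#' @export
compute_reho <- function(neighborhood_series) {
  x <- as.matrix(neighborhood_series)
  n <- nrow(x)
  m <- ncol(x)
  if (m < 2) stop("need at least 2 series", call. = FALSE)
  if (n < 3) stop("need at least 3 time points", call. = FALSE)
  r <- apply(x, 2, rank, ties.method = "average")
  rs <- rowSums(r)
  s <- sum((rs - mean(rs))^2)
  tie_corr <- sum(apply(x, 2, function(col) {
    tl <- table(col)
    sum(tl^3 - tl)
  }))
  denom <- m^2 * (n^3 - n) - m * tie_corr
  if (denom <= 0) {
    warning("Kendall's W undefined: tie correction exhausts the denominator")
    return(NA_real_)
  }
  12 * s / denom
}

#' Per-parcel ALFF map from a subject's parcel-by-time matrix
#' @param series parcel x time matrix with parcel ids as rownames.
#' @inheritParams compute_alff
#' @return named numeric vector of ALFF values.
#' @export
alff_map <- function(series, tr, band = c(0.01, 0.08)) {
  apply(series, 1, compute_alff, tr = tr, band = band)
}

#' Neighbor structure of a parcellation
#'
#' Adjacency by distance: two parcels are neighbors when their Euclidean
#' distance is at most `radius`. On a lattice from [gen_parcellation()] the
#' default radius (1.8 spacings) yields 26-connectivity plus the parcel
#' itself excluded.
#'
#' @param parcels parcel table.
#' @param radius neighbor distance threshold.
#' @return named list of integer neighbor indices per parcel.
#' @export
parcel_adjacency <- function(parcels, radius = 18) {
  dmat <- parcel_distances(parcels)
  adj <- lapply(seq_len(nrow(dmat)), function(i) {
    which(dmat[i, ] > 0 & dmat[i, ] <= radius)
  })
  names(adj) <- parcels$parcel_id
  adj
}

#' Per-parcel ReHo map using a neighborhood graph
#' @param series parcel x time matrix.
#' @param adjacency neighbor list from [parcel_adjacency()].
#' @return named numeric vector of Kendall's W values.
#' @export
reho_map <- function(series, adjacency) {
  p <- nrow(series)
  w <- vapply(seq_len(p), function(i) {
    nb <- c(i, adjacency[[i]])
    compute_reho(t(series[nb, , drop = FALSE]))
  }, numeric(1))
  names(w) <- rownames(series)
  w
}

# Per-parcel t statistics for the group column of design X against the
# subject x parcel response matrix Y.
.group_tstats <- function(X, Y, group_col = 2L) {
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    bad <- colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  coefs <- qr.coef(qrx, Y)
  res <- Y - X %*% coefs
  df <- nrow(X) - ncol(X)
  sigma2 <- colSums(res^2) / df
  xtxinv <- chol2inv(qr.R(qrx))[group_col, group_col]
  t <- coefs[group_col, ] / sqrt(sigma2 * xtxinv)
  list(t = t, df = df)
}

# Connected components of `idx` (integer parcel indices) under a neighbor
# list; returns a list of integer vectors.
.components_in <- function(idx, adjacency) {
  if (length(idx) == 0) return(list())
  inset <- logical(length(adjacency))
  inset[idx] <- TRUE
  seen <- logical(length(adjacency))
  comps <- list()
  for (start in idx) {
    if (seen[start]) next
    queue <- start
    seen[start] <- TRUE
    comp <- integer()
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      comp <- c(comp, v)
      nb <- adjacency[[v]]
      nb <- nb[inset[nb] & !seen[nb]]
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}

#' Covariate-adjusted group contrast with cluster-level permutation FWE
#'
#' Fits a per-parcel linear model `value ~ group + covariates`, forms
#' clusters of supra-threshold parcels (two-sided `forming_p`, positive and
#' negative t clustered separately) on the neighbor graph, and assigns each
#' cluster a family-wise-error p-value from the permutation distribution of
#' the maximum cluster extent under group-label exchange.
#'
#' @param maps1,maps2 subject x parcel matrices (or lists of named vectors)
#'   for the two groups.
#' @param covariates optional data.frame of numeric covariates, rows aligned
#'   to `rbind(maps1, maps2)` subjects.
#' @param forming_p two-sided cluster-forming p threshold.
#' @param n_perm number of label permutations.
#' @param adjacency neighbor list from [parcel_adjacency()].
#' @param seed integer seed for the permutations.
#' @return list of class `bb_contrast`: `t_map`, `dof`, `clusters`
#'   (data.frame: id, sign, size, peak parcel, `fwe_p`), `cluster_labels`
#'   (integer per parcel, 0 = none), `forming_p`, `n_perm`,
#'   `covariates_used`, and `method` metadata.
#' @export
group_contrast <- function(maps1, maps2, covariates = NULL,
                           forming_p = 0.001, n_perm = 1000, adjacency,
                           seed = 1L) {
  to_mat <- function(m) if (is.list(m)) do.call(rbind, m) else as.matrix(m)
  y1 <- to_mat(maps1)
  y2 <- to_mat(maps2)
  if (nrow(y1) < 3 || nrow(y2) < 3) {
    stop("both groups need at least 3 subjects", call. = FALSE)
  }
  if (!identical(colnames(y1), colnames(y2))) {
    stop("groups have mismatched parcels", call. = FALSE)
  }
  Y <- rbind(y1, y2)
  group <- rep(c(0, 1), c(nrow(y1), nrow(y2)))
  if (length(unique(group)) < 2) stop("degenerate design: one group",
                                      call. = FALSE)
  X <- cbind(intercept = 1, group = group)
  if (!is.null(covariates)) {
    cov_m <- as.matrix(data.frame(covariates))
    if (nrow(cov_m) != nrow(Y)) {
      stop("covariates not row-aligned to subjects", call. = FALSE)
    }
    X <- cbind(X, cov_m)
  }
  obs <- .group_tstats(X, Y)
  tcrit <- qt(1 - forming_p / 2, obs$df)

  clusters_of <- function(tv) {
    pos <- .components_in(which(tv >= tcrit), adjacency)
    neg <- .components_in(which(tv <= -tcrit), adjacency)
    list(pos = pos, neg = neg)
  }
  obs_cl <- clusters_of(obs$t)
  all_cl <- c(lapply(obs_cl$pos, function(x) list(sign = 1L, idx = x)),
              lapply(obs_cl$neg, function(x) list(sign = -1L, idx = x)))

  set.seed(as.integer(seed))
  max_null <- vapply(seq_len(n_perm), function(i) {
    Xp <- X
    Xp[, "group"] <- sample(group)
    tp <- .group_tstats(Xp, Y)$t
    cl <- clusters_of(tp)
    sizes <- c(lengths(cl$pos), lengths(cl$neg), 0L)
    max(sizes)
  }, numeric(1))

  parcel_ids <- colnames(Y) %||% as.character(seq_along(obs$t))
  cluster_labels <- integer(length(obs$t))
  if (length(all_cl)) {
    ord <- order(vapply(all_cl, function(c) -length(c$idx), numeric(1)))
    all_cl <- all_cl[ord]
    rows <- lapply(seq_along(all_cl), function(i) {
      cl <- all_cl[[i]]
      cluster_labels[cl$idx] <<- i
      peak <- cl$idx[which.max(abs(obs$t[cl$idx]))]
      data.frame(
        cluster_id = i, sign = cl$sign, size = length(cl$idx),
        peak = parcel_ids[peak],
        fwe_p = (1 + sum(max_null >= length(cl$idx))) / (n_perm + 1),
        stringsAsFactors = FALSE
      )
    })
    clusters <- do.call(rbind, rows)
  } else {
    clusters <- data.frame(cluster_id = integer(), sign = integer(),
                           size = integer(), peak = character(),
                           fwe_p = numeric(), stringsAsFactors = FALSE)
  }
  names(cluster_labels) <- parcel_ids
  tm <- obs$t
  names(tm) <- parcel_ids
  structure(list(
    t_map = tm, dof = obs$df, clusters = clusters,
    cluster_labels = cluster_labels, forming_p = forming_p, n_perm = n_perm,
    covariates_used = if (is.null(covariates)) character()
                      else colnames(data.frame(covariates)),
    method = "max-cluster-extent permutation FWE", seed = as.integer(seed)
  ), class = "bb_contrast")
}

#' Overlap of a significant-parcel set with atlas networks
#'
#' Percentage of significant units falling in each network:
#' `|mask intersect network| / |mask| * 100`.
#'
#' @param significant_mask character vector of significant unit ids.
#' @param atlas named character vector mapping unit id to network label.
#' @return data.frame with `network`, `n_units`, `percent`; attribute
#'   `total_significant`.
#' @export
network_overlap <- function(significant_mask, atlas) {
  mask <- unique(significant_mask)
  if (length(mask) == 0) stop("empty significance mask", call. = FALSE)
  if (!all(mask %in% names(atlas))) {
    stop("atlas does not cover all significant units", call. = FALSE)
  }
  labels <- atlas[mask]
  tab <- table(factor(labels, levels = sort(unique(atlas))))
  out <- data.frame(
    network = names(tab), n_units = as.integer(tab),
    percent = 100 * as.integer(tab) / length(mask),
    stringsAsFactors = FALSE
  )
  attr(out, "total_significant") <- length(mask)
  out
}
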