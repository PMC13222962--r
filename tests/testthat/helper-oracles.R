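# Independent oracles used across the suite. Each recomputes a quantity by
# brute force (explicit formulas, enumeration, direct DFT) without touching
# the implementation paths it checks.

# average ranks computed by counting, not via rank()
oracle_ranks <- function(x) {
  vapply(x, function(xi) sum(x < xi) + (sum(x == xi) + 1) / 2, numeric(1))
}

# Spearman rho via the explicit product-moment formula on counted ranks
oracle_spearman <- function(x, y) {
  rx <- oracle_ranks(x)
  ry <- oracle_ranks(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Kendall's W with tie correction, from counted ranks
oracle_kendall_w <- function(mat) {
  n <- nrow(mat)
  m <- ncol(mat)
  r <- apply(mat, 2, oracle_ranks)
  rs <- rowSums(r)
  s <- sum((rs - mean(rs))^2)
  tie <- sum(apply(mat, 2, function(col) {
    tl <- as.numeric(table(col))
    sum(tl^3 - tl)
  }))
  12 * s / (m^2 * (n^3 - n) - m * tie)
}

# hypergeometric upper tail P[X >= k] by direct choose() summation
oracle_hyper_tail <- function(k, K, N, n) {
  if (k <= 0) return(1)
  j <- k:min(n, K)
  if (length(j) == 0 || k > min(n, K)) return(0)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# two-sided Wilcoxon rank-sum p by full enumeration of group assignments
oracle_ranksum_p <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  r <- oracle_ranks(pooled)
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(pooled), n1)
  w_all <- apply(combos, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mu <- mean(w_all)
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12)
}

# in-band mean amplitude by explicit DFT sums (no fft)
oracle_alff_dft <- function(x, tr, band = c(0.01, 0.08)) {
  n <- length(x)
  x <- x - mean(x)
  t_idx <- 0:(n - 1)
  ks <- seq_len(floor(n / 2))
  amps <- vapply(ks, function(k) {
    re <- sum(x * cos(2 * pi * k * t_idx / n))
    im <- sum(x * sin(2 * pi * k * t_idx / n))
    2 * sqrt(re^2 + im^2) / n
  }, numeric(1))
  freqs <- ks / (n * tr)
  mean(amps[freqs >= band[1] & freqs <= band[2]])
}

# smooth Gaussian random field over a parcellation (test fixture builder)
make_smooth_map <- function(parcels, length_scale = 10, seed = 1) {
  d <- as.matrix(dist(parcels[, c("x", "y", "z")]))
  K <- exp(-d^2 / (2 * length_scale^2))
  L <- chol(K + diag(1e-8, nrow(d)))
  set.seed(seed)
  v <- drop(t(L) %*% rnorm(nrow(d)))
  names(v) <- parcels$parcel_id
  v
}

# all permutations of 1..n as a list (recursive enumeration)
combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  sub <- combinat_perms(n - 1L)
  out <- list()
  for (s in sub) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(s, n, after = pos - 1L)
    }
  }
  out
}

parcel_dist <- function(parcels) {
  d <- as.matrix(dist(parcels[, c("x", "y", "z")]))
  dimnames(d) <- list(parcels$parcel_id, parcels$parcel_id)
  d
}
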