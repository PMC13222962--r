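#' @importFrom stats cor rnorm runif rpois rnbinom sd var qt pt phyper
#' @importFrom stats p.adjust wilcox.test lm hclust cophenetic as.dist dist
#' @importFrom stats fft complete.cases quantile rank
#' @importFrom utils head tail read.delim write.table
NULL

# Euclidean distance matrix from a parcel table (columns x, y, z).
parcel_distances <- function(parcels) {
  xyz <- as.matrix(parcels[, c("x", "y", "z")])
  d <- as.matrix(dist(xyz))
  dimnames(d) <- list(parcels$parcel_id, parcels$parcel_id)
  d
}

# Gaussian spatial kernel; `length_scale` in the same units as the distances.
gaussian_kernel <- function(dmat, length_scale) {
  if (length_scale <= 0) stop("length_scale must be positive")
  exp(-dmat^2 / (2 * length_scale^2))
}

# Cholesky factor of a kernel with a small jitter for numerical rank safety.
kernel_chol <- function(K, jitter = 1e-8) {
  chol(K + diag(jitter * nrow(K), nrow(K)))
}

# Draw n spatially correlated standard-normal fields (columns) over parcels.
smooth_fields <- function(L, n) {
  z <- matrix(rnorm(nrow(L) * n), nrow(L), n)
  crossprod(L, z)
}

stopifnot_scalar_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != round(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min),
         call. = FALSE)
  }
  invisible(as.integer(x))
}

# Derive a reproducible child seed (kept below 2^31) from a base seed.
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(offset)) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
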