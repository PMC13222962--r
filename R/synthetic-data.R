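#' Synthetic data generators with planted ground truth
#'
#' Every input the analysis pipeline consumes can be simulated with a known
#' ground truth: which parcels carry a group effect, which genes track the
#' contrast map spatially (and at what target Spearman rho), which gene
#' program is planted in which cell type of which region, and the mediation
#' path coefficients. All generators are pure functions of their arguments
#' including `seed`.
#'
#' @name synthetic-data
NULL

new_ground_truth <- function(...) {
  gt <- list(...)
  class(gt) <- "bb_ground_truth"
  gt
}

#' @method print bb_ground_truth
#' @export
print.bb_ground_truth <- function(x, ...) {
  cat("<bb_ground_truth>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    if (is.atomic(v) && length(v) <= 8) {
      cat(" ", nm, ":", paste(v, collapse = ", "), "\n")
    } else {
      cat(" ", nm, ": <", class(v)[1], " length ", length(v), ">\n", sep = "")
    }
  }
  invisible(x)
}

#' Generate a synthetic parcellation with 3D coordinates
#'
#' Parcels are laid out on a jittered 3D lattice (`geometry = "grid"`) or
#' uniformly at random in a cube (`geometry = "random"`), with a cyclic
#' assignment to seven canonical network labels. Coordinates are in
#' millimetre-like arbitrary units.
#'
#' @param n_parcels number of parcels (>= 10).
#' @param geometry `"grid"` or `"random"`.
#' @param seed integer seed; the same seed reproduces the table exactly.
#' @param spacing lattice spacing for the grid layout.
#' @return a `data.frame` with columns `parcel_id`, `x`, `y`, `z`,
#'   `network_label`.
#' @export
gen_parcellation <- function(n_parcels, geometry = c("grid", "random"),
                             seed = 1L, spacing = 10) {
  stopifnot_scalar_count(n_parcels, "n_parcels", min = 1L)
  if (n_parcels < 10) stop("n_parcels must be >= 10", call. = FALSE)
  geometry <- match.arg(geometry)
  set.seed(as.integer(seed))
  if (geometry == "grid") {
    side <- ceiling(n_parcels^(1 / 3))
    g <- expand.grid(x = seq_len(side), y = seq_len(side), z = seq_len(side))
    g <- g[seq_len(n_parcels), ] * spacing
    # sub-voxel jitter keeps pairwise distances strictly positive and breaks
    # lattice ties in the distance matrix
    jit <- matrix(runif(3 * n_parcels, -0.1, 0.1) * spacing, ncol = 3)
    xyz <- as.matrix(g) + jit
  } else {
    side <- spacing * ceiling(n_parcels^(1 / 3))
    xyz <- matrix(runif(3 * n_parcels, 0, side), ncol = 3)
  }
  networks <- c("Visual", "Somatomotor", "DorsalAttention", "VentralAttention",
                "Limbic", "Frontoparietal", "Default")
  out <- data.frame(
    parcel_id = sprintf("p%03d", seq_len(n_parcels)),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    network_label = networks[(seq_len(n_parcels) - 1L) %% 7L + 1L],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

# FFT band-pass of the columns of a (time x parcel) matrix; returns the
# real part of the inverse transform restricted to [lo, hi] Hz.
bandpass_columns <- function(x, tr, band) {
  n <- nrow(x)
  freqs <- (seq_len(n) - 1) / (n * tr)
  freqs <- pmin(freqs, 1 / tr - freqs)  # fold to [0, Nyquist]
  keep <- freqs >= band[1] & freqs <= band[2]
  xf <- stats::mvfft(x)
  xf[!keep, ] <- 0
  Re(stats::mvfft(xf, inverse = TRUE)) / n
}

#' Simulate two groups of parcel-by-time resting-state series
#'
#' Each subject's series is an in-band (default 0.01-0.08 Hz) component with a
#' subject- and parcel-specific amplitude plus broadband noise; both
#' components are spatially correlated across parcels with a Gaussian kernel
#' of length scale `autocorr_length`. In group 2, the in-band amplitude of
#' `effect_parcels` is shifted by `effect_size` standard deviations of the
#' between-subject amplitude variation, so ALFF carries a standardized group
#' difference of approximately `effect_size` there.
#'
#' @param parcels parcel table from [gen_parcellation()].
#' @param n_per_group subjects per group.
#' @param n_timepoints number of volumes (>= 64).
#' @param tr repetition time in seconds.
#' @param effect_parcels character vector of parcel ids carrying the effect.
#' @param effect_size standardized amplitude difference (Cohen's d scale).
#' @param autocorr_length spatial autocorrelation length scale (same units as
#'   parcel coordinates).
#' @param seed integer seed.
#' @param band frequency band in Hz.
#' @param amp_sd between-subject relative amplitude standard deviation.
#' @param noise_sd broadband noise standard deviation relative to the unit
#'   in-band amplitude.
#' @return list with `group1`, `group2` (each a list of parcel x time
#'   matrices), `parcels`, `tr`, `band`, and `ground_truth`.
#' @export
gen_group_timeseries <- function(parcels, n_per_group, n_timepoints, tr = 2,
                                 effect_parcels = character(),
                                 effect_size = 0, autocorr_length = 10,
                                 seed = 1L, band = c(0.01, 0.08),
                                 amp_sd = 0.15, noise_sd = 0.3) {
  stopifnot_scalar_count(n_per_group, "n_per_group", min = 3L)
  stopifnot_scalar_count(n_timepoints, "n_timepoints", min = 1L)
  if (n_timepoints < 64) stop("n_timepoints must be >= 64", call. = FALSE)
  if (tr <= 0) stop("tr must be positive", call. = FALSE)
  if (!all(effect_parcels %in% parcels$parcel_id)) {
    stop("effect_parcels contains ids absent from the parcellation",
         call. = FALSE)
  }
  set.seed(as.integer(seed))
  p <- nrow(parcels)
  dmat <- parcel_distances(parcels)
  L <- kernel_chol(gaussian_kernel(dmat, autocorr_length))
  eff <- parcels$parcel_id %in% effect_parcels

  sim_subject <- function(shift) {
    base <- t(smooth_fields(L, n_timepoints))         # time x parcel
    inband <- bandpass_columns(base, tr, band)
    # normalize each parcel's in-band component to unit ALFF so the planted
    # amplitude is the standardized quantity
    scale_p <- apply(inband, 2, function(v) {
      a <- compute_alff(v, tr, band)
      if (a > 0) a else 1
    })
    inband <- sweep(inband, 2, scale_p, "/")
    amp <- 1 + amp_sd * drop(smooth_fields(L, 1))
    if (shift) amp[eff] <- amp[eff] + effect_size * amp_sd
    amp <- pmax(amp, 0.05)
    noise <- t(smooth_fields(L, n_timepoints)) * noise_sd
    series <- sweep(inband, 2, amp, "*") + noise
    m <- t(series)                                    # parcel x time
    rownames(m) <- parcels$parcel_id
    m
  }

  group1 <- lapply(seq_len(n_per_group), function(i) sim_subject(FALSE))
  group2 <- lapply(seq_len(n_per_group), function(i) sim_subject(TRUE))
  names(group1) <- sprintf("g1_s%03d", seq_len(n_per_group))
  names(group2) <- sprintf("g2_s%03d", seq_len(n_per_group))
  list(
    group1 = group1, group2 = group2, parcels = parcels, tr = tr, band = band,
    ground_truth = new_ground_truth(
      effect_parcels = effect_parcels, effect_size = effect_size,
      autocorr_length = autocorr_length, seed = as.integer(seed)
    )
  )
}

#' Simulate a regional gene-expression matrix with spatially linked genes
#'
#' `n_linked` genes are constructed on the normal-score scale as a mixture of
#' the reference map's normal scores and an independent spatially smooth
#' field, with mixing weight chosen so the expected Spearman correlation with
#' the map equals `rho_target` (using the bivariate-normal rank-correlation
#' identity rho_s = (6/pi) asin(r/2)). The remaining genes are smooth fields
#' with the same autocorrelation. Values are exponentiated so the matrix is
#' strictly positive.
#'
#' @param parcels parcel table.
#' @param n_genes total genes.
#' @param reference_map named numeric vector over `parcels$parcel_id`.
#' @param n_linked number of linked genes (<= n_genes).
#' @param rho_target target Spearman correlation in (0, 1].
#' @param noise_sd standard-deviation multiplier of the orthogonal component;
#'   `0` collapses linked genes onto an exact monotone transform of the map.
#' @param autocorr_length spatial length scale of the gene fields.
#' @param seed integer seed.
#' @return list with `expr` (genes x parcels matrix) and `ground_truth`.
#' @export
gen_expression_matrix <- function(parcels, n_genes, reference_map,
                                  n_linked = 0, rho_target = 0.6,
                                  noise_sd = 1, autocorr_length = 10,
                                  seed = 1L) {
  stopifnot_scalar_count(n_genes, "n_genes", min = 1L)
  if (n_linked > n_genes) stop("n_linked must be <= n_genes", call. = FALSE)
  if (rho_target <= 0 || rho_target > 1) {
    stop("rho_target must lie in (0, 1]", call. = FALSE)
  }
  if (!all(parcels$parcel_id %in% names(reference_map))) {
    stop("reference_map does not cover all parcels", call. = FALSE)
  }
  set.seed(as.integer(seed))
  p <- nrow(parcels)
  map <- reference_map[parcels$parcel_id]
  z_map <- stats::qnorm((rank(map, ties.method = "average") - 0.5) / p)
  dmat <- parcel_distances(parcels)
  L <- kernel_chol(gaussian_kernel(dmat, autocorr_length))
  r <- 2 * sin(pi * rho_target / 6)

  genes <- sprintf("g%05d", seq_len(n_genes))
  expr <- matrix(NA_real_, n_genes, p, dimnames = list(genes, parcels$parcel_id))
  if (n_linked > 0) {
    eps <- smooth_fields(L, n_linked)
    zz <- r * matrix(z_map, p, n_linked) + sqrt(1 - r^2) * noise_sd * eps
    if (noise_sd == 0) zz <- r * matrix(z_map, p, n_linked)
    expr[seq_len(n_linked), ] <- t(zz)
  }
  if (n_linked < n_genes) {
    idx <- (n_linked + 1):n_genes
    expr[idx, ] <- t(smooth_fields(L, length(idx)))
  }
  expr <- exp(expr)
  list(
    expr = expr,
    ground_truth = new_ground_truth(
      linked_genes = genes[seq_len(n_linked)], rho_target = rho_target,
      seed = as.integer(seed)
    )
  )
}

#' Simulate single-cell counts with a planted gene program
#'
#' Counts follow a low-rank Poisson (optionally negative-binomial) rate
#' model: gene baselines, per-region marker genes, `program_rank` latent
#' factors whose activities vary by cell type, and one designated program
#' whose gene loadings are concentrated on a planted gene set and whose
#' activity is high only in `program_cell_type` cells of `program_region`.
#'
#' @param n_genes number of genes.
#' @param regions character vector of region labels.
#' @param cell_types character vector of cell-type labels.
#' @param cells_per_group cells per (region, cell type) combination.
#' @param program_rank number of latent factors (the planted program is the
#'   last one).
#' @param program_cell_type,program_region labels carrying the planted
#'   program.
#' @param seed integer seed.
#' @param program_strength activity of the planted program in its target
#'   cells; `0` removes the program (null data).
#' @param program_size number of genes in the planted program.
#' @param markers_per_region region-marker genes per region.
#' @param nb_size negative-binomial size parameter; `Inf` gives Poisson.
#' @param background `"cell_type"` concentrates each background factor in
#'   one cell type (well-separated programs); `"shared"` draws activities
#'   independently of the labels, making cells exchangeable across types
#'   when the program is absent (a clean type-I null).
#' @return list with `counts` (genes x cells), `cells` (data.frame with
#'   `cell_id`, `region`, `cell_type`), and `ground_truth`.
#' @export
gen_cell_counts <- function(n_genes, regions, cell_types, cells_per_group = 50,
                            program_rank = 4, program_cell_type = cell_types[1],
                            program_region = regions[1], seed = 1L,
                            program_strength = 2, program_size = 40,
                            markers_per_region = 10, nb_size = Inf,
                            background = c("cell_type", "shared")) {
  background <- match.arg(background)
  if (length(regions) == 0 || length(cell_types) == 0) {
    stop("regions and cell_types must be non-empty", call. = FALSE)
  }
  if (!program_cell_type %in% cell_types) {
    stop("program_cell_type not in cell_types", call. = FALSE)
  }
  if (!program_region %in% regions) {
    stop("program_region not in regions", call. = FALSE)
  }
  set.seed(as.integer(seed))
  genes <- sprintf("g%05d", seq_len(n_genes))
  grid <- expand.grid(region = regions, cell_type = cell_types,
                      stringsAsFactors = FALSE)
  cells <- grid[rep(seq_len(nrow(grid)), each = cells_per_group), ]
  n_cells <- nrow(cells)
  cells$cell_id <- sprintf("c%05d", seq_len(n_cells))
  rownames(cells) <- NULL

  baseline <- exp(rnorm(n_genes, log(0.5), 0.6))
  rate <- matrix(baseline, n_genes, n_cells)

  # region markers guarantee region-specific genes for specificity scoring
  marker_sets <- list()
  free <- seq_len(n_genes)
  for (r in regions) {
    pick <- sample(free, markers_per_region)
    free <- setdiff(free, pick)
    marker_sets[[r]] <- genes[pick]
    rate[pick, cells$region == r] <- rate[pick, cells$region == r] + 3
  }

  # latent factors: gene loadings on random subsets, activities by cell type
  k <- program_rank
  w0 <- matrix(0, n_genes, k)
  h0 <- matrix(0, k, n_cells)
  factor_size <- max(10L, round(n_genes / 10))
  if (program_size > length(free)) {
    stop("program_size exceeds the genes left after region markers; ",
         "increase n_genes or reduce program_size/markers_per_region",
         call. = FALSE)
  }
  prog_genes_idx <- sample(free, program_size)
  for (j in seq_len(k)) {
    if (j == k) {
      w0[prog_genes_idx, j] <- stats::rgamma(program_size, 4, 1)
      target <- cells$region == program_region &
        cells$cell_type == program_cell_type
      h0[j, ] <- ifelse(target, program_strength,
                        min(0.02, program_strength))
    } else {
      idx <- sample(setdiff(seq_len(n_genes), prog_genes_idx), factor_size)
      w0[idx, j] <- stats::rgamma(factor_size, 2, 1)
      if (background == "cell_type") {
        # each background factor is concentrated in one cell type, so the
        # planted factorization has well-separated programs
        ct <- cell_types[(j - 1L) %% length(cell_types) + 1L]
        h0[j, ] <- ifelse(cells$cell_type == ct, 1.5, 0.05) *
          stats::runif(n_cells, 0.8, 1.2)
      } else {
        # exchangeable background: activities independent of the labels
        h0[j, ] <- stats::runif(n_cells, 0.5, 1.5)
      }
    }
  }
  w0 <- sweep(w0, 2, pmax(colMeans(w0), 1e-12), "/")
  rate <- rate + w0 %*% h0
  lib <- stats::runif(n_cells, 0.5, 1.5)
  rate <- sweep(rate, 2, lib, "*")
  counts <- if (is.finite(nb_size)) {
    matrix(rnbinom(length(rate), mu = rate, size = nb_size), n_genes, n_cells)
  } else {
    matrix(rpois(length(rate), rate), n_genes, n_cells)
  }
  dimnames(counts) <- list(genes, cells$cell_id)
  list(
    counts = counts,
    cells = cells[, c("cell_id", "region", "cell_type")],
    ground_truth = new_ground_truth(
      program_rank = program_rank, program_gene_set = genes[prog_genes_idx],
      program_cell_type = program_cell_type, program_region = program_region,
      region_markers = marker_sets, seed = as.integer(seed)
    )
  )
}

#' Simulate a mediation cohort with known path coefficients
#'
#' Generates a bone-density-like exposure `BMD`, a hippocampal-activity-like
#' mediator `ALFF`, and a cognition-like outcome `MoCA` following exactly
#' `M = a X + e1`, `Y = c' X + b M + e2`, plus independent nuisance
#' covariates (age, sex, education).
#'
#' @param n subjects (>= 10).
#' @param a,b,c_prime path coefficients.
#' @param noise_sds length-2 vector: SD of e1 and e2.
#' @param seed integer seed.
#' @return a `data.frame` with columns `BMD`, `ALFF`, `MoCA`, `age`, `sex`,
#'   `education`.
#' @export
gen_mediation_cohort <- function(n, a, b, c_prime, noise_sds = c(1, 1),
                                 seed = 1L) {
  stopifnot_scalar_count(n, "n", min = 10L)
  if (!all(is.finite(c(a, b, c_prime, noise_sds)))) {
    stop("path coefficients and noise SDs must be finite", call. = FALSE)
  }
  set.seed(as.integer(seed))
  x <- rnorm(n)
  m <- a * x + noise_sds[1] * rnorm(n)
  y <- c_prime * x + b * m + noise_sds[2] * rnorm(n)
  data.frame(
    BMD = x, ALFF = m, MoCA = y,
    age = round(rnorm(n, 65, 8), 1),
    sex = sample(c(0L, 1L), n, replace = TRUE),
    education = pmax(0, round(rnorm(n, 12, 3)))
  )
}
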