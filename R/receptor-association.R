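#' Subject-minus-control-mean difference map
#'
#' @param subject_map named numeric vector (one value per parcel).
#' @param control_reference named numeric vector, the mean control map on
#'   the same parcels.
#' @return named numeric difference map.
#' @export
subject_difference_map <- function(subject_map, control_reference) {
  if (!identical(names(subject_map), names(control_reference))) {
    stop("parcel mismatch between subject map and control reference",
         call. = FALSE)
  }
  subject_map - control_reference
}

#' Fisher-z Spearman correlations of subject difference maps with a
#' receptor density map
#'
#' Rho is clamped to +/- (1 - 1e-12) before the arctanh transform so z stays
#' finite when a subject map matches the receptor map exactly.
#'
#' @param diff_maps subjects x parcels matrix (or list of named vectors) of
#'   difference maps.
#' @param receptor named numeric receptor density map on the same parcels.
#' @param receptor_name label carried into the output.
#' @return data.frame with `subject`, `receptor`, `rho`, `fisher_z`.
#' @export
receptor_correlate <- function(diff_maps, receptor,
                               receptor_name = "receptor") {
  if (is.list(diff_maps)) diff_maps <- do.call(rbind, diff_maps)
  diff_maps <- as.matrix(diff_maps)
  if (ncol(diff_maps) < 8) stop("need at least 8 parcels", call. = FALSE)
  if (!identical(colnames(diff_maps), names(receptor))) {
    stop("parcel mismatch between difference maps and receptor map",
         call. = FALSE)
  }
  if (length(unique(receptor)) == 1) {
    stop("constant receptor map: ranks undefined", call. = FALSE)
  }
  rr <- rank(receptor, ties.method = "average")
  rho <- apply(diff_maps, 1, function(v) {
    cor(rank(v, ties.method = "average"), rr)
  })
  rho <- pmin(pmax(rho, -(1 - 1e-12)), 1 - 1e-12)
  data.frame(
    subject = rownames(diff_maps) %||% sprintf("s%03d", seq_along(rho)),
    receptor = receptor_name, rho = as.numeric(rho),
    fisher_z = atanh(rho), stringsAsFactors = FALSE
  )
}

#' Group-level receptor association test against spatial surrogate nulls
#'
#' For each receptor, the observed statistic is the mean Fisher z across
#' subjects; the null distribution recomputes the same statistic replacing
#' the receptor map by each of its spatial surrogates. Two-sided empirical
#' p-values are Benjamini-Hochberg corrected across receptors.
#'
#' @param diff_maps subjects x parcels matrix of difference maps.
#' @param receptors named list of receptor maps (named numeric vectors).
#' @param ensembles named list of `bb_surrogates`, one per receptor, built
#'   from each receptor map.
#' @param fdr_q FDR threshold used for the `significant` flag.
#' @return data.frame with `receptor`, `mean_z` (the reported R statistic),
#'   `mean_rho`, `p`, `q`, `significant`.
#' @export
group_receptor_test <- function(diff_maps, receptors, ensembles,
                                fdr_q = 0.05) {
  if (is.list(diff_maps)) diff_maps <- do.call(rbind, diff_maps)
  diff_maps <- as.matrix(diff_maps)
  n_sub <- nrow(diff_maps)
  if (n_sub < 2) stop("need at least 2 subjects", call. = FALSE)
  if (n_sub < 5) warning("fewer than 5 subjects: group statistic unstable")
  stopifnot(identical(names(receptors), names(ensembles)))

  ranks_sub <- t(apply(diff_maps, 1, rank, ties.method = "average"))
  mean_z_for <- function(map_vals) {
    rr <- rank(map_vals, ties.method = "average")
    rho <- drop(cor(t(ranks_sub), rr))
    rho <- pmin(pmax(rho, -(1 - 1e-12)), 1 - 1e-12)
    mean(atanh(rho))
  }

  rows <- lapply(names(receptors), function(nm) {
    obs <- mean_z_for(receptors[[nm]])
    null <- apply(ensembles[[nm]]$surrogates, 2, mean_z_for)
    p <- (1 + sum(abs(null) >= abs(obs))) / (length(null) + 1)
    stats_tab <- receptor_correlate(diff_maps, receptors[[nm]],
                                    receptor_name = nm)
    data.frame(receptor = nm, mean_z = obs, mean_rho = mean(stats_tab$rho),
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, method = "BH")
  out$significant <- out$q < fdr_q
  out
}
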