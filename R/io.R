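#' Read and write the pipeline's plain-text formats
#'
#' Parcel tables, parcellated maps, expression matrices and subject time
#' series travel as TSV; single-cell counts as MatrixMarket MTX plus label
#' TSVs; gene-set collections as GMT; cohorts as CSV; ground truth as JSON.
#'
#' @name io
NULL

#' @rdname io
#' @param parcels parcel table.
#' @param path file path.
#' @export
write_parcels <- function(parcels, path) {
  write.table(parcels, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_parcels <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname io
#' @param map named numeric vector over parcels.
#' @export
write_map_tsv <- function(map, path) {
  write.table(data.frame(parcel_id = names(map), value = as.numeric(map)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_map_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  out <- df[[2]]
  names(out) <- df[[1]]
  out
}

#' @rdname io
#' @param expr genes x parcels (or genes x cells) matrix.
#' @export
write_expression_tsv <- function(expr, path) {
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_expression_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' @rdname io
#' @param series parcel x time matrix for one subject.
#' @export
write_subject_series <- function(series, path) {
  df <- data.frame(parcel_id = rownames(series), series, check.names = FALSE)
  colnames(df)[-1] <- sprintf("t%04d", seq_len(ncol(series)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_subject_series <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' @rdname io
#' @param counts genes x cells count matrix.
#' @param cells cell label table (`cell_id`, `region`, `cell_type`).
#' @param dir output directory (created if missing); writes `matrix.mtx`,
#'   `genes.tsv`, `cells.tsv`.
#' @export
write_counts_mtx <- function(counts, cells, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts), file.path(dir, "genes.tsv"))
  write.table(cells, file.path(dir, "cells.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(dir)
}

#' @rdname io
#' @export
read_counts_mtx <- function(dir) {
  m <- as.matrix(Matrix::readMM(file.path(dir, "matrix.mtx")))
  genes <- readLines(file.path(dir, "genes.tsv"))
  cells <- read.delim(file.path(dir, "cells.tsv"), stringsAsFactors = FALSE)
  dimnames(m) <- list(genes, cells$cell_id)
  list(counts = m, cells = cells)
}

#' @rdname io
#' @param sets named list of character gene sets.
#' @param description optional per-set description (recycled).
#' @export
write_gmt <- function(sets, path, description = "na") {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, description, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname io
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1)
  sets
}

#' @rdname io
#' @param cohort cohort data.frame.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_cohort_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname io
#' @param gt a `bb_ground_truth` object.
#' @export
write_ground_truth <- function(gt, path) {
  jsonlite::write_json(unclass(gt), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname io
#' @export
read_ground_truth <- function(path) {
  gt <- jsonlite::read_json(path, simplifyVector = TRUE)
  class(gt) <- "bb_ground_truth"
  gt
}
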