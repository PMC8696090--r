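#' Feature-by-cell matrices
#'
#' A `FeatureCellMatrix` holds a sparse features x cells matrix of
#' fragment-overlap counts (or 0/1 after [binarize()]), with feature ids as
#' rows and cell barcodes as columns.
#'
#' @param values A matrix or sparse Matrix, features x cells.
#' @param feature_ids Row ids.
#' @param cell_barcodes Column ids.
#' @param binarized Logical flag.
#' @return A `FeatureCellMatrix`.
#' @export
feature_cell_matrix <- function(values, feature_ids, cell_barcodes,
                                binarized = FALSE) {
  values <- methods::as(methods::as(Matrix::Matrix(values, sparse = TRUE),
                                    "CsparseMatrix"), "generalMatrix")
  if (nrow(values) != length(feature_ids) ||
      ncol(values) != length(cell_barcodes))
    stop("matrix dimensions must match id lists")
  if (any(values@x < 0)) stop("counts must be non-negative")
  if (binarized && !all(values@x %in% c(0, 1)))
    stop("binarized matrix must contain only 0/1")
  dimnames(values) <- list(feature_ids, cell_barcodes)
  structure(list(values = values, feature_ids = as.character(feature_ids),
                 barcodes = as.character(cell_barcodes),
                 binarized = isTRUE(binarized)),
            class = "FeatureCellMatrix")
}

#' @export
print.FeatureCellMatrix <- function(x, ...) {
  cat("FeatureCellMatrix:", length(x$feature_ids), "features x",
      length(x$barcodes), "cells,",
      if (x$binarized) "binarized," else "counts,",
      format(Matrix::nnzero(x$values), big.mark = ","), "nonzero\n")
  invisible(x)
}

#' Build the feature-by-cell count matrix
#'
#' Entry (i, j) is the number of deduplicated nuclear fragments of cell j
#' overlapping feature i by >= 1 bp; a fragment overlapping k features
#' increments all k (no fractional assignment).
#'
#' @param fragments A `FragmentCollection`.
#' @param features A non-empty `FeatureSet`.
#' @param cells Barcodes to include as columns (default: all barcodes in
#'   the collection). Must be a subset of the barcodes present.
#' @return A `FeatureCellMatrix` of counts.
#' @export
build_matrix <- function(fragments, features, cells = NULL) {
  if (n_features(features) == 0L) stop("empty feature set")
  qf <- qualified_fragments(fragments)
  all_bc <- barcodes(fragments)
  if (is.null(cells)) cells <- all_bc
  missing_bc <- setdiff(cells, all_bc)
  if (length(missing_bc))
    stop("cells not present in fragments: ",
         paste(utils::head(missing_bc, 3), collapse = ", "))
  dt <- qf$records[barcode %in% cells]
  fid <- features$features$feature_id
  hits <- GenomicRanges::findOverlaps(intervals_granges(features$features),
                                      intervals_granges(dt))
  i <- S4Vectors::queryHits(hits)
  j <- match(dt$barcode[S4Vectors::subjectHits(hits)], cells)
  values <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                                 dims = c(length(fid), length(cells)))
  feature_cell_matrix(values, fid, cells, binarized = FALSE)
}

#' Binarize a count matrix
#'
#' Presence/absence transform: entries become 1 iff the count is > 0,
#' reducing the influence of noisy low counts before TF-IDF weighting.
#' Binarizing an already binarized matrix is a no-op with a warning.
#'
#' @param m A `FeatureCellMatrix`.
#' @return The binarized `FeatureCellMatrix`.
#' @export
binarize <- function(m) {
  if (m$binarized) {
    warning("matrix is already binarized; no-op")
    return(m)
  }
  v <- m$values
  v@x <- rep(1, length(v@x))
  v <- Matrix::drop0(v)
  feature_cell_matrix(v, m$feature_ids, m$barcodes, binarized = TRUE)
}

#' Drop ubiquitous and rare features
#'
#' A feature's prevalence is the fraction of cells in which it is detected
#' (value 1 in the binarized matrix). Features strictly above `max_prev`
#' (ubiquitous, uninformative) or strictly below `min_prev` (rare, noise)
#' are removed; features sitting exactly at a threshold are kept.
#'
#' @param m A binarized `FeatureCellMatrix`.
#' @param max_prev Upper prevalence bound (default 0.80).
#' @param min_prev Lower prevalence bound (default 0.001).
#' @return Filtered `FeatureCellMatrix`; attribute `"dropped"` records the
#'   number of features dropped by each rule.
#' @export
filter_features_by_prevalence <- function(m, max_prev = 0.80,
                                          min_prev = 0.001) {
  if (!m$binarized) stop("prevalence filtering requires a binarized matrix")
  prev <- Matrix::rowSums(m$values) / length(m$barcodes)
  ubiquitous <- prev > max_prev
  rare <- prev < min_prev
  keep <- !(ubiquitous | rare)
  out <- feature_cell_matrix(m$values[keep, , drop = FALSE],
                             m$feature_ids[keep], m$barcodes,
                             binarized = TRUE)
  attr(out, "dropped") <- c(ubiquitous = sum(ubiquitous), rare = sum(rare))
  out
}

#' Write a matrix directory (MatrixMarket triple)
#'
#' `matrix.mtx` + `features.tsv` + `barcodes.tsv`, the standard single-cell
#' matrix exchange layout.
#'
#' @param m A `FeatureCellMatrix`.
#' @param dir Output directory (created if needed).
#' @export
write_matrix_dir <- function(m, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(m$values, file.path(dir, "matrix.mtx"))
  writeLines(m$feature_ids, file.path(dir, "features.tsv"))
  writeLines(m$barcodes, file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read a matrix directory written by [write_matrix_dir()]
#' @param dir Directory containing matrix.mtx, features.tsv, barcodes.tsv.
#' @param binarized Whether the stored matrix is binarized.
#' @return A `FeatureCellMatrix`.
#' @export
read_matrix_dir <- function(dir, binarized = FALSE) {
  v <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  # readMM returns a pattern (ngCMatrix) for binary files; force numeric
  v <- methods::as(methods::as(methods::as(v, "CsparseMatrix"),
                               "generalMatrix"), "dMatrix")
  feature_cell_matrix(v, readLines(file.path(dir, "features.tsv")),
                      readLines(file.path(dir, "barcodes.tsv")),
                      binarized = binarized)
}
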