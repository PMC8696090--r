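#' TF-IDF weighting of a binarized feature-by-cell matrix
#'
#' The term-frequency/inverse-document-frequency normalization used by
#' latent semantic indexing of single-cell epigenomic matrices:
#' `TF(i,j) = x_ij / sum_i x_ij` (per-cell column normalization) and
#' `IDF(i) = log(1 + N_cells / df_i)` with `df_i` the number of cells in
#' which feature i is detected; the output entry is their product. TF-IDF
#' down-weights features detected in most cells and equalizes per-cell
#' depth before SVD.
#'
#' @param m A binarized, prevalence-filtered `FeatureCellMatrix` with no
#'   all-zero cells (such cells must be filtered upstream; they raise an
#'   error naming the barcode).
#' @return A sparse real features x cells matrix (dgCMatrix).
#' @export
tfidf <- function(m) {
  if (!m$binarized) stop("tfidf requires a binarized matrix")
  x <- m$values
  depth <- Matrix::colSums(x)
  if (any(depth == 0))
    stop("cell(s) with zero detected features: ",
         paste(utils::head(m$barcodes[depth == 0], 5), collapse = ", "))
  df <- Matrix::rowSums(x)
  idf <- log(1 + length(m$barcodes) / df)
  idf[df == 0] <- 0
  tf <- x %*% Matrix::Diagonal(x = 1 / depth)
  out <- Matrix::Diagonal(x = idf) %*% tf
  out <- methods::as(methods::as(out, "CsparseMatrix"), "generalMatrix")
  dimnames(out) <- dimnames(m$values)
  out
}

#' Latent semantic indexing embedding (truncated SVD)
#'
#' Rank-K truncated singular value decomposition of the TF-IDF-weighted
#' matrix. The cell embedding is `V_K %*% diag(d_K)` (cells in rows). The
#' SVD sign ambiguity is fixed deterministically: each component is flipped
#' so that its largest-magnitude feature loading is positive, making
#' results reproducible across platforms.
#'
#' @param weighted Real features x cells matrix from [tfidf()].
#' @param K Number of components (default 30; `2 <= K <= min(dim)`).
#' @param depth Optional per-cell log10 detected-feature counts used to
#'   annotate components with their depth correlation (see
#'   [drop_depth_components()]).
#' @return An `LSIResult`: list with `embedding` (cells x K, rownames =
#'   barcodes), `singular_values` (non-increasing), `component_depth_corr`,
#'   `dropped_components` (empty), `feature_loadings`.
#' @export
lsi <- function(weighted, K = 30L, depth = NULL) {
  d <- dim(weighted)
  if (length(K) != 1L || K < 2L) stop("K must be an integer >= 2")
  if (K > min(d)) stop("K must not exceed min(n_features, n_cells)")
  K <- as.integer(K)
  s <- svd(as.matrix(weighted), nu = K, nv = K)
  sv <- s$d[seq_len(K)]
  u <- s$u
  v <- s$v
  for (k in seq_len(K)) {
    i <- which.max(abs(u[, k]))
    if (u[i, k] < 0) {
      u[, k] <- -u[, k]
      v[, k] <- -v[, k]
    }
  }
  emb <- v %*% diag(sv, nrow = K)
  rownames(emb) <- colnames(weighted)
  colnames(emb) <- paste0("LSI", seq_len(K))
  corr <- rep(NA_real_, K)
  if (!is.null(depth)) corr <- component_depth_correlation(emb, depth)
  structure(list(embedding = emb, singular_values = sv,
                 component_depth_corr = corr,
                 dropped_components = integer(0),
                 feature_loadings = u),
            class = "LSIResult")
}

#' @export
print.LSIResult <- function(x, ...) {
  cat("LSIResult:", nrow(x$embedding), "cells x", ncol(x$embedding),
      "components",
      if (length(x$dropped_components))
        paste0("(dropped: ", paste(x$dropped_components, collapse = ","), ")")
      else "", "\n")
  invisible(x)
}

component_depth_correlation <- function(embedding, depth) {
  if (length(depth) != nrow(embedding))
    stop("depth must have one value per cell")
  apply(embedding, 2L, function(col) {
    if (stats::sd(col) == 0 || stats::sd(depth) == 0) return(0)
    stats::cor(col, depth)
  })
}

#' Remove sequencing-depth-driven LSI components
#'
#' Components whose absolute Pearson correlation with per-cell log10
#' detected-feature counts exceeds `r_max` capture library size rather than
#' biology and are removed from the embedding before clustering.
#'
#' @param r An `LSIResult`.
#' @param depth Per-cell log10 counts (one value per embedded cell).
#' @param r_max Correlation threshold (default 0.9); `r_max = 1` drops
#'   nothing.
#' @return The `LSIResult` with offending components removed and recorded
#'   in `dropped_components` (indices refer to the original components).
#' @export
drop_depth_components <- function(r, depth, r_max = 0.9) {
  corr <- component_depth_correlation(r$embedding, depth)
  drop <- which(abs(corr) > r_max)
  orig <- seq_len(ncol(r$embedding) + length(r$dropped_components))
  remaining <- setdiff(orig, r$dropped_components)
  if (length(drop)) {
    r$embedding <- r$embedding[, -drop, drop = FALSE]
    r$singular_values <- r$singular_values[-drop]
    r$feature_loadings <- r$feature_loadings[, -drop, drop = FALSE]
    r$dropped_components <- sort(c(r$dropped_components, remaining[drop]))
    corr <- corr[-drop]
  }
  r$component_depth_corr <- corr
  r
}

#' Cluster cells on the LSI embedding
#'
#' Seeded k-means on the retained embedding components: 10 random restarts
#' drawn from a deterministic RNG stream, best total within-cluster sum of
#' squares wins (ties broken by the earliest restart). Labels are
#' canonicalized — clusters numbered 0..k-1 by decreasing size, ties by the
#' lexicographically smallest member barcode — so identical inputs and seed
#' give bitwise-identical assignments.
#'
#' @param r An `LSIResult` (post any depth filtering).
#' @param k Number of clusters (`2 <= k <= n_cells`).
#' @param seed Integer RNG seed.
#' @param restarts Number of k-means restarts (default 10).
#' @return A `ClusterAssignment`: list with `assignment` (named integer
#'   vector, barcode -> cluster id), `k`, `seed`.
#' @export
cluster_cells <- function(r, k, seed, restarts = 10L) {
  x <- r$embedding
  if (k < 2L) stop("k must be >= 2")
  if (k > nrow(x)) stop("k must not exceed the number of cells")
  if (k == nrow(x)) {
    # degenerate case: every cell its own cluster; canonical order by barcode
    assignment <- stats::setNames(order(order(rownames(x))) - 1L,
                                  rownames(x))
    return(structure(list(assignment = assignment, k = as.integer(k),
                          seed = as.integer(seed)),
                     class = "ClusterAssignment"))
  }
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  best <- NULL
  for (i in seq_len(restarts)) {
    fit <- tryCatch(
      stats::kmeans(x, centers = k, nstart = 1L, iter.max = 100L),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  if (is.null(best)) stop("k-means failed for all restarts")
  labels <- best$cluster
  names(labels) <- rownames(x)
  # canonicalize: size descending, ties by smallest member barcode
  info <- data.table::data.table(old_label = seq_len(k))
  info[, size := tabulate(labels, nbins = k)]
  info[, min_bc := vapply(old_label, function(l) {
    bcs <- names(labels)[labels == l]
    if (length(bcs)) min(bcs) else ""
  }, character(1))]
  data.table::setorder(info, -size, min_bc)
  remap <- integer(k)
  remap[info$old_label] <- seq_len(k) - 1L
  assignment <- stats::setNames(remap[labels], names(labels))
  structure(list(assignment = assignment, k = as.integer(k),
                 seed = as.integer(seed)),
            class = "ClusterAssignment")
}

#' @export
print.ClusterAssignment <- function(x, ...) {
  cat("ClusterAssignment:", length(x$assignment), "cells in", x$k,
      "clusters (sizes:",
      paste(tabulate(x$assignment + 1L, nbins = x$k), collapse = ","),
      ")\n")
  invisible(x)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between a clustering and reference labels,
#' from the contingency table: 1 for identical partitions (up to label
#' permutation), approximately 0 for independent ones.
#'
#' @param a A `ClusterAssignment` or named label vector.
#' @param truth Named label vector over the same barcodes.
#' @return ARI in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(a, truth) {
  if (inherits(a, "ClusterAssignment")) a <- a$assignment
  if (is.null(names(a)) || is.null(names(truth)))
    stop("both partitions must be named by barcode")
  if (!setequal(names(a), names(truth)))
    stop("partitions are over different barcode sets")
  truth <- truth[names(a)]
  tab <- table(a, truth)
  comb2 <- function(n) n * (n - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(0)
  (sum_ij - expected) / (max_index - expected)
}
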