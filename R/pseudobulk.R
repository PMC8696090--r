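#' Pseudo-bulk aggregation of clustered cells
#'
#' Partitions a fragment collection by cluster membership: each cluster's
#' cells are merged into one `PseudoBulk` that can then be treated as a
#' bulk sample for track generation and stringent peak calling. The
#' partition is exact — cluster fragment counts sum to the input total.
#'
#' @param fragments A `FragmentCollection` restricted to the assigned cells.
#' @param assignment A `ClusterAssignment`; every assigned barcode must
#'   have fragments.
#' @return List of `PseudoBulk` objects (list with `cluster_id`,
#'   `fragments`, `n_cells`), ordered by cluster id.
#' @export
make_pseudobulks <- function(fragments, assignment) {
  if (!inherits(assignment, "ClusterAssignment"))
    stop("assignment must be a ClusterAssignment")
  present <- barcodes(fragments)
  missing_bc <- setdiff(names(assignment$assignment), present)
  if (length(missing_bc))
    stop("assigned barcode(s) with no fragments: ",
         paste(utils::head(missing_bc, 3), collapse = ", "))
  ids <- sort(unique(assignment$assignment))
  lapply(ids, function(cid) {
    bcs <- names(assignment$assignment)[assignment$assignment == cid]
    structure(list(cluster_id = cid,
                   fragments = subset_barcodes(fragments, bcs),
                   n_cells = length(bcs)),
              class = "PseudoBulk")
  })
}

#' @export
print.PseudoBulk <- function(x, ...) {
  cat("PseudoBulk cluster", x$cluster_id, ":", x$n_cells, "cells,",
      n_fragments(x$fragments), "fragments\n")
  invisible(x)
}

# Binned fragment-overlap counts for one fragment set; raw counts with the
# count column expanded.
binned_coverage <- function(fragments, genome, bin_size) {
  bins <- make_bins(genome, bin_size)$features
  value <- numeric(nrow(bins))
  hits <- GenomicRanges::findOverlaps(intervals_granges(bins),
                                      frag_granges(fragments))
  if (length(hits)) {
    agg <- data.table::data.table(
      bin = S4Vectors::queryHits(hits),
      n = fragments$records$count[S4Vectors::subjectHits(hits)])[
        , list(n = sum(n)), by = bin]
    value[agg$bin] <- agg$n
  }
  data.table::data.table(chrom = bins$chrom, start = bins$start,
                         end = bins$end, value = value)
}

#' Pseudo-bulk signal track
#'
#' Binned fragment-overlap counts for one pseudo-bulk, raw or
#' counts-per-million normalized (`value * 1e6 / total fragments`; the
#' default, making clusters of different depths visually comparable).
#'
#' @param pb A `PseudoBulk`.
#' @param genome A `GenomeSpec` (defaults to the fragments' genome).
#' @param bin_size Track bin width in bp (default 200).
#' @param normalize `"cpm"` (default) or `"raw"`.
#' @return A `Track` labelled `cluster<id>`.
#' @export
pseudobulk_track <- function(pb, genome = NULL, bin_size = 200L,
                             normalize = c("cpm", "raw")) {
  normalize <- match.arg(normalize)
  if (is.null(genome)) genome <- pb$fragments$genome
  total <- n_fragments(pb$fragments)
  if (total == 0L) stop("empty pseudobulk")
  bins <- binned_coverage(pb$fragments, genome, bin_size)
  if (normalize == "cpm") bins[, value := value * 1e6 / total]
  track(bins, label = paste0("cluster", pb$cluster_id))
}

#' Per-cell signal tracks grouped by cluster
#'
#' One raw-count `Track` per barcode. When `dir` is given, each track is
#' written to `dir/cluster<id>/<barcode>.bedgraph`. Cells with no
#' fragments are skipped with a warning.
#'
#' @param fragments A `FragmentCollection`.
#' @param assignment A `ClusterAssignment` over (a superset of) the
#'   barcodes.
#' @param genome A `GenomeSpec` (defaults to the fragments' genome).
#' @param bin_size Track bin width in bp.
#' @param dir Optional output directory for bedGraph files.
#' @return Nested list: per cluster id (as character), a named list of
#'   `Track`s by barcode.
#' @export
per_cell_tracks <- function(fragments, assignment, genome = NULL,
                            bin_size = 200L, dir = NULL) {
  if (is.null(genome)) genome <- fragments$genome
  out <- list()
  for (cid in sort(unique(assignment$assignment))) {
    bcs <- sort(names(assignment$assignment)[assignment$assignment == cid])
    tracks <- list()
    for (bc in bcs) {
      fc <- subset_barcodes(fragments, bc)
      if (n_fragments(fc) == 0L) {
        warning("cell ", bc, " has no fragments; skipped")
        next
      }
      tr <- track(binned_coverage(fc, genome, bin_size), label = bc)
      tracks[[bc]] <- tr
      if (!is.null(dir)) {
        cdir <- file.path(dir, paste0("cluster", cid))
        dir.create(cdir, recursive = TRUE, showWarnings = FALSE)
        write_bedgraph(tr, file.path(cdir, paste0(bc, ".bedgraph")))
      }
    }
    out[[as.character(cid)]] <- tracks
  }
  out
}

#' Stringent per-cluster peak calling
#'
#' Calls peaks on one pseudo-bulk with the stringent defaults used for
#' cluster-specific domains: q-value < 0.01 and fold change > 5 over the
#' uniform background. Delegates to [call_peaks()].
#'
#' @param pb A `PseudoBulk`.
#' @param q_max q-value cutoff (default 0.01).
#' @param min_fold Minimum fold change (default 5).
#' @param width,step,merge_gap Window-caller geometry (defaults 1000/1000/1000).
#' @return Peak-call table (see [call_peaks()]).
#' @export
cluster_peaks <- function(pb, q_max = 0.01, min_fold = 5.0,
                          width = 1000L, step = 1000L, merge_gap = 1000L) {
  wc <- aggregate_windows(pb$fragments, width = width, step = step)
  call_peaks(wc, q_max = q_max, min_fold = min_fold, merge_gap = merge_gap)
}

#' Spike-in normalization scale factor
#'
#' Signal scaling for exogenous spike-in normalization: tracks multiplied
#' by `constant / spike_fragments` are comparable across samples with
#' different spike-in recovery. Spike-genome alignment happens upstream;
#' only the counts enter here.
#'
#' @param primary_fragments Fragments aligned to the primary genome
#'   (recorded for reporting; does not enter the factor).
#' @param spike_fragments Fragments aligned to the spike-in genome (> 0).
#' @param constant Scaling constant (default 10000).
#' @return The multiplicative scale factor.
#' @export
spike_in_scale_factor <- function(primary_fragments, spike_fragments,
                                  constant = 10000) {
  if (length(spike_fragments) != 1L || !is.finite(spike_fragments) ||
      spike_fragments <= 0)
    stop("spike_fragments must be a positive count")
  constant / spike_fragments
}
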