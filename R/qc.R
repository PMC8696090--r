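#' Per-cell quality control metrics
#'
#' Computes, for every distinct barcode: total fragment count (duplicate
#' copies expanded), deduplicated count, duplicate rate, mitochondrial
#' fraction, mean and median fragment size (on deduplicated nuclear
#' fragments), and the number of qualified fragments (deduplicated nuclear).
#' Duplicates are records identical in (chrom, start, end) within a barcode
#' beyond the first occurrence. FRiP is filled in separately by
#' [compute_frip()]; the pass/fail flag by [filter_cells()].
#'
#' @param fragments A non-empty `FragmentCollection`.
#' @return A data.table, one row per barcode, columns `barcode`,
#'   `total_fragments`, `dedup_fragments`, `duplicate_rate`,
#'   `mito_fraction`, `mean_fragment_size`, `median_fragment_size`,
#'   `qualified_fragments`, `frip` (NA), `pass_qc` (NA).
#' @export
compute_cell_qc <- function(fragments) {
  dt <- fragments$records
  if (!nrow(dt)) stop("no fragments")
  mito <- fragments$genome$mito_names
  totals <- dt[, list(total_fragments = as.integer(sum(count)),
                      mito_fragments = as.integer(sum(count[chrom %in% mito]))),
               by = barcode]
  uniq <- unique(dt, by = c("chrom", "start", "end", "barcode"))
  dedup <- uniq[, list(dedup_fragments = .N), by = barcode]
  nuc <- uniq[!chrom %in% mito]
  sizes <- nuc[, list(qualified_fragments = .N,
                      mean_fragment_size = mean(end - start),
                      median_fragment_size =
                        as.numeric(stats::median(end - start))),
               by = barcode]
  qc <- merge(totals, dedup, by = "barcode", all = TRUE)
  qc <- merge(qc, sizes, by = "barcode", all = TRUE)
  qc[is.na(qualified_fragments), qualified_fragments := 0L]
  qc[, duplicate_rate := 1 - dedup_fragments / total_fragments]
  qc[, mito_fraction := mito_fragments / total_fragments]
  qc[, mito_fragments := NULL]
  qc[, frip := NA_real_]
  qc[, pass_qc := NA]
  data.table::setcolorder(qc, c("barcode", "total_fragments",
                                "dedup_fragments", "duplicate_rate",
                                "mito_fraction", "mean_fragment_size",
                                "median_fragment_size",
                                "qualified_fragments", "frip", "pass_qc"))
  data.table::setorder(qc, barcode)
  qc[]
}

#' Fraction of reads in peaks per cell
#'
#' The per-cell signal-to-noise statistic: the fraction of a cell's
#' qualified (deduplicated, nuclear) fragments that overlap at least one
#' peak by >= 1 bp. A fragment overlapping several peaks counts once. Cells
#' with zero qualified fragments get `NA` (they auto-fail [filter_cells()]).
#'
#' @param fragments A `FragmentCollection`.
#' @param peaks A non-empty `FeatureSet` (called peaks, or any feature set
#'   to measure enrichment against).
#' @return Named numeric vector, barcode -> FRiP.
#' @export
compute_frip <- function(fragments, peaks) {
  if (n_features(peaks) == 0L) stop("peak set is empty")
  qf <- qualified_fragments(fragments)
  dt <- qf$records
  all_bc <- barcodes(fragments)
  frip <- stats::setNames(rep(NA_real_, length(all_bc)), all_bc)
  if (!nrow(dt)) return(frip)
  hits <- IRanges::overlapsAny(frag_granges(qf),
                               intervals_granges(peaks$features))
  per <- dt[, list(frip = mean(hits[.I])), by = barcode]
  frip[per$barcode] <- per$frip
  frip
}

#' Apply the cell-filtering rules
#'
#' A cell is excluded iff its FRiP is strictly below `frip_min` or its
#' qualified fragment count is strictly below `min_qualified` (cells sitting
#' exactly at a threshold are kept). Cells with undefined FRiP are excluded.
#'
#' @param qc QC table from [compute_cell_qc()], with the `frip` column
#'   populated (see [compute_frip()]).
#' @param frip_min Minimum FRiP, default 0.30.
#' @param min_qualified Minimum qualified fragments, default 10000.
#' @return A list with `kept` (character vector of barcodes), `excluded`
#'   (data.table barcode/reason), and `qc` (input with `pass_qc` and
#'   `exclusion_reason` filled in).
#' @export
filter_cells <- function(qc, frip_min = 0.30, min_qualified = 10000) {
  if (!all(c("barcode", "frip", "qualified_fragments") %in% names(qc)))
    stop("qc must be a table from compute_cell_qc with frip populated")
  qc <- data.table::copy(data.table::as.data.table(qc))
  low_frip <- is.na(qc$frip) | qc$frip < frip_min
  few_frag <- qc$qualified_fragments < min_qualified
  reason <- rep(NA_character_, nrow(qc))
  reason[few_frag] <- "few qualified fragments"
  reason[low_frip] <- ifelse(few_frag[low_frip],
                             "low FRiP; few qualified fragments", "low FRiP")
  reason[is.na(qc$frip)] <- "undefined FRiP"
  qc[, pass_qc := !(low_frip | few_frag)]
  qc[, exclusion_reason := reason]
  list(kept = qc$barcode[qc$pass_qc],
       excluded = qc[pass_qc == FALSE,
                     list(barcode, reason = exclusion_reason)],
       qc = qc[])
}

#' Pooled fragment-size histogram
#'
#' Size distribution of deduplicated nuclear fragments pooled over all
#' cells, in bins of `bin_width` bp. Single-cell CUT&Tag/CUT&RUN libraries
#' for histone marks show a nucleosomal ladder here (mono-/di-/tri-
#' nucleosome modes).
#'
#' @param fragments A `FragmentCollection`.
#' @param bin_width Histogram bin width in bp (default 1).
#' @return A `FragmentSizeHistogram`: data.table (`size_bin` = bin start,
#'   `count`) plus attributes `mean` (1 decimal) and `bin_width`.
#' @export
fragment_size_histogram <- function(fragments, bin_width = 1L) {
  qf <- qualified_fragments(fragments)
  sizes <- qf$records[, end - start]
  if (!length(sizes)) stop("no nuclear fragments to build a size histogram")
  bin <- as.integer(bin_width) * (sizes %/% as.integer(bin_width))
  hist <- data.table::data.table(size_bin = bin)[
    , list(count = .N), by = size_bin]
  data.table::setorder(hist, size_bin)
  structure(hist[], mean = round(mean(sizes), 1L),
            median = stats::median(sizes), bin_width = as.integer(bin_width),
            class = c("FragmentSizeHistogram", class(hist)))
}

#' Mean of a fragment-size histogram
#' @param x A `FragmentSizeHistogram`.
#' @export
mean_fragment_size <- function(x) attr(x, "mean")

#' QC summary table
#'
#' One-row dataset-level summary: cell count, median fragments per cell,
#' median duplicate rate, median mitochondrial fraction, median FRiP, and
#' exclusion counts by reason (when [filter_cells()] has been applied).
#'
#' @param qc QC table, optionally after [filter_cells()].
#' @return A one-row data.table.
#' @export
qc_summary <- function(qc) {
  qc <- data.table::as.data.table(qc)
  if (!nrow(qc)) stop("empty QC table")
  out <- data.table::data.table(
    n_cells = nrow(qc),
    median_fragments_per_cell = stats::median(qc$total_fragments),
    median_duplicate_rate = stats::median(qc$duplicate_rate),
    median_mito_fraction = stats::median(qc$mito_fraction),
    median_frip = stats::median(qc$frip, na.rm = TRUE))
  if ("exclusion_reason" %in% names(qc)) {
    excl <- qc$exclusion_reason[!is.na(qc$exclusion_reason)]
    out[, n_excluded := length(excl)]
    out[, n_excluded_low_frip := sum(grepl("low FRiP", excl))]
    out[, n_excluded_few_fragments :=
          sum(grepl("few qualified fragments", excl))]
    out[, n_excluded_undefined_frip := sum(excl == "undefined FRiP")]
  }
  out[]
}
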