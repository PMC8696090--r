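#' Window counts of pooled fragment coverage
#'
#' Tiles the genome with fixed-width windows (sliding when `step < width`)
#' and counts, per window, the deduplicated nuclear fragments overlapping it
#' by >= 1 bp, pooled over all cells in the collection.
#'
#' @param fragments A `FragmentCollection` (typically already restricted to
#'   QC-passing cells).
#' @param width Window width in bp (default 1000).
#' @param step Window step in bp (default 1000; must be <= width).
#' @return A `WindowCounts`: list with `windows` (data.table chrom/start/end),
#'   `counts`, `width`, `step`, `total_fragments` (qualified fragments
#'   pooled), `genome`.
#' @export
aggregate_windows <- function(fragments, width = 1000L, step = 1000L) {
  if (length(width) != 1L || !is.finite(width) || width < 1)
    stop("width must be a positive integer")
  if (length(step) != 1L || !is.finite(step) || step < 1 || step > width)
    stop("step must satisfy 1 <= step <= width")
  width <- as.integer(width)
  step <- as.integer(step)
  genome <- fragments$genome
  wins <- data.table::rbindlist(lapply(genome$chrom_names, function(ch) {
    len <- genome$chrom_lengths[[ch]]
    starts <- seq.int(0L, max(0L, len - 1L), by = step)
    data.table::data.table(chrom = ch, start = starts,
                           end = pmin(starts + width, len))
  }))
  qf <- qualified_fragments(fragments)
  counts <- GenomicRanges::countOverlaps(intervals_granges(wins),
                                         frag_granges(qf))
  structure(list(windows = wins, counts = as.integer(counts),
                 width = width, step = step,
                 total_fragments = nrow(qf$records), genome = genome),
            class = "WindowCounts")
}

#' @export
print.WindowCounts <- function(x, ...) {
  cat("WindowCounts:", nrow(x$windows), "windows (width", x$width,
      "step", x$step, "),", x$total_fragments, "fragments\n")
  invisible(x)
}

#' Poisson window peak calling on pooled signal
#'
#' A fixed-width window caller for aggregate (pseudo-bulk) signal. The
#' background rate per window is uniform:
#' `lambda = total_fragments * width / effective_genome_size` (nuclear
#' bases). Each nonzero window gets an upper-tail Poisson p-value
#' `P(X >= count)`; Benjamini-Hochberg across nonzero windows yields
#' q-values. Windows with `q < q_max` and `fold >= min_fold` that lie within
#' `merge_gap` bp of each other are merged; a merged peak's count is the sum
#' of its member window counts, its background rate is rescaled to the
#' merged width, fold change and p-value are recomputed on the merged
#' interval, and its q-value is the minimum over members.
#'
#' Suited to broad histone domains (e.g. H3K27me3) at the default 1 kb
#' width; it makes no claim of reproducing MACS2 boundaries. A pre-computed
#' peak BED can be supplied to the pipeline instead (see
#' [select_features()]).
#'
#' @param wc A `WindowCounts` from [aggregate_windows()].
#' @param q_max Significance cutoff on BH q-values (default 0.01,
#'   permissive regime).
#' @param min_fold Minimum fold change over background (default 1;
#'   the stringent per-cluster regime uses 5).
#' @param merge_gap Maximum gap (bp) between significant windows merged
#'   into one peak (default 1000).
#' @return data.table of peak calls: `chrom`, `start`, `end`, `count`,
#'   `lambda_bg`, `fold_change`, `p_value`, `q_value`; sorted and
#'   non-overlapping.
#' @export
call_peaks <- function(wc, q_max = 0.01, min_fold = 1.0, merge_gap = 1000L) {
  if (!inherits(wc, "WindowCounts")) stop("wc must be a WindowCounts")
  if (wc$total_fragments <= 0L) stop("no fragments: cannot call peaks")
  egs <- effective_genome_size(wc$genome)
  lambda <- wc$total_fragments * wc$width / egs
  dt <- data.table::copy(wc$windows)
  dt[, count := wc$counts]
  nz <- dt[count > 0L]
  if (!nrow(nz)) return(empty_peaks())
  nz[, p_value := stats::ppois(count - 1L, lambda, lower.tail = FALSE)]
  nz[, q_value := stats::p.adjust(p_value, method = "BH")]
  nz[, fold_change := count / lambda]
  sig <- nz[q_value < q_max & fold_change >= min_fold]
  if (!nrow(sig)) return(empty_peaks())
  gr <- intervals_granges(sig)
  merged <- GenomicRanges::reduce(gr, min.gapwidth = merge_gap + 1L)
  hit <- GenomicRanges::findOverlaps(gr, merged)
  mem <- data.table::data.table(grp = S4Vectors::subjectHits(hit),
                                count = sig$count[S4Vectors::queryHits(hit)],
                                q = sig$q_value[S4Vectors::queryHits(hit)])
  agg <- mem[, list(count = sum(count), q_value = min(q)), by = grp]
  data.table::setorder(agg, grp)
  stopifnot(identical(agg$grp, seq_along(merged)))
  peaks <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(merged)),
    start = GenomicRanges::start(merged) - 1L,
    end = GenomicRanges::end(merged),
    count = as.integer(agg$count),
    q_value = agg$q_value)
  peaks[, lambda_bg := wc$total_fragments * (end - start) / egs]
  peaks[, fold_change := count / lambda_bg]
  peaks[, p_value := stats::ppois(count - 1L, lambda_bg, lower.tail = FALSE)]
  data.table::setcolorder(peaks, c("chrom", "start", "end", "count",
                                   "lambda_bg", "fold_change", "p_value",
                                   "q_value"))
  peaks[, chrom := factor(chrom, levels = wc$genome$chrom_names)]
  data.table::setorder(peaks, chrom, start)
  peaks[, chrom := as.character(chrom)]
  peaks[]
}

empty_peaks <- function() {
  data.table::data.table(chrom = character(), start = integer(),
                         end = integer(), count = integer(),
                         lambda_bg = numeric(), fold_change = numeric(),
                         p_value = numeric(), q_value = numeric())
}

#' Select features for the feature-by-cell matrix
#'
#' The three feature-selection modes: `"peaks"` calls peaks on the pooled
#' cells ([aggregate_windows()] + [call_peaks()] with permissive settings,
#' or reads a pre-computed peak BED when `bed_path` is given); `"bins"`
#' tiles the genome ([make_bins()], default 5000 bp); `"custom"` reads a
#' user BED of functional elements ([read_features()]).
#'
#' @param mode `"peaks"`, `"bins"` or `"custom"`.
#' @param fragments `FragmentCollection` (required for `"peaks"`).
#' @param genome `GenomeSpec` (defaults to the collection's genome).
#' @param bin_size Bin width for `"bins"` (default 5000).
#' @param bed_path BED path: required for `"custom"`; for `"peaks"` it
#'   supplies pre-computed peaks instead of the internal caller.
#' @param width,step,merge_gap,q_max,min_fold Internal peak-caller settings
#'   for `"peaks"` mode.
#' @return A `FeatureSet` with the corresponding mode.
#' @export
select_features <- function(mode = c("peaks", "bins", "custom"),
                            fragments = NULL, genome = NULL,
                            bin_size = 5000L, bed_path = NULL,
                            width = 1000L, step = 1000L, merge_gap = 1000L,
                            q_max = 0.01, min_fold = 1.0) {
  mode <- match.arg(mode)
  if (is.null(genome) && !is.null(fragments)) genome <- fragments$genome
  if (is.null(genome)) stop("a genome (or fragments) is required")
  switch(mode,
    bins = make_bins(genome, bin_size),
    custom = {
      if (is.null(bed_path)) stop("mode 'custom' requires a BED path")
      read_features(bed_path, genome)
    },
    peaks = {
      if (!is.null(bed_path)) {
        fs <- read_features(bed_path, genome)
        feature_set(fs$features, mode = "peaks", genome = genome)
      } else {
        if (is.null(fragments)) stop("mode 'peaks' requires fragments")
        wc <- aggregate_windows(fragments, width = width, step = step)
        pk <- call_peaks(wc, q_max = q_max, min_fold = min_fold,
                         merge_gap = merge_gap)
        if (!nrow(pk)) stop("no peaks called; cannot build peak features")
        peaks_to_features(pk, genome)
      }
    })
}

#' Convert peak calls to a FeatureSet
#' @param peaks Peak-call table from [call_peaks()].
#' @param genome A `GenomeSpec`.
#' @export
peaks_to_features <- function(peaks, genome) {
  feature_set(peaks[, list(chrom, start, end)], mode = "peaks",
              genome = genome, validate = FALSE)
}

#' Number of peaks in `a` overlapping any peak in `b`
#'
#' Each peak of `a` is counted once however many peaks of `b` it touches
#' (>= 1 bp overlap).
#'
#' @param a,b Peak-call tables (or any interval tables with
#'   chrom/start/end).
#' @return Integer count.
#' @export
count_overlapping_peaks <- function(a, b) {
  if (!nrow(a) || !nrow(b)) return(0L)
  sum(IRanges::overlapsAny(intervals_granges(a), intervals_granges(b)))
}

#' Fraction of peaks proximal to transcription start sites
#'
#' A peak is proximal when its midpoint lies within `d` bp of a TSS
#' position (the start coordinate of the TSS BED interval; strand-unaware).
#'
#' @param peaks Non-empty peak-call table.
#' @param tss A non-empty `FeatureSet` of TSS positions.
#' @param d Distance threshold in bp (default 2000).
#' @return Fraction in `[0, 1]`.
#' @export
tss_proximal_fraction <- function(peaks, tss, d = 2000L) {
  if (!nrow(peaks)) stop("empty peak list")
  if (n_features(tss) == 0L) stop("empty TSS set")
  mid <- (peaks$start + peaks$end) %/% 2L
  mid_dt <- data.table::data.table(chrom = peaks$chrom, start = mid,
                                   end = mid + 1L)
  tss_dt <- tss$features
  win <- data.table::data.table(chrom = tss_dt$chrom,
                                start = pmax(0L, tss_dt$start - as.integer(d)),
                                end = tss_dt$start + as.integer(d) + 1L)
  mean(IRanges::overlapsAny(intervals_granges(mid_dt),
                            intervals_granges(win)))
}

#' Write peak calls as BED6+
#'
#' Columns: chrom, start, end, id, score (`round(-10*log10(q))`, capped at
#' 1000), strand ".", then count, fold_change, p_value, q_value.
#'
#' @param peaks Peak-call table.
#' @param path Output path.
#' @export
write_peaks <- function(peaks, path) {
  out <- data.table::data.table(
    chrom = peaks$chrom, start = peaks$start, end = peaks$end,
    name = sprintf("peak_%d", seq_len(nrow(peaks))),
    score = pmin(1000L, as.integer(round(-10 * log10(pmax(
      peaks$q_value, 1e-100))))),
    strand = ".",
    count = peaks$count, fold_change = peaks$fold_change,
    p_value = peaks$p_value, q_value = peaks$q_value)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
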