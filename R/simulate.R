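#' Simulation configuration
#'
#' Describes a synthetic single-cell CUT&Tag/CUT&RUN experiment: a small
#' genome, a set of planted peak domains per cell type (partially shared
#' between types), and per-fragment sampling rules. Defaults emulate the
#' regime of a two-cell-type broad-histone-mark experiment: per-cell
#' signal fraction 0.45 (within the 28-68% FRiP range typical of good
#' single-cell CUT&Tag libraries), a tri-modal nucleosomal fragment-size
#' mixture with analytic mean 238 bp, duplicate and mitochondrial rates
#' below 1%.
#'
#' @param genome `GenomeSpec`; default one 5 Mb synthetic chromosome plus
#'   a 16 kb mitochondrial contig.
#' @param n_cell_types Number of cell types (default 2).
#' @param cells_per_type Cells per type (default 100).
#' @param fragments_per_cell Fragments drawn per cell (single number, or a
#'   vector recycled over cells; default 2000).
#' @param peaks_per_type Peaks per cell type (default 100).
#' @param shared_peak_fraction Fraction of each type's peaks shared by all
#'   types (default 0.5).
#' @param peak_width Planted peak width in bp (default 2000).
#' @param min_peak_gap Minimum gap between planted peaks in bp (default
#'   5000), so distinct domains stay resolvable by a window caller.
#' @param signal_fraction Probability that a fragment's midpoint is placed
#'   inside one of its cell's peaks (default 0.45); the rest fall uniformly
#'   on the nuclear background.
#' @param size_mixture data.frame with columns `weight`, `mean`, `sd`:
#'   Gaussian mixture of fragment sizes, truncated to `[30, 1500]` bp;
#'   default `0.70 N(170,30) + 0.20 N(340,45) + 0.10 N(510,70)`
#'   (mono/di/tri-nucleosome, analytic mean 238 bp).
#' @param duplicate_rate Probability that an emitted fragment is an exact
#'   copy of an earlier fragment of the same cell (default 0.005).
#' @param mito_fraction Probability that a fragment lands on the
#'   mitochondrial contig instead (default 0.005).
#' @param seed Integer seed; the single source of randomness.
#' @return A `SimulationConfig`.
#' @export
simulation_config <- function(
    genome = genome_spec(c("chrS", "chrM"), c(5e6, 16000),
                         mito_names = "chrM"),
    n_cell_types = 2L, cells_per_type = 100L, fragments_per_cell = 2000L,
    peaks_per_type = 100L, shared_peak_fraction = 0.5, peak_width = 2000L,
    min_peak_gap = 5000L, signal_fraction = 0.45,
    size_mixture = data.frame(weight = c(0.70, 0.20, 0.10),
                              mean = c(170, 340, 510),
                              sd = c(30, 45, 70)),
    duplicate_rate = 0.005, mito_fraction = 0.005, seed = 1L) {
  cfg <- structure(
    list(genome = genome, n_cell_types = as.integer(n_cell_types),
         cells_per_type = as.integer(cells_per_type),
         fragments_per_cell = as.integer(fragments_per_cell),
         peaks_per_type = as.integer(peaks_per_type),
         shared_peak_fraction = shared_peak_fraction,
         peak_width = as.integer(peak_width),
         min_peak_gap = as.integer(min_peak_gap),
         signal_fraction = signal_fraction,
         size_mixture = as.data.frame(size_mixture),
         duplicate_rate = duplicate_rate, mito_fraction = mito_fraction,
         seed = as.integer(seed)),
    class = "SimulationConfig")
  validate_simulation_config(cfg)
  cfg
}

validate_simulation_config <- function(cfg) {
  if (!is_genome_spec(cfg$genome)) stop("genome must be a GenomeSpec")
  if (abs(sum(cfg$size_mixture$weight) - 1) > 1e-8)
    stop("size mixture weights must sum to 1")
  for (f in c("shared_peak_fraction", "signal_fraction", "duplicate_rate",
              "mito_fraction")) {
    v <- cfg[[f]]
    if (length(v) != 1L || !is.finite(v) || v < 0 || v > 1)
      stop(f, " must lie in [0, 1]")
  }
  if (cfg$n_cell_types < 1L || cfg$cells_per_type < 1L ||
      cfg$peaks_per_type < 1L || cfg$peak_width < 1L)
    stop("counts and widths must be positive")
  if (cfg$mito_fraction > 0 &&
      !any(cfg$genome$mito_names %in% cfg$genome$chrom_names))
    stop("mito_fraction > 0 requires a mitochondrial chromosome")
  invisible(cfg)
}

#' Analytic mean of the configured fragment-size mixture
#' @param cfg A `SimulationConfig`.
#' @return Mixture mean in bp (ignoring the [30, 1500] truncation, whose
#'   effect is negligible for the default components).
#' @export
size_mixture_mean <- function(cfg) {
  with(cfg$size_mixture, sum(weight * mean))
}

#' Expected FRiP against the planted truth peaks
#'
#' Closed-form expectation of per-cell FRiP measured with the >= 1 bp
#' overlap rule against a cell's own type's peaks: a signal fragment always
#' overlaps its peak, and a background fragment overlaps some peak when its
#' midpoint falls within half a fragment length of one, giving
#' `s + (1 - s) * sum(peak_width + E[size]) / nuclear_bases`.
#'
#' @param cfg A `SimulationConfig`.
#' @return Expected FRiP for one cell.
#' @export
expected_frip <- function(cfg) {
  nuclear <- effective_genome_size(cfg$genome)
  # peaks visible to one cell: shared + its own specific = peaks_per_type;
  # mito fragments are excluded from FRiP's denominator, so condition on
  # nuclear placement
  reach <- cfg$peaks_per_type * (cfg$peak_width + size_mixture_mean(cfg))
  s <- cfg$signal_fraction
  s + (1 - s) * reach / nuclear
}

# Place n non-overlapping peaks of width w with pairwise gaps >= g on the
# nuclear chromosomes, proportionally to chromosome length.
place_peaks <- function(genome, n, w, g) {
  chroms <- nuclear_chroms(genome)
  lens <- genome$chrom_lengths[chroms]
  alloc <- floor(n * lens / sum(lens))
  rem <- n - sum(alloc)
  if (rem > 0) {
    extra <- order(n * lens / sum(lens) - alloc, decreasing = TRUE)
    alloc[extra[seq_len(rem)]] <- alloc[extra[seq_len(rem)]] + 1L
  }
  pieces <- lapply(seq_along(chroms), function(ci) {
    ni <- alloc[ci]
    if (ni == 0L) return(NULL)
    len <- lens[ci]
    slack <- len - ni * w - (ni + 1) * g
    if (slack < 0)
      stop("cannot place ", ni, " peaks of width ", w, " with gap ", g,
           " on a ", len, " bp chromosome")
    u <- sort(stats::runif(ni, 0, slack))
    starts <- floor(u) + seq_len(ni) * g + (seq_len(ni) - 1L) * w
    data.table::data.table(chrom = chroms[ci], start = as.integer(starts),
                           end = as.integer(starts + w))
  })
  data.table::rbindlist(pieces)
}

#' Simulate a single-cell fragment dataset with ground truth
#'
#' Generates barcode-tagged fragments for `n_cell_types * cells_per_type`
#' cells. Each cell type owns `peaks_per_type` planted peak domains, of
#' which a `shared_peak_fraction` are common to all types. Per fragment:
#' with probability `mito_fraction` it is placed uniformly on the
#' mitochondrial contig; otherwise with probability `signal_fraction` its
#' midpoint is uniform inside a uniformly chosen peak of the cell's type,
#' else uniform on the nuclear background. Fragment sizes follow the
#' truncated nucleosomal Gaussian mixture. Finally, with probability
#' `duplicate_rate` an emitted fragment is replaced by an exact copy of an
#' earlier fragment of the same cell. All randomness derives from
#' `cfg$seed`; the same configuration reproduces the dataset bitwise.
#'
#' @param cfg A `SimulationConfig`.
#' @return List with `fragments` (a `FragmentCollection`) and `truth` (a
#'   `TruthManifest`: `cells` table barcode/cell_type, `peaks` table with
#'   per-type and shared flags, `signal_fraction`, `config`).
#' @export
simulate_dataset <- function(cfg) {
  validate_simulation_config(cfg)
  with_local_seed(cfg$seed, {
    g <- cfg$genome
    n_types <- cfg$n_cell_types
    n_shared <- as.integer(round(cfg$shared_peak_fraction *
                                   cfg$peaks_per_type))
    n_specific <- cfg$peaks_per_type - n_shared
    n_peaks <- n_shared + n_types * n_specific
    peaks <- place_peaks(g, n_peaks, cfg$peak_width, cfg$min_peak_gap)
    role <- sample(c(rep(0L, n_shared),
                     rep(seq_len(n_types), each = n_specific)))
    peaks[, peak_id := sprintf("peak_%04d", seq_len(n_peaks))]
    peaks[, shared := role == 0L]
    peaks[, cell_types := ifelse(role == 0L,
                                 paste(seq_len(n_types), collapse = ","),
                                 as.character(role))]
    type_peak_idx <- lapply(seq_len(n_types), function(t)
      which(role == 0L | role == t))

    n_cells <- n_types * cfg$cells_per_type
    cell_type <- rep(seq_len(n_types), each = cfg$cells_per_type)
    bc <- sprintf("T%d_C%04d", cell_type,
                  rep(seq_len(cfg$cells_per_type), times = n_types))
    fpc <- rep_len(cfg$fragments_per_cell, n_cells)
    n <- sum(fpc)
    frag_cell <- rep.int(seq_len(n_cells), fpc)
    within_idx <- sequence(fpc)

    is_mito <- stats::runif(n) < cfg$mito_fraction
    is_signal <- !is_mito & stats::runif(n) < cfg$signal_fraction

    # sizes: truncated mixture, rejection sampling
    sizes <- numeric(n)
    todo <- seq_len(n)
    while (length(todo)) {
      comp <- sample.int(nrow(cfg$size_mixture), length(todo),
                         replace = TRUE, prob = cfg$size_mixture$weight)
      draw <- stats::rnorm(length(todo), cfg$size_mixture$mean[comp],
                           cfg$size_mixture$sd[comp])
      ok <- draw >= 30 & draw <= 1500
      sizes[todo[ok]] <- draw[ok]
      todo <- todo[!ok]
    }
    sizes <- as.integer(round(sizes))

    mid <- integer(n)
    chrom <- character(n)
    # mitochondrial placement
    if (any(is_mito)) {
      mchr <- intersect(g$mito_names, g$chrom_names)[1L]
      chrom[is_mito] <- mchr
      mid[is_mito] <- as.integer(floor(
        stats::runif(sum(is_mito), 0, g$chrom_lengths[[mchr]])))
    }
    # signal placement: uniform peak of the cell's type, midpoint uniform
    if (any(is_signal)) {
      tt <- cell_type[frag_cell[is_signal]]
      pick_u <- stats::runif(sum(is_signal))
      n_type_peaks <- lengths(type_peak_idx)[tt]
      pk_local <- as.integer(floor(pick_u * n_type_peaks)) + 1L
      idx_mat <- vapply(type_peak_idx, identity,
                        integer(cfg$peaks_per_type))
      pk <- idx_mat[cbind(pk_local, tt)]
      chrom[is_signal] <- peaks$chrom[pk]
      mid[is_signal] <- peaks$start[pk] + as.integer(floor(
        stats::runif(sum(is_signal)) * (peaks$end[pk] - peaks$start[pk])))
    }
    # background placement: uniform over concatenated nuclear bases
    bg <- !is_mito & !is_signal
    if (any(bg)) {
      chroms <- nuclear_chroms(g)
      lens <- g$chrom_lengths[chroms]
      offs <- cumsum(c(0, lens))
      pos <- floor(stats::runif(sum(bg), 0, sum(lens)))
      ci <- findInterval(pos, offs, rightmost.closed = FALSE)
      chrom[bg] <- chroms[ci]
      mid[bg] <- as.integer(pos - offs[ci])
    }

    len <- g$chrom_lengths[chrom]
    start <- pmax(0L, pmin(mid - sizes %/% 2L, as.integer(len - sizes)))
    end <- start + sizes

    # duplicates: replace flagged fragments by a copy of an earlier
    # fragment of the same cell
    dup <- stats::runif(n) < cfg$duplicate_rate & within_idx > 1L
    if (any(dup)) {
      src_u <- stats::runif(n)
      offsets <- cumsum(c(0L, fpc))
      for (i in which(dup)) {
        j <- offsets[frag_cell[i]] +
          as.integer(floor(src_u[i] * (within_idx[i] - 1L))) + 1L
        chrom[i] <- chrom[j]
        start[i] <- start[j]
        end[i] <- end[j]
      }
    }

    records <- data.table::data.table(
      chrom = chrom, start = start, end = end, barcode = bc[frag_cell],
      count = 1L)
    fragments <- fragment_collection(records, g, validate = FALSE)
    truth <- structure(
      list(cells = data.table::data.table(barcode = bc,
                                          cell_type = cell_type),
           peaks = peaks[], signal_fraction = cfg$signal_fraction,
           config = cfg),
      class = "TruthManifest")
    list(fragments = fragments, truth = truth)
  })
}

#' @export
print.TruthManifest <- function(x, ...) {
  cat("TruthManifest:", nrow(x$cells), "cells,", nrow(x$peaks),
      "planted peaks (", sum(x$peaks$shared), "shared )\n")
  invisible(x)
}

#' Truth peaks visible to one cell type
#' @param truth A `TruthManifest`.
#' @param type Cell-type index.
#' @return data.table of that type's peaks (shared + specific).
#' @export
truth_peaks_for_type <- function(truth, type) {
  truth$peaks[shared == TRUE |
                vapply(strsplit(cell_types, ","),
                       function(v) as.character(type) %in% v, logical(1))]
}

#' Write a truth manifest to disk
#'
#' `truth_cells.tsv` (barcode, cell_type) and `truth_peaks.bed`
#' (chrom, start, end, peak_id, cell_types, shared). Round-trip readable
#' with [read_truth()].
#'
#' @param truth A `TruthManifest`.
#' @param dir Output directory (created if needed).
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(truth$cells, file.path(dir, "truth_cells.tsv"),
                     sep = "\t")
  data.table::fwrite(
    truth$peaks[, list(chrom, start, end, peak_id, cell_types, shared)],
    file.path(dir, "truth_peaks.bed"), sep = "\t", col.names = FALSE)
  invisible(dir)
}

#' Read a truth manifest written by [write_truth()]
#' @param dir Directory with truth_cells.tsv and truth_peaks.bed.
#' @return A `TruthManifest` (without the generating config).
#' @export
read_truth <- function(dir) {
  cells <- data.table::fread(file.path(dir, "truth_cells.tsv"))
  pk <- data.table::fread(file.path(dir, "truth_peaks.bed"), header = FALSE,
                          col.names = c("chrom", "start", "end", "peak_id",
                                        "cell_types", "shared"),
                          colClasses = list(character = c(1, 5)))
  pk[, shared := as.logical(shared)]
  structure(list(cells = cells, peaks = pk, signal_fraction = NA_real_,
                 config = NULL),
            class = "TruthManifest")
}
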