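---
title: "Methods: single-cell CUT&RUN/CUT&Tag fragment analysis with sccut"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-cell CUT&RUN/CUT&Tag fragment analysis with sccut}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sccut)
```

# Scope and model

`sccut` analyses single-cell CUT&RUN/CUT&Tag experiments starting from
*fragment files*: barcode-tagged genomic intervals in 0-based half-open
(BED) coordinates, one row per sequenced fragment. Everything upstream —
trimming, alignment, barcode demultiplexing, mate pairing — is assumed
done. The pipeline covers:

1. per-cell quality control and cell filtering,
2. aggregate (pooled) peak calling and feature selection,
3. binarized feature-by-cell matrix construction,
4. latent semantic indexing (LSI) embedding and k-means clustering,
5. pseudo-bulk aggregation: browser tracks and per-cluster peaks,
6. a seeded simulator providing ground truth for all of the above.

Two recurring conventions:

* **Overlap rule.** Two half-open intervals overlap iff they share at
  least one base: `start1 < end2 && start2 < end1`. Every counting
  operation (FRiP, window counts, matrix entries, track bins) uses this
  rule, so a fragment abutting a feature end-to-start does not count.
* **Qualified fragments.** QC statistics and all downstream counting use
  each cell's *qualified* fragments: deduplicated (unique on chromosome,
  start, end, barcode) and nuclear (non-mitochondrial).

# Per-cell quality control

`compute_cell_qc()` reports, per barcode: total fragments (duplicate
copies expanded), deduplicated fragments, duplicate rate, mitochondrial
fraction, mean and median fragment size (on deduplicated nuclear
fragments), and the number of qualified fragments. `compute_frip()` adds
FRiP — the fraction of a cell's qualified fragments overlapping the
selected features — the per-cell signal-to-noise statistic.

`filter_cells()` excludes a cell iff `FRiP < frip_min` **or**
`qualified < min_qualified`, with *strict* inequalities: a cell exactly
at a threshold is kept. Defaults are `frip_min = 0.30` and
`min_qualified = 10000`, calibrated to experiment-scale libraries
(~10^5 reads/cell). For shallower data — including the simulator's
default 2,000 fragments/cell — `min_qualified` must be scaled to the
depth; the examples below use 1,000. Cells whose FRiP is undefined
(zero qualified fragments) are excluded with their own reason.

# Poisson sliding-window peak calling

The aggregate caller (`aggregate_windows()` + `call_peaks()`) replaces
an external caller with a transparent fixed-width window scan suited to
broad marks:

* Tile nuclear chromosomes with `width = 1000` bp windows at
  `step = 1000` (non-overlapping by default).
* Background model: fragments fall uniformly on the nuclear genome, so
  a window's count is Poisson with
  `lambda = total_qualified * width / effective_genome_size`, where the
  effective genome size excludes mitochondrial contigs.
* Per window, the upper-tail p-value `P(X >= count)` is
  `ppois(count - 1, lambda, lower.tail = FALSE)`; fold change is
  `count / lambda`.
* Benjamini–Hochberg correction is applied over windows with nonzero
  counts (empty windows can never be significant and would only dilute
  the correction).
* Windows with `q < q_max` and `fold >= min_fold` are kept and merged
  when separated by at most `merge_gap` (default 1000) bp. A merged
  peak's count is the sum over member windows, its lambda is rescaled to
  the merged width, p and fold are recomputed, and its q-value is the
  minimum member q.

Two regimes mirror common practice for broad histone marks: a
*permissive* feature-selection call (`q < 0.01`, `fold >= 1`) and a
*stringent* per-cluster call (`q < 0.01`, `fold > 5`).

```{r peakdemo}
sim <- simulate_dataset(simulation_config(
  n_cell_types = 1, cells_per_type = 20, fragments_per_cell = 1500,
  peaks_per_type = 25, shared_peak_fraction = 0, seed = 42))
pk <- call_peaks(aggregate_windows(sim$fragments), q_max = 0.01)
nrow(pk)  # planted 25 peaks
```

# Features and the binarized matrix

`select_features()` offers three modes: `peaks` (the permissive pooled
call, or a pre-computed BED), `bins` (genome-wide tiles, default 5000
bp), and `custom` (user-supplied elements). `build_matrix()` counts
qualified fragments per feature and cell into a sparse matrix, which is
then binarized — for sparse single-cell epigenomic data, presence/absence
is the robust signal. `filter_features_by_prevalence()` drops features
detected in more than 80% of cells (ubiquitous, uninformative) or fewer
than 0.1% (noise), again with strict inequalities so a feature exactly
at a boundary is kept.

# LSI embedding and clustering

`tfidf()` applies the term-frequency/inverse-document-frequency
weighting standard in single-cell chromatin analysis: columns (cells)
are normalized to unit sum, and feature `i` is scaled by
`log(1 + n_cells / df_i)` with `df_i` its detection count.

`lsi()` computes a rank-`K` truncated SVD (default `K = 30`) of the
weighted matrix and embeds cells as `V_K diag(d_K)`. Numerical choices:

* The SVD is computed densely via base R's LAPACK interface. Matrices at
  this pipeline's scale (10^4–10^5 features by 10^2–10^4 cells) fit in
  memory, and the dense factorization is deterministic — no iterative
  solver tolerances enter the results.
* The SVD sign ambiguity is fixed by flipping each component so its
  largest-magnitude feature loading is positive, making embeddings
  reproducible across platforms.
* Components whose absolute Pearson correlation with per-cell log10
  detected-feature counts exceeds 0.9 track sequencing depth rather than
  biology; `drop_depth_components()` removes them before clustering.

`cluster_cells()` runs k-means with 10 restarts drawn from a seeded RNG
stream, keeping the solution with the lowest total within-cluster sum of
squares. Labels are canonicalized (0..k-1 by decreasing cluster size,
ties by smallest member barcode) so a fixed seed yields bitwise-identical
outputs. `adjusted_rand_index()` scores recovery against known labels.

# Pseudo-bulk aggregation

`make_pseudobulks()` partitions fragments by cluster; the partition is
exactly conservative (every fragment appears in exactly one pseudo-bulk).
`pseudobulk_track()` writes binned bedGraph tracks (default 200 bp bins),
raw or counts-per-million normalized; zero bins are omitted from the
files. `cluster_peaks()` applies the stringent caller per cluster, and
`count_overlapping_peaks()` and `tss_proximal_fraction()` (peak midpoint
within `d` of a TSS) annotate the results. `spike_in_scale_factor()`
returns `constant / spike_fragments` for exogenous-genome normalization.

# The simulator

`simulate_dataset()` generates a synthetic experiment whose defaults
*are* the study conditions used throughout the package's tests: 2 cell
types × 100 cells, 2,000 fragments/cell, 100 peaks/type of width 2,000
bp with 50% shared between types, on a 5 Mb chromosome plus a 16 kb
mitochondrial contig. Per fragment: with probability `mito_fraction`
(0.005) it lands uniformly on the mitochondrial contig; otherwise with
probability `signal_fraction` (0.45) its midpoint falls uniformly inside
one of its cell type's peaks, else uniformly on the nuclear background.
Sizes follow a truncated tri-modal Gaussian mixture
`0.70 N(170,30) + 0.20 N(340,45) + 0.10 N(510,70)` (mono-, di-,
tri-nucleosome; analytic mean 238.0 bp; truncated to [30, 1500] bp by
rejection). With probability `duplicate_rate` (0.005) a fragment is
replaced by a copy of an earlier fragment of the same cell. A
`TruthManifest` records the cell-type labels and planted peaks.

Design notes:

* Planted peaks keep a minimum gap of 5,000 bp — larger than
  `merge_gap + 2 * window width` — so distinct planted domains remain
  resolvable by the window caller rather than merging into one called
  peak.
* The expected FRiP against the planted truth peaks has the closed form
  `s + (1 - s) * n_peaks * (peak_width + E[size]) / nuclear_bases`,
  accounting for background fragments that graze a peak under the >= 1 bp
  overlap rule; `expected_frip()` computes it and the test suite checks
  the simulator against it.

```{r simdemo}
cfg <- simulation_config()
size_mixture_mean(cfg)
expected_frip(cfg)
```

All randomness flows from the single `seed` argument, and the global RNG
state is saved and restored around every draw, so a given configuration
is bitwise reproducible and does not perturb the caller's RNG stream.

**Scope.** The simulator models fragment placement, sizes, duplicates
and mitochondrial contamination. It does not model doublets, batch
effects, copy-number variation, mappability, GC bias, or antibody
efficiency differences; conclusions about those phenomena cannot be
drawn from it.

# End-to-end run

```{r pipeline}
sim <- simulate_dataset(simulation_config(seed = 7))
res <- run_all(list(
  feature_mode = "peaks",
  qc = list(min_qualified = 1000),   # scaled to 2000 fragments/cell
  cluster = list(k = 2, seed = 11)),
  fragments = sim$fragments, out_dir = tempfile("vignette_run_"))
truth <- setNames(sim$truth$cells$cell_type, sim$truth$cells$barcode)
adjusted_rand_index(res$clusters, truth[names(res$clusters$assignment)])
res$summary
```

A command-line interface with the same stages (`simulate`, `qc`,
`peaks`, `matrix`, `cluster`, `tracks`, `run-all`) is installed at
`system.file("cli", "sccut.R", package = "sccut")`; it reads YAML
configurations, writes every stage's output to files so stages can be
re-run individually, and exits 0 on success, 2 on configuration errors
and 3 on data errors.

# Limitations

* The Poisson background is uniform; it has no local lambda correction,
  so regions of genuinely elevated background (e.g. copy-number gains)
  can yield false peaks on real data.
* Window width 1,000 bp targets broad marks; narrow factor binding would
  warrant smaller windows.
* k-means requires a user-chosen `k` and spherical-ish clusters in LSI
  space; no automatic model selection is provided.
* The dense SVD is deliberate at this scale but would need an iterative
  truncated solver for matrices that no longer fit in memory.
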