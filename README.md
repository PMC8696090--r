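# sccut

End-to-end analysis of **single-cell CUT&RUN / CUT&Tag** experiments in
R, starting from barcode-tagged fragment files.

CUT&RUN and CUT&Tag profile protein–DNA occupancy (e.g. histone
modifications such as H3K27me3) by antibody-targeted in-situ cleavage or
tagmentation. At single-cell resolution each sequenced fragment carries a
cell barcode, and the analytical challenge is to turn a sparse pile of
per-cell intervals — often only a few thousand fragments per cell — into
quality-filtered cells, a feature-by-cell matrix, a low-dimensional
embedding, cell clusters, and cluster-level ("pseudo-bulk") signal
tracks and peak sets.

`sccut` implements that workflow as composable functions plus a single
`run_all()` orchestrator:

* **Per-cell QC** — duplicate rate, mitochondrial fraction,
  fragment-size distribution, and FRiP (fraction of reads in peaks, the
  per-cell signal-to-noise statistic). Cells are excluded iff
  FRiP < 0.30 or qualified (deduplicated nuclear) fragments < a depth
  threshold, with strict inequalities.
* **Peak calling** — a transparent Poisson sliding-window caller on the
  pooled fragments (uniform-background model, Benjamini–Hochberg FDR
  over nonzero windows, window merging), with a permissive regime for
  feature selection and a stringent one (fold > 5) for per-cluster
  peaks.
* **Features and matrix** — called peaks, genome-wide bins, or custom
  BED elements; sparse fragment counting; binarization; prevalence
  filtering (drop features in > 80% or < 0.1% of cells).
* **Embedding and clustering** — TF-IDF weighting, latent semantic
  indexing via deterministic truncated SVD, removal of depth-correlated
  components, seeded k-means with canonicalized labels, and an adjusted
  Rand index for benchmarking.
* **Pseudo-bulk outputs** — count-conserving aggregation by cluster,
  CPM-normalized bedGraph tracks, stringent per-cluster peaks, peak
  overlap and TSS-proximity annotation, spike-in scale factors.
* **A seeded simulator** — synthetic experiments with known cell types
  and planted peak domains (ground-truth manifests), making every stage
  testable without external data.

All coordinates are 0-based half-open (BED convention); all overlap
counting uses the ≥ 1 bp rule. See the vignette
(`vignettes/single-cell-chromatin-profiling.Rmd`) for the full methods
description.

## Worked example

Simulate a two-cell-type experiment under the package's default study
conditions (2 × 100 cells, 2,000 fragments/cell, 100 peaks of 2 kb per
type with 50% shared, signal fraction 0.45) and run the whole pipeline.
The QC depth threshold is scaled to the simulated depth (the default
10,000 suits experiment-scale libraries):

```r
library(sccut)

sim <- simulate_dataset(simulation_config(seed = 7))
sim$fragments
#> FragmentCollection: 400000 records ( 400000 fragments ) from 200 barcode(s)
sim$truth
#> TruthManifest: 200 cells, 150 planted peaks ( 50 shared )

res <- run_all(list(
  feature_mode = "peaks",
  qc = list(min_qualified = 1000),
  cluster = list(k = 2, seed = 11)),
  fragments = sim$fragments, out_dir = "sccut_demo")

nrow(res$features$features)   # permissive pooled peaks used as features
#> [1] 150
dim(res$matrix$values)        # features x cells after prevalence filter
#> [1]  96 200
res$summary$median_frip
#> [1] 0.5003789
res$clusters
#> ClusterAssignment: 200 cells in 2 clusters (sizes: 100,100 )

truth <- setNames(sim$truth$cells$cell_type, sim$truth$cells$barcode)
adjusted_rand_index(res$clusters, truth[names(res$clusters$assignment)])
#> [1] 1
res$peak_overlap
#>    cluster_a cluster_b n_peaks_a n_peaks_b n_overlapping
#> 1:         0         1       100       100            50
```

The clustering recovers the two simulated cell types exactly
(ARI = 1), the pooled caller recovers all 150 planted peaks, the 54
ubiquitous shared peaks fall to the prevalence filter (150 → 96
features), and the stringent per-cluster calls overlap at exactly the
50 shared planted domains. The mean fragment size,
`mean_fragment_size(fragment_size_histogram(sim$fragments))`, is
237.8 bp against the size mixture's analytic mean of 238.0 bp.

Output files (`features.bed`, `qc_cells.tsv`, `matrix/`,
`embedding.tsv`, `clusters.tsv`, `cluster*.bedgraph`,
`peaks_cluster*.bed`, `peak_overlap.tsv`, `qc_summary.tsv`) are written
under `out_dir`.

## Command line

A thin CLI over the same functions is installed with the package:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "sccut.R", package = "sccut"))')
Rscript "$CLI" simulate --config sim.yaml --out data
Rscript "$CLI" run-all  --config pipeline.yaml --out results
```

Subcommands `simulate`, `qc`, `peaks`, `matrix`, `cluster`, `tracks`,
`run-all`; stage subcommands read their upstream inputs from the output
directory so individual stages can be re-run after a config change.
Exit codes: 0 ok, 2 configuration error, 3 data error.

## Testing

```r
testthat::test_dir("tests/testthat", package = "sccut",
                   load_package = "installed")
```

The suite checks counting primitives against independent brute-force
oracles, numerics (TF-IDF, truncated SVD, BH, Poisson tails) against
closed forms and dense references, simulator statistics against their
analytic expectations, and end-to-end cluster recovery on simulated
data; `tests/testthat/test-acceptance.R` holds the acceptance-level
properties.

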