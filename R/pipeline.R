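#' Pipeline configuration
#'
#' Builds a validated configuration for [run_all()] by merging user
#' settings over documented defaults. Unknown keys (at top level or inside
#' a section) are rejected, which catches typos early; thresholds are
#' range-checked before any compute.
#'
#' @param config Named list of settings (possibly nested), e.g. parsed
#'   from YAML. See the default object in the source for the schema:
#'   `fragments`, `chrom_sizes`, `mito_names`, `out_dir`, `feature_mode`,
#'   `feature_bed`, `tss_bed`, `bin_size`, and sections `peak`, `qc`,
#'   `prevalence`, `lsi`, `cluster`, `cluster_peaks`, `tracks`.
#' @return A `PipelineConfig` list.
#' @export
pipeline_config <- function(config = list()) {
  defaults <- list(
    version = 1L,
    fragments = NULL,
    chrom_sizes = NULL,
    mito_names = c("chrM", "MT"),
    out_dir = NULL,
    feature_mode = "peaks",
    feature_bed = NULL,
    tss_bed = NULL,
    tss_distance = 2000,
    bin_size = 5000,
    peak = list(width = 1000, step = 1000, merge_gap = 1000,
                q_max = 0.01, min_fold = 1.0),
    qc = list(frip_min = 0.30, min_qualified = 10000),
    prevalence = list(max = 0.80, min = 0.001),
    lsi = list(n_components = 30, depth_r_max = 0.9),
    cluster = list(k = 2, seed = 42),
    cluster_peaks = list(q_max = 0.01, min_fold = 5.0),
    tracks = list(bin_size = 200, normalize = "cpm", per_cell = FALSE))
  merged <- merge_config(defaults, config, path = "")
  validate_pipeline_config(merged)
  structure(merged, class = "PipelineConfig")
}

merge_config <- function(defaults, user, path) {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ",
         paste0(path, unknown, collapse = ", "))
  for (key in names(user)) {
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      defaults[[key]] <- merge_config(defaults[[key]],
                                      as.list(user[[key]]),
                                      paste0(path, key, "."))
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

validate_pipeline_config <- function(cfg) {
  in01 <- function(x) length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
  if (!in01(cfg$qc$frip_min))
    stop("qc.frip_min must lie in [0, 1]")
  if (!in01(cfg$prevalence$max) || !in01(cfg$prevalence$min) ||
      cfg$prevalence$min > cfg$prevalence$max)
    stop("prevalence thresholds must satisfy 0 <= min <= max <= 1")
  if (!in01(cfg$peak$q_max) || !in01(cfg$cluster_peaks$q_max))
    stop("q_max must lie in [0, 1]")
  if (!in01(cfg$lsi$depth_r_max))
    stop("lsi.depth_r_max must lie in [0, 1]")
  if (cfg$qc$min_qualified < 0) stop("qc.min_qualified must be >= 0")
  if (cfg$lsi$n_components < 2) stop("lsi.n_components must be >= 2")
  if (cfg$cluster$k < 2) stop("cluster.k must be >= 2")
  if (!cfg$feature_mode %in% c("peaks", "bins", "custom"))
    stop("feature_mode must be one of peaks, bins, custom")
  if (cfg$feature_mode == "custom" && is.null(cfg$feature_bed))
    stop("feature_mode 'custom' requires feature_bed")
  if (!cfg$tracks$normalize %in% c("cpm", "raw"))
    stop("tracks.normalize must be cpm or raw")
  invisible(cfg)
}

#' Read a pipeline configuration from YAML
#' @param path YAML file path.
#' @return A validated `PipelineConfig`.
#' @export
read_pipeline_config <- function(path) {
  pipeline_config(yaml::read_yaml(path))
}

stage <- function(name, expr) {
  t0 <- Sys.time()
  out <- tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  message(sprintf("[sccut] stage %-16s done in %.2fs", name,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  out
}

#' Run the full single-cell pipeline
#'
#' Executes the whole workflow on one fragment collection: feature
#' selection, per-cell QC and FRiP, cell filtering, matrix construction on
#' the kept cells, binarization and prevalence filtering, TF-IDF + LSI,
#' depth-component removal, k-means clustering, pseudo-bulk aggregation,
#' track generation, stringent per-cluster peak calling, peak overlap and
#' (optionally) TSS-proximity annotation, and a QC summary. Every stage's
#' output is persisted under `out_dir` so individual stages can be re-run
#' from files (see the `sccut` command-line script).
#'
#' @param config A `PipelineConfig`, raw list, or YAML path.
#' @param fragments Optional `FragmentCollection` (otherwise read from
#'   `config$fragments` + `config$chrom_sizes`).
#' @param out_dir Output directory; overrides `config$out_dir`; defaults
#'   to a temporary directory.
#' @return Invisibly, a result bundle: `qc`, `summary`, `features`,
#'   `matrix`, `lsi`, `clusters`, `pseudobulks`, `cluster_peaks` (list per
#'   cluster), `peak_overlap`, `tss_fraction`, `out_dir`.
#' @export
run_all <- function(config = list(), fragments = NULL, out_dir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "PipelineConfig")) config <- pipeline_config(config)
  cfg <- config
  if (is.null(out_dir)) out_dir <- cfg$out_dir
  if (is.null(out_dir)) out_dir <- tempfile("sccut_run_")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  if (is.null(fragments)) {
    if (is.null(cfg$fragments) || is.null(cfg$chrom_sizes))
      stop("config must provide fragments and chrom_sizes paths")
    genome <- read_chrom_sizes(cfg$chrom_sizes, mito_names = cfg$mito_names)
    fragments <- stage("read_fragments",
                       read_fragments(cfg$fragments, genome))
  }
  genome <- fragments$genome

  features <- stage("select_features", select_features(
    cfg$feature_mode, fragments = fragments, genome = genome,
    bin_size = cfg$bin_size, bed_path = cfg$feature_bed,
    width = cfg$peak$width, step = cfg$peak$step,
    merge_gap = cfg$peak$merge_gap, q_max = cfg$peak$q_max,
    min_fold = cfg$peak$min_fold))
  write_features(features, file.path(out_dir, "features.bed"))

  qc <- stage("qc", {
    qc <- compute_cell_qc(fragments)
    frip_vec <- compute_frip(fragments, features)
    qc[, frip := unname(frip_vec[barcode])]
    qc
  })
  hist <- stage("fragment_sizes", fragment_size_histogram(fragments))
  data.table::fwrite(hist, file.path(out_dir, "fragment_size_hist.tsv"),
                     sep = "\t")

  filt <- stage("filter_cells", filter_cells(
    qc, frip_min = cfg$qc$frip_min, min_qualified = cfg$qc$min_qualified))
  qc <- filt$qc
  data.table::fwrite(qc, file.path(out_dir, "qc_cells.tsv"), sep = "\t")
  if (!length(filt$kept)) stop("no cells pass QC")
  kept_frags <- subset_barcodes(fragments, filt$kept)

  m <- stage("matrix", {
    m <- build_matrix(kept_frags, features, cells = filt$kept)
    m <- binarize(m)
    filter_features_by_prevalence(m, max_prev = cfg$prevalence$max,
                                  min_prev = cfg$prevalence$min)
  })
  depth_counts <- Matrix::colSums(m$values)
  nonzero_cells <- depth_counts > 0
  if (!all(nonzero_cells)) {
    warning(sum(!nonzero_cells),
            " cell(s) with no features after filtering were dropped")
    m <- feature_cell_matrix(m$values[, nonzero_cells, drop = FALSE],
                             m$feature_ids, m$barcodes[nonzero_cells],
                             binarized = TRUE)
    depth_counts <- depth_counts[nonzero_cells]
  }
  write_matrix_dir(m, file.path(out_dir, "matrix"))

  emb <- stage("lsi", {
    w <- tfidf(m)
    K <- min(cfg$lsi$n_components, dim(w) - 0L)
    if (K < cfg$lsi$n_components)
      message("[sccut] n_components reduced to ", K, " (matrix size)")
    depth <- log10(depth_counts)
    r <- lsi(w, K = K, depth = depth)
    drop_depth_components(r, depth, r_max = cfg$lsi$depth_r_max)
  })
  emb_out <- data.table::data.table(barcode = rownames(emb$embedding))
  emb_out <- cbind(emb_out, data.table::as.data.table(emb$embedding))
  data.table::fwrite(emb_out, file.path(out_dir, "embedding.tsv"),
                     sep = "\t")

  clusters <- stage("cluster", cluster_cells(emb, k = cfg$cluster$k,
                                             seed = cfg$cluster$seed))
  cl_out <- data.table::data.table(barcode = names(clusters$assignment),
                                   cluster = unname(clusters$assignment))
  data.table::setorder(cl_out, barcode)
  data.table::fwrite(cl_out, file.path(out_dir, "clusters.tsv"), sep = "\t")

  pbs <- stage("pseudobulk", make_pseudobulks(
    subset_barcodes(kept_frags, names(clusters$assignment)), clusters))
  pk_list <- list()
  for (pb in pbs) {
    tr <- pseudobulk_track(pb, genome, bin_size = cfg$tracks$bin_size,
                           normalize = cfg$tracks$normalize)
    write_bedgraph(tr, file.path(out_dir, sprintf(
      "cluster%d.bedgraph", pb$cluster_id)))
    pk <- cluster_peaks(pb, q_max = cfg$cluster_peaks$q_max,
                        min_fold = cfg$cluster_peaks$min_fold,
                        width = cfg$peak$width, step = cfg$peak$step,
                        merge_gap = cfg$peak$merge_gap)
    write_peaks(pk, file.path(out_dir, sprintf("peaks_cluster%d.bed",
                                               pb$cluster_id)))
    pk_list[[as.character(pb$cluster_id)]] <- pk
  }
  if (isTRUE(cfg$tracks$per_cell))
    stage("per_cell_tracks", per_cell_tracks(
      kept_frags, clusters, genome, bin_size = cfg$tracks$bin_size,
      dir = out_dir))

  overlap <- NULL
  if (length(pk_list) >= 2L) {
    pairs <- utils::combn(names(pk_list), 2L)
    overlap <- data.table::rbindlist(apply(pairs, 2L, function(p)
      data.table::data.table(
        cluster_a = p[1], cluster_b = p[2],
        n_peaks_a = nrow(pk_list[[p[1]]]),
        n_peaks_b = nrow(pk_list[[p[2]]]),
        n_overlapping = count_overlapping_peaks(pk_list[[p[1]]],
                                                pk_list[[p[2]]]))))
    data.table::fwrite(overlap, file.path(out_dir, "peak_overlap.tsv"),
                       sep = "\t")
  }

  tss_frac <- NULL
  if (!is.null(cfg$tss_bed)) {
    tss <- read_features(cfg$tss_bed, genome)
    tss_frac <- data.table::rbindlist(lapply(names(pk_list), function(cid)
      data.table::data.table(
        cluster = cid,
        tss_proximal_fraction = if (nrow(pk_list[[cid]]))
          tss_proximal_fraction(pk_list[[cid]], tss,
                                d = cfg$tss_distance) else NA_real_)))
    data.table::fwrite(tss_frac, file.path(out_dir, "tss_fraction.tsv"),
                       sep = "\t")
  }

  summary <- qc_summary(qc)
  data.table::fwrite(summary, file.path(out_dir, "qc_summary.tsv"),
                     sep = "\t")

  invisible(list(qc = qc, summary = summary, features = features,
                 matrix = m, lsi = emb, clusters = clusters,
                 pseudobulks = pbs, cluster_peaks = pk_list,
                 peak_overlap = overlap, tss_fraction = tss_frac,
                 out_dir = out_dir))
}
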