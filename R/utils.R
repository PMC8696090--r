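# Evaluate expr with a local RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

.datatable.aware <- TRUE

utils::globalVariables(c(
  ".", ".N", ".I", "chrom", "start", "end", "barcode", "count", "value",
  "feature_id", "size_bin", "p_value", "q_value", "fold_change", "lambda_bg",
  "total_fragments", "dedup_fragments", "duplicate_rate", "mito_fraction",
  "mito_fragments", "qualified_fragments", "mean_fragment_size",
  "median_fragment_size", "frip", "pass_qc", "exclusion_reason",
  "n_excluded", "n_excluded_low_frip", "n_excluded_few_fragments",
  "n_excluded_undefined_frip", "grp", "q", "old_label", "min_bc",
  "cell_type", "peak_id", "shared", "cell_types", "V1", "size", "bin", "n"))
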