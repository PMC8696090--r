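#' Feature sets
#'
#' A `FeatureSet` is the set of genomic features that columns of coverage
#' are counted against: called peaks (`mode = "peaks"`), genome-wide bins
#' (`mode = "bins"`), or user-defined functional elements
#' (`mode = "custom"`). Coordinates are 0-based half-open. For peaks and
#' bins the features are guaranteed sorted and non-overlapping per
#' chromosome; custom features may overlap (a warning is logged).
#'
#' @param features data.frame with columns `chrom`, `start`, `end`,
#'   `feature_id` (ids generated as `"chrom:start-end"` when absent).
#' @param mode One of `"peaks"`, `"bins"`, `"custom"`.
#' @param genome A `GenomeSpec` (used for validation and chromosome order).
#' @param validate Check invariants.
#' @return A `FeatureSet`.
#' @export
feature_set <- function(features, mode = c("custom", "peaks", "bins"),
                        genome, validate = TRUE) {
  mode <- match.arg(mode)
  if (!is_genome_spec(genome)) stop("genome must be a GenomeSpec")
  dt <- data.table::as.data.table(features)
  if (!all(c("chrom", "start", "end") %in% names(dt)))
    stop("features must have columns chrom, start, end")
  dt <- data.table::copy(dt)
  dt[, `:=`(chrom = as.character(chrom), start = as.integer(start),
            end = as.integer(end))]
  if (!"feature_id" %in% names(dt))
    dt[, feature_id := paste0(chrom, ":", start, "-", end)]
  dt <- dt[, list(chrom, start, end, feature_id = as.character(feature_id))]
  if (validate && nrow(dt)) {
    bad_chrom <- setdiff(unique(dt$chrom), genome$chrom_names)
    if (length(bad_chrom))
      stop("feature chromosome(s) not in genome: ",
           paste(bad_chrom, collapse = ", "))
    if (any(dt$start < 0L) || any(dt$start >= dt$end))
      stop("invalid feature interval (require 0 <= start < end)")
    if (any(dt$end > genome$chrom_lengths[dt$chrom]))
      stop("feature interval beyond chromosome end")
    if (anyDuplicated(dt$feature_id))
      stop("feature ids must be unique")
  }
  dt[, chrom := factor(chrom, levels = genome$chrom_names)]
  data.table::setorder(dt, chrom, start, end)
  dt[, chrom := as.character(chrom)]
  if (nrow(dt) > 1L) {
    ovl <- dt[, any(start[-1L] < end[-.N]), by = chrom][, any(V1)]
    if (ovl) {
      if (mode %in% c("peaks", "bins"))
        stop("features must be non-overlapping in mode '", mode, "'")
      warning("custom feature set contains overlapping intervals")
    }
  }
  structure(list(features = dt, mode = mode, genome = genome),
            class = "FeatureSet")
}

#' @export
print.FeatureSet <- function(x, ...) {
  cat("FeatureSet:", nrow(x$features), "feature(s), mode", x$mode, "\n")
  invisible(x)
}

#' Number of features
#' @param features A `FeatureSet`.
#' @export
n_features <- function(features) nrow(features$features)

#' Read user-defined features from a BED file
#'
#' BED3+ (tab-separated, 0-based half-open; column 4, when present, supplies
#' feature ids). An empty file yields an empty `FeatureSet` with a warning.
#'
#' @param path BED file path.
#' @param genome A `GenomeSpec`.
#' @return A `FeatureSet` with mode `"custom"`.
#' @export
read_features <- function(path, genome) {
  if (!file.exists(path)) stop("feature file not found: ", path)
  if (file.size(path) == 0L) {
    warning("feature file is empty: ", path)
    return(feature_set(
      data.table::data.table(chrom = character(), start = integer(),
                             end = integer(), feature_id = character()),
      mode = "custom", genome = genome, validate = FALSE))
  }
  dt <- tryCatch(
    data.table::fread(path, header = FALSE, sep = "\t",
                      colClasses = list(character = 1)),
    error = function(e) stop("malformed BED file ", path, ": ",
                             conditionMessage(e)))
  if (ncol(dt) < 3L)
    stop("BED file must have at least 3 columns: ", path)
  feats <- data.table::data.table(
    chrom = dt[[1]], start = as.integer(dt[[2]]), end = as.integer(dt[[3]]))
  if (ncol(dt) >= 4L) feats[, feature_id := as.character(dt[[4]])]
  feature_set(feats, mode = "custom", genome = genome)
}

#' Write features as BED
#' @param features A `FeatureSet`.
#' @param path Output path.
#' @export
write_features <- function(features, path) {
  data.table::fwrite(features$features, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
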