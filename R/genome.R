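#' Genome specification
#'
#' A minimal genome description: an ordered set of chromosome names with
#' lengths, plus the set of names treated as mitochondrial. Chromosome order
#' is the order given here (typically the order of the chrom.sizes file), and
#' it is the sort key used everywhere downstream.
#'
#' @param chrom_names Character vector of unique chromosome names.
#' @param chrom_lengths Positive integer vector of lengths (bp), parallel to
#'   `chrom_names`.
#' @param mito_names Character vector of names counted as mitochondrial.
#'   Defaults to `c("chrM", "MT")`; names absent from the genome are ignored
#'   until mitochondrial metrics are actually requested.
#' @return An object of class `GenomeSpec`.
#' @export
genome_spec <- function(chrom_names, chrom_lengths, mito_names = c("chrM", "MT")) {
  chrom_names <- as.character(chrom_names)
  chrom_lengths <- as.numeric(chrom_lengths)
  if (length(chrom_names) == 0L)
    stop("genome must contain at least one chromosome")
  if (anyDuplicated(chrom_names))
    stop("chromosome names must be unique")
  if (length(chrom_lengths) != length(chrom_names))
    stop("chrom_names and chrom_lengths must have the same length")
  if (any(!is.finite(chrom_lengths)) || any(chrom_lengths <= 0) ||
      any(chrom_lengths != floor(chrom_lengths)))
    stop("chromosome lengths must be positive integers")
  structure(
    list(chrom_names = chrom_names,
         chrom_lengths = stats::setNames(chrom_lengths, chrom_names),
         mito_names = as.character(mito_names)),
    class = "GenomeSpec")
}

#' Read a chrom.sizes file
#'
#' Two-column TSV: chromosome name, length. Chromosome order in the file is
#' preserved as the genome's canonical order.
#'
#' @param path Path to the chrom.sizes file.
#' @inheritParams genome_spec
#' @return A `GenomeSpec`.
#' @export
read_chrom_sizes <- function(path, mito_names = c("chrM", "MT")) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = 1))
  if (ncol(dt) < 2L)
    stop("chrom.sizes file must have two columns (name, length): ", path)
  genome_spec(dt[[1]], dt[[2]], mito_names = mito_names)
}

#' Write a chrom.sizes file
#' @param genome A `GenomeSpec`.
#' @param path Output path.
#' @export
write_chrom_sizes <- function(genome, path) {
  data.table::fwrite(
    data.table::data.table(chrom = genome$chrom_names,
                           length = unname(genome$chrom_lengths)),
    path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' @export
print.GenomeSpec <- function(x, ...) {
  cat("GenomeSpec:", length(x$chrom_names), "chromosome(s),",
      format(sum(x$chrom_lengths), big.mark = ","), "bp total;",
      "mito names:", paste(x$mito_names, collapse = ","), "\n")
  invisible(x)
}

is_genome_spec <- function(x) inherits(x, "GenomeSpec")

#' Nuclear (non-mitochondrial) chromosome names
#' @param genome A `GenomeSpec`.
#' @return Character vector.
#' @export
nuclear_chroms <- function(genome) {
  setdiff(genome$chrom_names, genome$mito_names)
}

#' Effective genome size
#'
#' Total number of non-mitochondrial bases; used as the background
#' normalizer by the Poisson window peak caller.
#'
#' @param genome A `GenomeSpec`.
#' @return Number of nuclear bases.
#' @export
effective_genome_size <- function(genome) {
  sum(genome$chrom_lengths[nuclear_chroms(genome)])
}

#' Tile a genome into fixed-width bins
#'
#' Tiles each chromosome with half-open windows
#' `[k*bin_size, min((k+1)*bin_size, length))`. The last bin on each
#' chromosome is clipped to the chromosome end, so bin widths always sum to
#' the genome length.
#'
#' @param genome A `GenomeSpec`.
#' @param bin_size Bin width in bp (>= 1).
#' @return A `FeatureSet` with mode `"bins"` and deterministic ids
#'   `"chrom:start-end"`.
#' @export
make_bins <- function(genome, bin_size) {
  if (!is_genome_spec(genome)) stop("genome must be a GenomeSpec")
  if (length(bin_size) != 1L || !is.finite(bin_size) || bin_size < 1)
    stop("bin_size must be a positive integer")
  bin_size <- as.integer(bin_size)
  per_chrom <- lapply(genome$chrom_names, function(ch) {
    len <- genome$chrom_lengths[[ch]]
    starts <- seq.int(0L, len - 1L, by = bin_size)
    data.table::data.table(chrom = ch, start = starts,
                           end = pmin(starts + bin_size, len))
  })
  dt <- data.table::rbindlist(per_chrom)
  dt[, feature_id := paste0(chrom, ":", start, "-", end)]
  feature_set(dt, mode = "bins", genome = genome, validate = FALSE)
}
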