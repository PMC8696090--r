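# Shared fixtures and brute-force oracles, independent of the package's
# interval machinery (plain loops over rows).

tiny_genome <- function(len1 = 10000L, mito_len = 1000L) {
  genome_spec(c("chr1", "chrM"), c(len1, mito_len), mito_names = "chrM")
}

frags <- function(genome, chrom, start, end, barcode, count = 1L) {
  fragment_collection(
    data.frame(chrom = chrom, start = start, end = end,
               barcode = barcode, count = count),
    genome)
}

# >= 1 bp overlap of two half-open intervals
hits_interval <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1

# all-pairs overlap indicator: does row i of a overlap any row of b
bf_overlaps_any <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    any(a$chrom[i] == b$chrom &
          hits_interval(a$start[i], a$end[i], b$start, b$end))
  }, logical(1))
}

# per-row-of-b count of overlapping rows of a
bf_count_overlaps <- function(b, a) {
  vapply(seq_len(nrow(b)), function(j) {
    sum(a$chrom == b$chrom[j] &
          hits_interval(a$start, a$end, b$start[j], b$end[j]))
  }, integer(1))
}

# brute-force FRiP per barcode on deduplicated nuclear fragments
bf_frip <- function(fragments, peaks) {
  dt <- as.data.frame(fragments$records[
    !chrom %in% fragments$genome$mito_names])
  dt <- dt[!duplicated(dt[, c("chrom", "start", "end", "barcode")]), ]
  pk <- as.data.frame(peaks$features)
  hit <- bf_overlaps_any(dt, pk)
  out <- tapply(hit, dt$barcode, mean)
  setNames(as.numeric(out), names(out))
}

# brute-force triple loop feature x cell count matrix
bf_matrix <- function(fragments, features, cells) {
  dt <- as.data.frame(fragments$records[
    !chrom %in% fragments$genome$mito_names])
  dt <- dt[!duplicated(dt[, c("chrom", "start", "end", "barcode")]), ]
  dt <- dt[dt$barcode %in% cells, ]
  ft <- as.data.frame(features$features)
  m <- matrix(0L, nrow(ft), length(cells),
              dimnames = list(ft$feature_id, cells))
  for (i in seq_len(nrow(ft))) {
    for (r in seq_len(nrow(dt))) {
      if (dt$chrom[r] == ft$chrom[i] &&
          hits_interval(dt$start[r], dt$end[r], ft$start[i], ft$end[i]))
        m[i, dt$barcode[r]] <- m[i, dt$barcode[r]] + 1L
    }
  }
  m
}

# dense reference TF-IDF on a plain 0/1 matrix
bf_tfidf <- function(x) {
  n <- ncol(x)
  tf <- sweep(x, 2, colSums(x), "/")
  idf <- log(1 + n / rowSums(x))
  tf * idf
}

# textbook step-up BH adjustment
bf_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# random fragment instance on a tiny genome
random_instance <- function(genome, n_frags, n_cells, seed) {
  set.seed(seed)
  len <- genome$chrom_lengths[["chr1"]]
  start <- sample.int(len - 200L, n_frags, replace = TRUE) - 1L
  end <- start + sample(30:200, n_frags, replace = TRUE)
  end <- pmin(end, len)
  frags(genome, "chr1", start, end,
        sample(sprintf("BC%02d", seq_len(n_cells)), n_frags,
               replace = TRUE))
}

random_features <- function(genome, n, width_max, seed, mode = "custom") {
  set.seed(seed)
  len <- genome$chrom_lengths[["chr1"]]
  start <- sample.int(len - width_max - 1L, n) - 1L
  start <- sort(start)
  end <- pmin(start + sample(20:width_max, n, replace = TRUE), len)
  # keep non-overlapping so peaks/bins modes also accept them
  keep <- c(TRUE, start[-1] >= cummax(end[-n]))
  feature_set(data.frame(chrom = "chr1", start = start, end = end)[keep, ],
              mode = mode, genome = genome)
}

# >= 50% reciprocal overlap matching between two interval tables
reciprocal_match <- function(a, b, frac = 0.5) {
  vapply(seq_len(nrow(a)), function(i) {
    same <- b$chrom == a$chrom[i]
    if (!any(same)) return(FALSE)
    ov <- pmax(0, pmin(a$end[i], b$end[same]) -
                 pmax(a$start[i], b$start[same]))
    wa <- a$end[i] - a$start[i]
    wb <- b$end[same] - b$start[same]
    any(ov >= frac * wa & ov >= frac * wb)
  }, logical(1))
}
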