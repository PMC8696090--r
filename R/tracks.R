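#' Genome signal tracks
#'
#' A `Track` is a sequence of sorted, non-overlapping genome bins with a
#' non-negative value each — the in-memory form of a bedGraph file.
#'
#' @param bins data.frame with columns `chrom`, `start`, `end`, `value`
#'   (0-based half-open intervals, finite non-negative values).
#' @param label Track label, written into the bedGraph track line.
#' @return A `Track`.
#' @export
track <- function(bins, label = "track") {
  dt <- data.table::as.data.table(bins)
  if (!all(c("chrom", "start", "end", "value") %in% names(dt)))
    stop("bins must have columns chrom, start, end, value")
  dt <- dt[, list(chrom = as.character(chrom), start = as.integer(start),
                  end = as.integer(end), value = as.numeric(value))]
  if (any(!is.finite(dt$value)) || any(dt$value < 0))
    stop("track values must be finite and non-negative")
  if (any(dt$start >= dt$end)) stop("track bins must satisfy start < end")
  structure(list(bins = dt, label = label), class = "Track")
}

#' @export
print.Track <- function(x, ...) {
  cat("Track '", x$label, "': ", nrow(x$bins), " bins, ",
      sum(x$bins$value > 0), " nonzero\n", sep = "")
  invisible(x)
}

#' Write a track as bedGraph
#'
#' Standard 4-column bedGraph (chrom, start, end, value; 0-based half-open)
#' preceded by a `track type=bedGraph` line. Zero-value bins are omitted, so
#' an all-zero track yields a header-only file. `read_bedgraph` of the
#' result reproduces the nonzero bins exactly.
#'
#' @param track A `Track`.
#' @param path Output path.
#' @export
write_bedgraph <- function(track, path) {
  writeLines(sprintf('track type=bedGraph name="%s"', track$label), path)
  nz <- track$bins[value > 0]
  if (nrow(nz))
    data.table::fwrite(nz, path, sep = "\t", col.names = FALSE,
                       append = TRUE)
  invisible(path)
}

#' Read a bedGraph file
#' @param path bedGraph path.
#' @param label Track label; defaults to the name in the track line, else
#'   the file name.
#' @return A `Track` holding the file's (nonzero) bins.
#' @export
read_bedgraph <- function(path, label = NULL) {
  lines <- readLines(path)
  is_header <- grepl("^(track|#|browser)", lines)
  if (is.null(label)) {
    m <- regmatches(lines[is_header],
                    regexpr('name="[^"]*"', lines[is_header]))
    label <- if (length(m)) sub('name="([^"]*)"', "\\1", m[1]) else
      sub("\\..*$", "", basename(path))
  }
  body <- lines[!is_header]
  if (!length(body))
    return(track(data.table::data.table(chrom = character(),
                                        start = integer(), end = integer(),
                                        value = numeric()), label = label))
  dt <- data.table::fread(text = body, header = FALSE, sep = "\t")
  if (ncol(dt) != 4L) stop("bedGraph must have 4 columns: ", path)
  track(data.table::data.table(chrom = dt[[1]], start = dt[[2]],
                               end = dt[[3]], value = dt[[4]]),
        label = label)
}

#' Pearson correlation between two identically binned tracks
#'
#' Computed over the union of bins that are nonzero in either track, after
#' an optional `log1p` transform (the default; avoids inflation from the
#' genome-wide mass of shared zero bins). Tracks must share the same
#' binning. Two bin-wise identical tracks correlate at exactly 1.
#'
#' @param a,b `Track`s over the same bins.
#' @param transform `"log1p"` (default) or `"none"`.
#' @return Pearson correlation in `[-1, 1]`.
#' @export
correlate_tracks <- function(a, b, transform = c("log1p", "none")) {
  transform <- match.arg(transform)
  if (nrow(a$bins) != nrow(b$bins) ||
      !identical(a$bins$chrom, b$bins$chrom) ||
      !identical(a$bins$start, b$bins$start) ||
      !identical(a$bins$end, b$bins$end))
    stop("tracks must share identical binning")
  keep <- a$bins$value > 0 | b$bins$value > 0
  x <- a$bins$value[keep]
  y <- b$bins$value[keep]
  if (!length(x)) stop("no nonzero bins in either track")
  if (identical(x, y)) return(1.0)
  if (transform == "log1p") {
    x <- log1p(x)
    y <- log1p(y)
  }
  stats::cor(x, y, method = "pearson")
}
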