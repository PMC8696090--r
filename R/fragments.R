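#' Fragment collections
#'
#' A `FragmentCollection` holds barcode-tagged genomic intervals — one row
#' per sequenced fragment record — together with the `GenomeSpec` they were
#' validated against. Coordinates are 0-based half-open (BED convention)
#' throughout. Records are kept sorted by (chromosome order as given in the
#' genome, start, end, barcode); the optional `count` column records how many
#' identical copies of a record were observed.
#'
#' @param records A data.frame with columns `chrom`, `start`, `end`,
#'   `barcode` and optionally `count` (default 1).
#' @param genome A `GenomeSpec`.
#' @param validate Check invariants (coordinates within chromosomes,
#'   start < end). Internal callers that construct valid records may skip.
#' @return A `FragmentCollection`.
#' @export
fragment_collection <- function(records, genome, validate = TRUE) {
  if (!is_genome_spec(genome)) stop("genome must be a GenomeSpec")
  dt <- data.table::as.data.table(records)
  req <- c("chrom", "start", "end", "barcode")
  if (!all(req %in% names(dt)))
    stop("records must have columns chrom, start, end, barcode")
  if (!"count" %in% names(dt)) dt[, count := 1L]
  dt <- dt[, list(chrom = as.character(chrom), start = as.integer(start),
                  end = as.integer(end), barcode = as.character(barcode),
                  count = as.integer(count))]
  if (validate) validate_fragment_records(dt, genome)
  dt[, chrom := factor(chrom, levels = genome$chrom_names)]
  data.table::setorder(dt, chrom, start, end, barcode)
  dt[, chrom := as.character(chrom)]
  structure(list(records = dt, genome = genome), class = "FragmentCollection")
}

validate_fragment_records <- function(dt, genome) {
  bad_chrom <- setdiff(unique(dt$chrom), genome$chrom_names)
  if (length(bad_chrom))
    stop("chromosome(s) not in genome: ", paste(bad_chrom, collapse = ", "))
  if (any(is.na(dt$start)) || any(is.na(dt$end)))
    stop("non-integer coordinates in fragment records")
  bad <- dt$start < 0L | dt$start >= dt$end
  if (any(bad))
    stop("invalid interval (require 0 <= start < end) at record ",
         which(bad)[1L], ": ", dt$chrom[which(bad)[1L]], ":",
         dt$start[which(bad)[1L]], "-", dt$end[which(bad)[1L]])
  lens <- genome$chrom_lengths[dt$chrom]
  over <- dt$end > lens
  if (any(over))
    stop("interval beyond chromosome end at record ", which(over)[1L],
         ": ", dt$chrom[which(over)[1L]], ":", dt$start[which(over)[1L]],
         "-", dt$end[which(over)[1L]])
  if (any(dt$count < 1L))
    stop("fragment counts must be positive integers")
  invisible(TRUE)
}

#' @export
print.FragmentCollection <- function(x, ...) {
  cat("FragmentCollection:", nrow(x$records), "records (",
      sum(x$records$count), "fragments ) from",
      length(barcodes(x)), "barcode(s)\n")
  invisible(x)
}

#' Number of fragment records (rows)
#' @param fragments A `FragmentCollection`.
#' @export
n_records <- function(fragments) nrow(fragments$records)

#' Total fragment count (count column expanded)
#' @param fragments A `FragmentCollection`.
#' @export
n_fragments <- function(fragments) sum(fragments$records$count)

#' Distinct cell barcodes
#' @param fragments A `FragmentCollection`.
#' @return Sorted character vector.
#' @export
barcodes <- function(fragments) sort(unique(fragments$records$barcode))

#' Read fragment files
#'
#' Reads one or more BED-like fragment files (tab-separated; columns
#' chrom, start, end, barcode, and optionally count; optionally
#' gzip-compressed). When a file carries only 3 columns it is treated as a
#' per-cell file and the barcode is inferred from the file name (basename
#' without extensions); a pooled 4/5-column file carries barcodes in column 4.
#'
#' @param paths One or more file paths.
#' @param genome A `GenomeSpec`; records on chromosomes absent from it are a
#'   validation error.
#' @return A sorted, validated `FragmentCollection`.
#' @export
read_fragments <- function(paths, genome) {
  pieces <- lapply(paths, function(path) {
    if (!file.exists(path)) stop("fragment file not found: ", path)
    if (file.size(path) == 0L)
      return(data.table::data.table(chrom = character(), start = integer(),
                                    end = integer(), barcode = character(),
                                    count = integer()))
    dt <- tryCatch({
      if (grepl("\\.gz$", path)) {
        con <- gzfile(path, open = "rt")
        on.exit(close(con), add = TRUE)
        data.table::fread(text = readLines(con), header = FALSE,
                          sep = "\t", fill = FALSE,
                          colClasses = list(character = 1))
      } else {
        data.table::fread(path, header = FALSE, sep = "\t", fill = FALSE,
                          colClasses = list(character = 1))
      }
    }, error = function(e) stop("malformed fragment file ", path, ": ",
                                conditionMessage(e)))
    if (nrow(dt) == 0L)
      return(data.table::data.table(chrom = character(), start = integer(),
                                    end = integer(), barcode = character(),
                                    count = integer()))
    nc <- ncol(dt)
    if (nc < 3L || nc > 5L)
      stop("fragment file ", path, " must have 3-5 columns, found ", nc)
    for (j in 2:3) {
      v <- dt[[j]]
      if (!is.integer(v) && !(is.numeric(v) && all(v == floor(v)))) {
        bad <- if (is.numeric(v)) which(v != floor(v))[1L] else
          which(is.na(suppressWarnings(as.integer(v))))[1L]
        stop("non-integer coordinate in ", path, " at line ",
             if (is.na(bad)) 1L else bad)
      }
    }
    out <- data.table::data.table(
      chrom = dt[[1]], start = as.integer(dt[[2]]), end = as.integer(dt[[3]]))
    if (nc >= 4L) {
      out[, barcode := as.character(dt[[4]])]
    } else {
      out[, barcode := sub("\\..*$", "", basename(path))]
    }
    out[, count := if (nc == 5L) as.integer(dt[[5]]) else 1L]
    out
  })
  fragment_collection(data.table::rbindlist(pieces), genome)
}

#' Write a fragment file
#'
#' TSV with columns chrom, start, end, barcode, count. `read_fragments` of
#' the result reproduces the collection exactly.
#'
#' @param fragments A `FragmentCollection`.
#' @param path Output path (gzip-compressed when it ends in `.gz`).
#' @export
write_fragments <- function(fragments, path) {
  data.table::fwrite(fragments$records, path, sep = "\t", col.names = FALSE,
                     compress = if (grepl("\\.gz$", path)) "gzip" else "none")
  invisible(path)
}

#' Restrict a collection to deduplicated nuclear fragments
#'
#' Duplicates are records identical in (chrom, start, end, barcode) beyond
#' the first occurrence, with the count column expanded; deduplication keeps
#' one copy (count 1). Mitochondrial records are dropped. These "qualified"
#' fragments are the substrate for FRiP, window counting and matrix building.
#'
#' @param fragments A `FragmentCollection`.
#' @return A `FragmentCollection` of unique nuclear records, all counts 1.
#' @export
qualified_fragments <- function(fragments) {
  dt <- fragments$records[!chrom %in% fragments$genome$mito_names]
  dt <- unique(dt, by = c("chrom", "start", "end", "barcode"))
  dt <- data.table::copy(dt)
  dt[, count := 1L]
  structure(list(records = dt, genome = fragments$genome),
            class = "FragmentCollection")
}

#' Subset a collection by barcode
#' @param fragments A `FragmentCollection`.
#' @param keep Character vector of barcodes to retain.
#' @export
subset_barcodes <- function(fragments, keep) {
  structure(list(records = fragments$records[barcode %in% keep],
                 genome = fragments$genome),
            class = "FragmentCollection")
}

# GRanges view of fragment records (1-based closed, for overlap queries).
frag_granges <- function(fragments) {
  dt <- fragments$records
  GenomicRanges::GRanges(
    seqnames = dt$chrom,
    ranges = IRanges::IRanges(start = dt$start + 1L, end = dt$end))
}

# GRanges for any 0-based half-open interval table.
intervals_granges <- function(dt) {
  GenomicRanges::GRanges(
    seqnames = dt$chrom,
    ranges = IRanges::IRanges(start = dt$start + 1L, end = dt$end))
}
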