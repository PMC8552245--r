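#' @import GenomicRanges
#' @import IRanges
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits
NULL

# All intervals in this package live in GRanges (1-based, closed), the single
# internal convention; BED and bedGraph (0-based, half-open) and GFF3
# (1-based, closed) are converted at the I/O boundary.

strip_header_lines <- function(lines) {
  keep <- !grepl("^\\s*(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  list(lines = lines[keep], index = which(keep))
}

#' Read a BED file into a peak set
#'
#' Reads BED3-BED6 into a `GRanges` (1-based closed internally; BED's 0-based
#' half-open coordinates are shifted at the boundary). Track, browser and `#`
#' comment lines are tolerated. Input order is preserved; name, score and
#' strand are filled when the columns are present.
#'
#' @param path path to a BED file.
#' @return A `GRanges`; `name` (also used as `names()`) and `score` metadata
#'   columns are set when present in the file.
#' @export
load_intervals <- function(path) {
  stopifnot(file.exists(path))
  raw <- readLines(path)
  kept <- strip_header_lines(raw)
  if (length(kept$lines) == 0L) return(GRanges())
  fields <- strsplit(kept$lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    bad <- kept$index[which(nf < 3L)[1L]]
    stop(sprintf("malformed BED line %d: fewer than 3 columns", bad))
  }
  ncol_use <- min(nf, 6L)
  get_col <- function(i) vapply(fields, function(f) if (length(f) >= i) f[i] else NA_character_, "")
  chrom <- get_col(1L)
  start0 <- suppressWarnings(as.numeric(get_col(2L)))
  end0 <- suppressWarnings(as.numeric(get_col(3L)))
  if (any(is.na(start0)) || any(is.na(end0))) {
    bad <- kept$index[which(is.na(start0) | is.na(end0))[1L]]
    stop(sprintf("malformed BED line %d: non-numeric coordinates", bad))
  }
  if (any(start0 >= end0)) {
    bad <- kept$index[which(start0 >= end0)[1L]]
    stop(sprintf("invalid interval on BED line %d: start >= end", bad))
  }
  gr <- GRanges(chrom, IRanges(start0 + 1, end0))
  if (ncol_use >= 4L) {
    nm <- get_col(4L)
    mcols(gr)$name <- nm
    names(gr) <- nm
  }
  if (ncol_use >= 5L) mcols(gr)$score <- suppressWarnings(as.numeric(get_col(5L)))
  if (ncol_use >= 6L) {
    str <- get_col(6L)
    str[!str %in% c("+", "-")] <- "*"
    strand(gr) <- str
  }
  gr
}

format_bed_score <- function(s) {
  s[is.na(s)] <- 0
  ifelse(s == round(s), format(s, scientific = FALSE, trim = TRUE),
         as.character(s))
}

#' Write a peak set as BED
#'
#' Canonical 6-column BED (0-based half-open); `name` defaults to `.` and
#' `score` to 0 when absent. Round-trips byte-identically with
#' [load_intervals()] for files it wrote itself.
#'
#' @param peaks a `GRanges`.
#' @param path output path.
#' @export
write_intervals <- function(peaks, path) {
  nm <- if (!is.null(mcols(peaks)$name)) mcols(peaks)$name else names(peaks)
  if (is.null(nm)) nm <- rep(".", length(peaks))
  nm[is.na(nm) | nm == ""] <- "."
  sc <- if (!is.null(mcols(peaks)$score)) mcols(peaks)$score else rep(0, length(peaks))
  str <- as.character(strand(peaks))
  str[str == "*"] <- "."
  dt <- data.table::data.table(
    chrom = as.character(seqnames(peaks)),
    start = start(peaks) - 1L,
    end = end(peaks),
    name = nm,
    score = format_bed_score(as.numeric(sc)),
    strand = str)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Merge overlapping or book-ended intervals
#'
#' Strand-blind union of the input: the output intervals are pairwise
#' disjoint, sorted by (chrom, start), and cover exactly the same bases as
#' the input. Book-ended intervals (zero-gap neighbours) are merged, matching
#' common `bedtools merge` semantics.
#'
#' @param peaks a `GRanges`.
#' @return A sorted, disjoint `GRanges`.
#' @export
merge_intervals <- function(peaks) {
  if (length(peaks) == 0L) return(GRanges())
  out <- reduce(granges(peaks), ignore.strand = TRUE)
  sort(out, ignore.strand = TRUE)
}

#' Rescale peaks to fixed-width windows around their midpoints
#'
#' Standardises peaks to `mid - halfwidth, mid + halfwidth` (a 2*halfwidth
#' window, half-open in 0-based terms) around the midpoint
#' `floor((start0 + end0)/2)`; even-length peaks take the left-biased
#' midpoint. Windows are clipped at the chromosome start (position 0);
#' right-clipping is left to operations that know the chromosome length.
#'
#' @param peaks a `GRanges`.
#' @param halfwidth half window width in bp (default 100, giving the
#'   +/-100 bp windows used for peak-level counting and comparison).
#' @return A `GRanges` with the same metadata, names and strand.
#' @export
rescale_to_midpoint <- function(peaks, halfwidth = 100L) {
  stopifnot(halfwidth > 0)
  if (length(peaks) == 0L) return(peaks)
  mid0 <- floor((start(peaks) - 1 + end(peaks)) / 2)
  new_start <- pmax(mid0 - halfwidth, 0) + 1
  new_end <- mid0 + halfwidth
  ranges(peaks) <- IRanges(new_start, new_end, names = names(peaks))
  peaks
}

#' Fraction of query peaks overlapping a reference set
#'
#' Fraction of `query` intervals that overlap at least 1 bp of any
#' `reference` interval (strand-blind).
#'
#' @param query,reference `GRanges` objects.
#' @return A number in `[0, 1]`; an empty query returns 0 with a warning.
#' @export
overlap_fraction <- function(query, reference) {
  if (length(query) == 0L) {
    warning("empty query peak set; overlap fraction defined as 0")
    return(0)
  }
  if (length(reference) == 0L) return(0)
  mean(countOverlaps(query, reference, ignore.strand = TRUE) > 0)
}
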