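# Per-base coverage on a single chromosome, stored densely from base 1.
# bedGraph is the on-disk format (0-based half-open records, value column).

#' Construct a coverage track
#'
#' @param chrom chromosome name.
#' @param values per-base non-negative signal, position 1 = first base.
#' @param resolution bp per bin (only 1 is used by the pipeline).
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(chrom, values, resolution = 1L) {
  stopifnot(nzchar(chrom), resolution >= 1)
  values <- as.numeric(values)
  if (any(!is.finite(values))) stop("coverage values must be finite")
  if (any(values < 0)) stop("coverage values must be non-negative")
  structure(list(chrom = chrom, values = values, resolution = as.integer(resolution)),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("coverage_track: %s, %d bases, mean %.3f\n",
              x$chrom, length(x$values), mean(x$values)))
  invisible(x)
}

#' Read a bedGraph file into a coverage track
#'
#' Expands bedGraph records (0-based half-open) into a dense per-base vector;
#' uncovered bases are 0. Overlapping records and negative values are
#' rejected. Large synthetic tracks run to millions of rows, so the file is
#' read with `data.table::fread`.
#'
#' @param path bedGraph file.
#' @param chrom chromosome to extract; default: the first seen in the file.
#' @param length declared chromosome length; default: the largest record end.
#' @return A [coverage_track()].
#' @export
load_coverage <- function(path, chrom = NULL, length = NULL) {
  stopifnot(file.exists(path))
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "start", "end", "value"),
                          colClasses = list(character = 1),
                          skip = 0, blank.lines.skip = TRUE)
  dt <- dt[!grepl("^(#|track|browser)", dt$chrom), ]
  if (is.null(chrom)) chrom <- if (nrow(dt)) dt$chrom[1L] else stop("empty bedGraph and no chrom declared")
  dt <- dt[dt$chrom == chrom, ]
  if (is.null(length)) {
    if (nrow(dt) == 0L) stop("no records for chromosome and no length declared")
    length <- max(dt$end)
  }
  v <- numeric(length)
  if (nrow(dt)) {
    if (any(dt$value < 0)) stop("negative bedGraph values")
    o <- order(dt$start)
    dt <- dt[o, ]
    if (any(dt$start[-1L] < dt$end[-nrow(dt)]))
      stop("overlapping bedGraph records")
    if (any(dt$end > length)) stop("bedGraph record beyond declared length")
    # dense expansion via run boundaries
    n <- nrow(dt)
    starts <- dt$start + 1L
    ends <- dt$end
    idx <- sequence(ends - starts + 1L, from = starts)
    v[idx] <- rep(dt$value, ends - starts + 1L)
  }
  coverage_track(chrom, v)
}

#' Write a coverage track as bedGraph
#'
#' Emits maximal runs of equal value; zero runs are omitted (uncovered bases
#' read back as 0).
#'
#' @param track a [coverage_track()].
#' @param path output path.
#' @export
write_coverage <- function(track, path) {
  r <- rle(track$values)
  ends <- cumsum(r$lengths)
  starts0 <- ends - r$lengths
  keep <- r$values != 0
  dt <- data.table::data.table(chrom = track$chrom,
                               start = starts0[keep],
                               end = ends[keep],
                               value = r$values[keep])
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}
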