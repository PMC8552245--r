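# Window construction and coverage quantification: gene-body windows for
# histone-variant occupancy, promoter-associated peak windows for repressive
# promoter marks, and generic sum/mean quantification into a signal table.

#' Gene-body quantification windows
#'
#' Strand-aware window from the most upstream TSS advanced 500 bp in the
#' direction of transcription to the most downstream TTS. In 0-based
#' half-open terms: `[tss + offset, tts)` on plus, `[tts, tss - offset)` on
#' minus. Genes whose span is shorter than `min_gene_length` are excluded;
#' genes whose window would be empty or inverted are excluded with a warning.
#'
#' @param gm a [gene_models()] object.
#' @param offset bp to advance past the TSS (default 500).
#' @param min_gene_length minimum gene span length in bp (default 500).
#' @return A named `GRanges` (names = gene ids) with `kind = "gene_body"`.
#' @export
gene_body_windows <- function(gm, offset = 500L, min_gene_length = 500L) {
  ids <- gene_ids(gm)
  rows <- lapply(ids, function(g) {
    sp <- gm$genes[g]
    if (width(sp) < min_gene_length) return(NULL)
    tx <- gm$transcripts[[g]]
    if (as.character(strand(sp)) == "+") {
      s <- min(start(tx)) + offset
      e <- max(end(tx))
    } else {
      s <- min(start(tx))
      e <- max(end(tx)) - offset
    }
    if (s > e) return(NA)
    GRanges(seqnames(sp), IRanges(s, e), strand = strand(sp))
  })
  inverted <- vapply(rows, function(x) identical(x, NA), logical(1))
  if (any(inverted))
    warning(sprintf("%d gene(s) with empty or inverted body window excluded",
                    sum(inverted)))
  keep <- !inverted & !vapply(rows, is.null, logical(1))
  if (!any(keep)) return(GRanges())
  out <- do.call(c, rows[keep])
  names(out) <- ids[keep]
  mcols(out)$kind <- "gene_body"
  out
}

# strand-aware putative promoter regions, one per transcript TSS:
# [tss - upstream, tss) upstream of the TSS in 0-based half-open terms
promoter_regions <- function(gm, upstream = 500L) {
  ids <- gene_ids(gm)
  pieces <- lapply(ids, function(g) {
    sp <- gm$genes[g]
    tss <- tss_positions(gm, g)
    if (as.character(strand(sp)) == "+") {
      s <- pmax(tss - upstream, 1L); e <- tss - 1L
    } else {
      s <- tss + 1L; e <- tss + upstream
    }
    ok <- s <= e
    if (!any(ok)) return(NULL)
    GRanges(seqnames(sp), IRanges(s[ok], e[ok]),
            gene_id = rep(g, sum(ok)))
  })
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  if (length(pieces) == 0L) return(GRanges(gene_id = character(0)))
  do.call(c, pieces)
}

#' Promoter-associated peak windows
#'
#' Keeps peaks overlapping (>= 1 bp) the putative promoter region
#' (`upstream` bp immediately 5' of any transcript TSS, strand-aware) of any
#' gene; each kept peak becomes one window tagged with every gene whose
#' promoter region it touches.
#'
#' @param peaks a `GRanges` of peaks.
#' @param gm a [gene_models()] object.
#' @param upstream promoter extent upstream of the TSS (default 500 bp).
#' @return A `GRanges` subset of `peaks` with a comma-separated `gene_ids`
#'   column and `kind = "promoter_peak"`.
#' @export
promoter_peak_windows <- function(peaks, gm, upstream = 500L) {
  prom <- promoter_regions(gm, upstream)
  if (length(peaks) == 0L || length(prom) == 0L) return(GRanges())
  ov <- findOverlaps(peaks, prom, ignore.strand = TRUE)
  if (length(ov) == 0L) return(GRanges())
  hit_idx <- sort(unique(queryHits(ov)))
  gene_tags <- vapply(hit_idx, function(i) {
    g <- unique(prom$gene_id[subjectHits(ov)[queryHits(ov) == i]])
    paste(sort(g), collapse = ",")
  }, "")
  out <- peaks[hit_idx]
  mcols(out)$gene_ids <- gene_tags
  mcols(out)$kind <- "promoter_peak"
  out
}

#' Quantify coverage in feature windows
#'
#' Sums (or averages) per-base signal within each window, per sample.
#' Windows extending past a track are clipped with a warning; a sample
#' lacking a window's chromosome is an error naming the sample.
#'
#' @param tracks named list (by sample) of [coverage_track()] objects, or of
#'   named lists of tracks keyed by chromosome.
#' @param windows a named `GRanges` of feature windows.
#' @param mode `"sum"` or `"mean"`.
#' @return A numeric matrix, features x samples, with a `kind` attribute.
#' @export
quantify <- function(tracks, windows, mode = c("sum", "mean")) {
  mode <- match.arg(mode)
  stopifnot(length(tracks) >= 1L, !is.null(names(tracks)))
  ids <- names(windows)
  if (is.null(ids)) ids <- sprintf("feature_%d", seq_along(windows))
  out <- matrix(0, nrow = length(windows), ncol = length(tracks),
                dimnames = list(ids, names(tracks)))
  clipped <- FALSE
  for (s in names(tracks)) {
    tr <- tracks[[s]]
    for (ch in unique(as.character(seqnames(windows)))) {
      trk <- if (inherits(tr, "coverage_track")) {
        if (tr$chrom != ch) stop(sprintf("sample %s lacks chromosome %s", s, ch))
        tr
      } else {
        if (is.null(tr[[ch]])) stop(sprintf("sample %s lacks chromosome %s", s, ch))
        tr[[ch]]
      }
      n <- length(trk$values)
      cs <- c(0, cumsum(trk$values))
      sel <- which(as.character(seqnames(windows)) == ch)
      ss <- start(windows)[sel]; ee <- end(windows)[sel]
      if (any(ss < 1L) || any(ee > n)) clipped <- TRUE
      ss <- pmax(ss, 1L); ee <- pmin(ee, n)
      len <- pmax(ee - ss + 1L, 0L)
      val <- ifelse(len > 0, cs[ee + 1L] - cs[ss], 0)
      if (mode == "mean") val <- ifelse(len > 0, val / len, 0)
      out[sel, s] <- val
    }
  }
  if (clipped) warning("some windows extended beyond track bounds and were clipped")
  attr(out, "kind") <- unique(c(mcols(windows)$kind, character(0)))
  attr(out, "mode") <- mode
  out
}

#' Keep features in the top quantile of a reference sample
#'
#' Retains rows whose value in `reference_sample` is at least the
#' `1 - keep_fraction` quantile (linear interpolation, type 7) of that
#' sample; ties at the cutoff are retained and row order is preserved.
#'
#' @param table numeric matrix, features x samples.
#' @param reference_sample column name to rank by.
#' @param keep_fraction fraction to keep (default 0.90, the "top 90%" rule).
#' @return The filtered matrix.
#' @export
top_quantile_filter <- function(table, reference_sample, keep_fraction = 0.90) {
  stopifnot(keep_fraction > 0, keep_fraction <= 1)
  if (nrow(table) == 0L) return(table)
  if (!reference_sample %in% colnames(table))
    stop(sprintf("reference sample %s not in table", reference_sample))
  ref <- table[, reference_sample]
  cutoff <- quantile(ref, 1 - keep_fraction, type = 7, names = FALSE)
  table[ref >= cutoff, , drop = FALSE]
}
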