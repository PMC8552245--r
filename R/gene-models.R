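# Gene models: span + strand per gene, per-transcript extents, and optional
# promoter intervals. TSS/TTS are derived strand-aware from transcript
# extents (the TSS of a minus-strand transcript is its larger coordinate).

#' Construct a gene model set
#'
#' @param genes a named `GRanges` of gene spans (names = gene ids) with
#'   strand `+` or `-`.
#' @param transcripts named list (by gene id) of `IRanges`, one range per
#'   transcript (1-based closed extents).
#' @param promoters named list (by gene id) of `GRanges` promoter intervals;
#'   genes may be absent from the list (no promoter annotated).
#' @return An object of class `gene_models`.
#' @export
gene_models <- function(genes, transcripts, promoters = list()) {
  ids <- names(genes)
  if (is.null(ids) || anyDuplicated(ids) > 0L || any(ids == ""))
    stop("gene spans must carry unique, non-empty gene ids as names")
  if (!all(as.character(strand(genes)) %in% c("+", "-")))
    stop("gene strand must be + or -")
  if (!all(names(transcripts) %in% ids))
    stop("transcripts reference unknown gene ids")
  for (g in names(transcripts)) {
    tx <- transcripts[[g]]
    sp <- genes[g]
    if (any(start(tx) < start(sp)) || any(end(tx) > end(sp)))
      warning(sprintf("gene %s: transcript outside the declared span", g))
  }
  if (length(promoters) && !all(names(promoters) %in% ids))
    stop("promoters reference unknown gene ids")
  structure(list(genes = genes, transcripts = transcripts,
                 promoters = promoters),
            class = "gene_models")
}

#' @export
length.gene_models <- function(x) length(x$genes)

#' @export
print.gene_models <- function(x, ...) {
  n_prom <- sum(lengths(x$promoters) > 0)
  cat(sprintf("gene_models: %d genes (%d with promoter annotation)\n",
              length(x$genes), n_prom))
  invisible(x)
}

gene_ids <- function(gm) names(gm$genes)

# per-gene TSS positions (1-based bases): plus strand -> transcript starts,
# minus strand -> transcript ends
tss_positions <- function(gm, gene) {
  tx <- gm$transcripts[[gene]]
  if (as.character(strand(gm$genes[gene])) == "+") start(tx) else end(tx)
}

#' Read gene models from GFF3 (plus an optional promoter BED)
#'
#' GFF3 `gene` and `mRNA`/`transcript` features are read via rtracklayer
#' (1-based closed, matching the internal convention). mRNAs whose Parent is
#' not a known gene are skipped with a warning. Promoters come from an
#' auxiliary BED whose name column holds the gene id.
#'
#' @param path GFF3 file.
#' @param promoter_bed optional BED file of promoter intervals, name column =
#'   gene id.
#' @return A [gene_models()] object.
#' @export
load_gene_models <- function(path, promoter_bed = NULL) {
  gff <- rtracklayer::import(path, format = "gff3")
  is_gene <- gff$type == "gene"
  genes <- gff[is_gene]
  ids <- genes$ID
  if (is.null(ids) || any(is.na(ids))) stop("GFF3 gene features must carry ID attributes")
  names(genes) <- ids
  tx <- gff[gff$type %in% c("mRNA", "transcript")]
  transcripts <- list()
  if (length(tx)) {
    parent <- vapply(tx$Parent, function(p) if (length(p)) p[[1L]] else NA_character_, "")
    known <- parent %in% ids
    if (any(!known)) {
      warning(sprintf("%d mRNA feature(s) without a parent gene skipped", sum(!known)))
      tx <- tx[known]; parent <- parent[known]
    }
    transcripts <- split(ranges(tx), parent)
    transcripts <- lapply(as.list(transcripts), function(r) IRanges(start(r), end(r)))
  }
  # genes with no mRNA: treat the span as the single transcript
  missing_tx <- setdiff(ids, names(transcripts))
  for (g in missing_tx) transcripts[[g]] <- ranges(genes[g])
  promoters <- list()
  if (!is.null(promoter_bed)) {
    pb <- load_intervals(promoter_bed)
    pn <- mcols(pb)$name
    if (is.null(pn)) stop("promoter BED needs a name column holding gene ids")
    keep <- pn %in% ids
    if (any(!keep)) warning(sprintf("%d promoter(s) for unknown genes skipped", sum(!keep)))
    pb <- pb[keep]
    promoters <- lapply(split(pb, mcols(pb)$name), identity)
  }
  gene_models(granges(genes), transcripts, promoters)
}

#' Write gene models as GFF3 (plus a promoter BED)
#'
#' @param gm a [gene_models()] object.
#' @param path output GFF3 path.
#' @param promoter_bed optional path for the promoter BED.
#' @export
write_gene_models <- function(gm, path, promoter_bed = NULL) {
  lines <- c("##gff-version 3")
  for (g in gene_ids(gm)) {
    sp <- gm$genes[g]
    str <- as.character(strand(sp))
    lines <- c(lines, paste(as.character(seqnames(sp)), "dreamtargets", "gene",
                            start(sp), end(sp), ".", str, ".",
                            sprintf("ID=%s", g), sep = "\t"))
    tx <- gm$transcripts[[g]]
    for (i in seq_along(tx)) {
      lines <- c(lines, paste(as.character(seqnames(sp)), "dreamtargets", "mRNA",
                              start(tx)[i], end(tx)[i], ".", str, ".",
                              sprintf("ID=%s.t%d;Parent=%s", g, i, g), sep = "\t"))
    }
  }
  writeLines(lines, path)
  if (!is.null(promoter_bed)) {
    with_prom <- names(gm$promoters)[lengths(gm$promoters) > 0]
    if (length(with_prom)) {
      pr <- unlist(GRangesList(lapply(with_prom, function(g) {
        p <- gm$promoters[[g]]
        mcols(p) <- NULL
        mcols(p)$name <- rep(g, length(p))
        p
      })))
      names(pr) <- mcols(pr)$name
      write_intervals(pr, promoter_bed)
    } else {
      writeLines(character(0), promoter_bed)
    }
  }
  invisible(path)
}
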