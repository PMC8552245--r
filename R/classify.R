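# Peak-to-gene assignment and the target taxonomy: direct targets per
# factor, LIN-36-shared and LIN-15B-shared classes, overlap enrichment, and
# germline expression specificity.

#' Assign peaks to genes
#'
#' For genes with promoter annotation the assignment window runs from the
#' furthest upstream promoter (strand-aware) through the gene's 3' end; for
#' genes without an annotated promoter the window is the gene span
#' (fallback rule). A peak is assigned when it overlaps the window by at
#' least 1 bp; a peak may be assigned to several genes, and each assignment
#' records which rule fired.
#'
#' @param peaks a named `GRanges` of peaks.
#' @param gm a [gene_models()] object.
#' @return A `data.frame` with peak_id, gene_id and rule
#'   (`promoter_window` or `gene_span_fallback`).
#' @export
assign_peaks_to_genes <- function(peaks, gm) {
  ids <- gene_ids(gm)
  if (is.null(names(peaks))) names(peaks) <- sprintf("peak_%d", seq_along(peaks))
  win_list <- lapply(ids, function(g) {
    sp <- gm$genes[g]
    prom <- gm$promoters[[g]]
    has_prom <- !is.null(prom) && length(prom) > 0L
    if (has_prom) {
      if (as.character(strand(sp)) == "+") {
        s <- min(min(start(prom)), start(sp)); e <- end(sp)
      } else {
        s <- start(sp); e <- max(max(end(prom)), end(sp))
      }
    } else {
      s <- start(sp); e <- end(sp)
    }
    GRanges(seqnames(sp), IRanges(s, e),
            gene_id = g,
            rule = if (has_prom) "promoter_window" else "gene_span_fallback")
  })
  wins <- do.call(c, win_list)
  ov <- findOverlaps(peaks, wins, ignore.strand = TRUE)
  data.frame(peak_id = names(peaks)[queryHits(ov)],
             gene_id = wins$gene_id[subjectHits(ov)],
             rule = wins$rule[subjectHits(ov)],
             stringsAsFactors = FALSE)
}

#' Direct targets per factor
#'
#' A gene is a direct target of a factor when it is upregulated in that
#' factor's mutant and carries at least one assigned peak of that factor.
#'
#' @param up_genes named list (by factor) of upregulated gene-id vectors.
#' @param bound_genes named list (by factor) of gene-id vectors with >= 1
#'   assigned peak, e.g. derived from [assign_peaks_to_genes()].
#' @return Named list (by factor) of direct-target gene-id vectors.
#' @export
direct_targets <- function(up_genes, bound_genes) {
  factors <- names(up_genes)
  if (is.null(factors) || !all(factors %in% names(bound_genes)))
    stop("factor names must be consistent between up_genes and bound_genes")
  out <- lapply(factors, function(f) sort(intersect(up_genes[[f]], bound_genes[[f]])))
  names(out) <- factors
  out
}

#' Shared-target classes
#'
#' LIN-36-shared targets are direct targets of both LIN-35 and LIN-36 that
#' are not upregulated in the lin-15B mutant; LIN-15B-shared targets are
#' direct targets of both LIN-35 and LIN-15B not upregulated in the lin-36
#' mutant. The two classes are disjoint whenever each direct set is
#' contained in the corresponding up-set.
#'
#' @param direct35,direct36,direct15B direct-target gene sets.
#' @param up36,up15B genes upregulated in the lin-36 / lin-15B mutants.
#' @return list with `lin36_shared` and `lin15B_shared` gene-id vectors.
#' @export
shared_targets <- function(direct35, direct36, direct15B, up36, up15B) {
  list(lin36_shared = sort(setdiff(intersect(direct35, direct36), up15B)),
       lin15B_shared = sort(setdiff(intersect(direct35, direct15B), up36)))
}

#' Gene-set overlap enrichment
#'
#' Fold enrichment of the observed overlap over the expectation
#' |A||B|/|U|, with an exact upper-tail hypergeometric p-value.
#'
#' @param setA,setB gene-id vectors, subsets of `universe`.
#' @param universe gene-id vector.
#' @return list with `fold` (NA, flagged, when a set is empty), `p`,
#'   `overlap`, and `expected`.
#' @export
overlap_enrichment <- function(setA, setB, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  setA <- unique(setA); setB <- unique(setB)
  if (!all(setA %in% universe) || !all(setB %in% universe))
    stop("sets must be subsets of the universe")
  k <- length(intersect(setA, setB))
  expected <- length(setA) * length(setB) / length(universe)
  if (expected == 0) {
    return(list(fold = NA_real_, p = 1, overlap = k, expected = 0,
                degenerate = TRUE))
  }
  list(fold = k / expected,
       p = hypergeom_upper_tail(length(universe), length(setA), length(setB), k),
       overlap = k, expected = expected, degenerate = FALSE)
}

#' Germline expression specificity
#'
#' Per gene: germline TPM divided by the sum of TPM over all cell types.
#' Genes with zero total expression are flagged undefined (NA score) and
#' should be excluded from downstream comparisons.
#'
#' @param tpm numeric matrix, genes x cell types, in TPM.
#' @param germline_label column name of the germline cell type.
#' @return `data.frame` with gene_id, score and defined.
#' @export
germline_specificity <- function(tpm, germline_label) {
  tpm <- as.matrix(tpm)
  if (!germline_label %in% colnames(tpm))
    stop(sprintf("column %s not present", germline_label))
  if (any(tpm < 0)) stop("negative TPM values")
  total <- rowSums(tpm)
  score <- ifelse(total > 0, tpm[, germline_label] / total, NA_real_)
  ids <- rownames(tpm)
  if (is.null(ids)) ids <- sprintf("gene_%d", seq_len(nrow(tpm)))
  data.frame(gene_id = ids, score = score, defined = total > 0,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Compare specificity score distributions
#'
#' Two-sided Wilcoxon rank-sum test between two sets of specificity scores
#' (undefined scores dropped): exact null for small samples, tie-corrected
#' normal approximation otherwise.
#'
#' @param scoresA,scoresB numeric score vectors.
#' @return list with `U`, `p` and `method` (see [wilcoxon_rank_sum()]).
#' @export
compare_specificity <- function(scoresA, scoresB) {
  a <- scoresA[!is.na(scoresA)]
  b <- scoresB[!is.na(scoresB)]
  if (length(a) == 0L || length(b) == 0L) stop("empty score set")
  wilcoxon_rank_sum(a, b)
}
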