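# PWM scanning with exact p-values (FIMO-like), hierarchical overlap
# resolution of motif hits, inclusion filtering, and differential
# motif-association tests between peak classes.

MOTIF_FAMILIES <- c("CDE-CHR", "LONG", "E2F", "other")
PWM_SCORE_DELTA <- 1e-3  # log2-odds discretisation step for the exact null

pwm_bases <- c("A", "C", "G", "T")

infer_family <- function(motif_id) {
  if (grepl("^CDE-CHR", motif_id)) return("CDE-CHR")
  if (grepl("^LONG", motif_id)) return("LONG")
  if (grepl("^E2F", motif_id)) return("E2F")
  "other"
}

#' Construct a position weight matrix object
#'
#' @param motif_id motif name.
#' @param matrix L x 4 matrix of base probabilities (columns A, C, G, T);
#'   each row must sum to 1 within 1e-6 and L must be >= 4.
#' @param background named base probabilities summing to 1 (default
#'   uniform).
#' @param family one of CDE-CHR, LONG, E2F, other; default inferred from
#'   the motif id prefix.
#' @return An object of class `pwm`.
#' @export
pwm <- function(motif_id, matrix, background = NULL, family = NULL) {
  matrix <- as.matrix(matrix)
  colnames(matrix) <- pwm_bases
  if (nrow(matrix) < 4L) stop("PWM length must be >= 4")
  if (any(abs(rowSums(matrix) - 1) > 1e-6))
    stop("PWM rows must sum to 1")
  if (is.null(background)) background <- setNames(rep(0.25, 4), pwm_bases)
  background <- background[pwm_bases]
  if (abs(sum(background) - 1) > 1e-6) stop("background must sum to 1")
  if (is.null(family)) family <- infer_family(motif_id)
  if (!family %in% MOTIF_FAMILIES) stop(sprintf("unknown motif family %s", family))
  structure(list(motif_id = motif_id, matrix = matrix,
                 background = background, family = family),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm %s (%s), length %d\n", x$motif_id, x$family, nrow(x$matrix)))
  invisible(x)
}

reverse_complement_matrix <- function(mat) {
  out <- mat[rev(seq_len(nrow(mat))), c("T", "G", "C", "A"), drop = FALSE]
  colnames(out) <- pwm_bases
  out
}

# exact null distribution of the discretised score under the background
# model: returns smin and the upper-tail probabilities over the score grid
score_null_tail <- function(imat, bg) {
  L <- nrow(imat)
  rmin <- apply(imat, 1, min)
  rmax <- apply(imat, 1, max)
  smin <- sum(rmin); smax <- sum(rmax)
  d <- 1
  off <- 0L
  for (r in seq_len(L)) {
    width_new <- length(d) + (rmax[r] - rmin[r])
    nd <- numeric(width_new)
    for (b in 1:4) {
      sh <- imat[r, b] - rmin[r]
      idx <- seq_along(d) + sh
      nd[idx] <- nd[idx] + d * bg[b]
    }
    d <- nd
    off <- off + rmin[r]
  }
  tail_p <- rev(cumsum(rev(d)))
  list(smin = smin, smax = smax, tail = tail_p)
}

# pre-compute integer score matrices and exact nulls for both strands
compile_pwm <- function(p) {
  stopifnot(inherits(p, "pwm"))
  mat <- pmax(p$matrix, 1e-4)  # pseudo-probability floor for zero entries
  mat <- mat / rowSums(mat)
  bg <- p$background
  lo <- log2(sweep(mat, 2, bg, "/"))
  imat_f <- round(lo / PWM_SCORE_DELTA)
  rc <- reverse_complement_matrix(mat)
  lo_rc <- log2(sweep(rc, 2, bg, "/"))
  imat_r <- round(lo_rc / PWM_SCORE_DELTA)
  list(pwm = p,
       fwd = list(imat = imat_f, null = score_null_tail(imat_f, bg)),
       rev = list(imat = imat_r, null = score_null_tail(imat_r, bg)))
}

scan_one_strand <- function(codes, imat, null, strand, cutoff) {
  L <- nrow(imat)
  n <- length(codes)
  if (L > n) return(NULL)
  n_off <- n - L + 1L
  acc <- numeric(n_off)
  for (j in seq_len(L)) {
    cc <- codes[j:(j + n_off - 1L)]
    acc <- acc + imat[j, ][cc]  # NA at any N propagates: window skipped
  }
  ok <- !is.na(acc)
  if (!any(ok)) return(NULL)
  idx <- round(acc[ok]) - null$smin + 1L
  pv <- ifelse(idx < 1L, 1,
               ifelse(idx > length(null$tail), 0, null$tail[pmax(idx, 1L)]))
  keep <- pv <= cutoff
  if (!any(keep)) return(NULL)
  offs <- which(ok)[keep]
  data.frame(offset = offs, strand = strand,
             score = acc[ok][keep] * PWM_SCORE_DELTA,
             pvalue = pv[keep], stringsAsFactors = FALSE)
}

#' Scan a DNA sequence with a PWM
#'
#' Scores every window on both strands with the log2-odds of the PWM against
#' the background model and reports hits whose exact p-value (computed by
#' dynamic programming over the discretised score distribution, step 1e-3)
#' is at or below the cutoff. Windows containing N are skipped. Zero
#' probabilities are floored at 1e-4 before log-odds.
#'
#' @param sequence character DNA string over A, C, G, T, N.
#' @param p a [pwm()] (or a compiled PWM from the internal cache).
#' @param pvalue_cutoff report hits with p <= cutoff (default 1e-4).
#' @param peak_id optional id attached to the hits.
#' @return A `data.frame` of hits: peak_id, motif_id, family, offset
#'   (1-based start in the sequence), width, strand, score, pvalue.
#' @export
scan_pwm <- function(sequence, p, pvalue_cutoff = 1e-4, peak_id = NA_character_) {
  comp <- if (inherits(p, "pwm")) compile_pwm(p) else p
  codes <- match(strsplit(toupper(sequence), "")[[1L]], pwm_bases)
  L <- nrow(comp$fwd$imat)
  hits <- rbind(
    scan_one_strand(codes, comp$fwd$imat, comp$fwd$null, "+", pvalue_cutoff),
    scan_one_strand(codes, comp$rev$imat, comp$rev$null, "-", pvalue_cutoff))
  if (is.null(hits) || nrow(hits) == 0L)
    return(empty_hits())
  data.frame(peak_id = peak_id, motif_id = comp$pwm$motif_id,
             family = comp$pwm$family, offset = hits$offset, width = L,
             strand = hits$strand, score = hits$score, pvalue = hits$pvalue,
             stringsAsFactors = FALSE)
}

empty_hits <- function() {
  data.frame(peak_id = character(0), motif_id = character(0),
             family = character(0), offset = integer(0), width = integer(0),
             strand = character(0), score = numeric(0), pvalue = numeric(0),
             stringsAsFactors = FALSE)
}

#' Scan many peak sequences with many PWMs
#'
#' @param sequences named character vector (or `DNAStringSet`) of peak
#'   sequences; names are the peak ids.
#' @param pwms list of [pwm()] objects.
#' @param pvalue_cutoff hit cutoff (default 1e-4).
#' @return Combined hits `data.frame` (see [scan_pwm()]).
#' @export
scan_peaks <- function(sequences, pwms, pvalue_cutoff = 1e-4) {
  if (methods::is(sequences, "DNAStringSet"))
    sequences <- setNames(as.character(sequences), names(sequences))
  stopifnot(!is.null(names(sequences)))
  out <- list()
  for (p in pwms) {
    comp <- compile_pwm(p)
    for (id in names(sequences)) {
      h <- scan_pwm(sequences[[id]], comp, pvalue_cutoff, peak_id = id)
      if (nrow(h)) out[[length(out) + 1L]] <- h
    }
  }
  if (length(out) == 0L) return(empty_hits())
  do.call(rbind, out)
}

#' Resolve overlapping motif hits by family hierarchy
#'
#' Among hits overlapping by >= 1 bp on the same peak, the highest-priority
#' family wins (CDE-CHR over LONG over E2F, then other); within a family the
#' best (lowest p) hit is kept. Implemented as a greedy sweep in
#' (priority, p) order, which is idempotent; non-overlapping hits are
#' untouched.
#'
#' @param hits a hits `data.frame` (see [scan_pwm()]).
#' @return The surviving subset of `hits`.
#' @export
resolve_overlaps <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  if (any(!hits$family %in% MOTIF_FAMILIES))
    stop("unknown motif family in hits")
  rank <- match(hits$family, MOTIF_FAMILIES)
  keep_rows <- integer(0)
  for (pk in unique(hits$peak_id)) {
    idx <- which(hits$peak_id == pk)
    ord <- idx[order(rank[idx], hits$pvalue[idx], hits$offset[idx])]
    kept_s <- integer(0); kept_e <- integer(0); kept <- integer(0)
    for (i in ord) {
      s <- hits$offset[i]; e <- hits$offset[i] + hits$width[i] - 1L
      if (!any(s <= kept_e & e >= kept_s)) {
        kept <- c(kept, i); kept_s <- c(kept_s, s); kept_e <- c(kept_e, e)
      }
    }
    keep_rows <- c(keep_rows, kept)
  }
  hits[sort(keep_rows), , drop = FALSE]
}

peak_id_vector <- function(x) {
  if (methods::is(x, "GRanges")) {
    if (is.null(names(x))) stop("peak set needs names (peak ids)")
    return(names(x))
  }
  as.character(x)
}

#' Inclusion filter for motifs
#'
#' A motif is kept when the fraction of peaks containing at least one
#' surviving hit exceeds `min_fraction` (strictly) in at least one class.
#'
#' @param hits a hits `data.frame` (after [resolve_overlaps()]).
#' @param peak_sets named list of peak classes; each element a character
#'   vector of peak ids (or a named `GRanges`).
#' @param min_fraction strict inclusion threshold (default 0.30).
#' @return Character vector of motif ids kept.
#' @export
inclusion_filter <- function(hits, peak_sets, min_fraction = 0.30) {
  stopifnot(length(peak_sets) >= 1L)
  motifs <- unique(hits$motif_id)
  kept <- character(0)
  fracs <- list()
  for (cls in names(peak_sets)) {
    ids <- peak_id_vector(peak_sets[[cls]])
    if (length(ids) == 0L) {
      warning(sprintf("empty peak set for class %s skipped", cls))
      next
    }
    fr <- vapply(motifs, function(m)
      mean(ids %in% hits$peak_id[hits$motif_id == m]), numeric(1))
    fracs[[cls]] <- fr
  }
  if (length(fracs) == 0L) return(character(0))
  for (m in motifs)
    if (any(vapply(fracs, function(fr) fr[[m]] > min_fraction, logical(1))))
      kept <- c(kept, m)
  kept
}

#' Differential motif association between two peak classes
#'
#' Per motif, a 2x2 table (contains / lacks x class A / class B) tested
#' with the two-sided Fisher exact test, BH-corrected across motifs.
#'
#' @param peaksA,peaksB character vectors of peak ids (or named `GRanges`),
#'   disjointly labelled.
#' @param hits a hits `data.frame`.
#' @param motif_ids motifs to test (default: all motifs present in `hits`).
#' @return `data.frame` with motif_id, frac_a, frac_b, odds_ratio, p, padj.
#' @export
association_test <- function(peaksA, peaksB, hits, motif_ids = NULL) {
  a_ids <- peak_id_vector(peaksA)
  b_ids <- peak_id_vector(peaksB)
  if (length(intersect(a_ids, b_ids)))
    stop("peak classes must be disjoint")
  if (is.null(motif_ids)) motif_ids <- unique(hits$motif_id)
  rows <- lapply(motif_ids, function(m) {
    with_m <- unique(hits$peak_id[hits$motif_id == m])
    a <- sum(a_ids %in% with_m); b <- sum(b_ids %in% with_m)
    ft <- fisher_exact_two_sided(a, b, length(a_ids) - a, length(b_ids) - b)
    data.frame(motif_id = m,
               frac_a = if (length(a_ids)) a / length(a_ids) else NA_real_,
               frac_b = if (length(b_ids)) b / length(b_ids) else NA_real_,
               odds_ratio = ft$odds_ratio, p = ft$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- if (nrow(out)) bh_adjust(out$p) else numeric(0)
  out
}

#' Read PWMs from MEME minimal motif format
#'
#' Parses the minimal text format (MEME version, optional background
#' frequencies, `MOTIF` blocks with letter-probability matrices). Families
#' are inferred from the motif id prefix (CDE-CHR*, LONG*, E2F*), or
#' overridden via `family_map`.
#'
#' @param path MEME minimal format file.
#' @param family_map optional named character vector motif_id -> family.
#' @return List of [pwm()] objects.
#' @export
read_meme <- function(path, family_map = NULL) {
  lines <- readLines(path)
  bg <- setNames(rep(0.25, 4), pwm_bases)
  i_bg <- grep("^Background letter frequencies", lines)
  if (length(i_bg)) {
    toks <- strsplit(trimws(lines[i_bg[1L] + 1L]), "\\s+")[[1L]]
    vals <- as.numeric(toks[seq(2, length(toks), 2)])
    names(vals) <- toks[seq(1, length(toks), 2)]
    bg <- vals[pwm_bases]
  }
  starts <- grep("^MOTIF\\b", lines)
  pwms <- list()
  for (s in starts) {
    id <- strsplit(trimws(lines[s]), "\\s+")[[1L]][2L]
    hdr <- grep("^letter-probability matrix", lines[s:length(lines)])[1L] + s - 1L
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr]))
    rows <- lines[(hdr + 1L):(hdr + w)]
    mat <- do.call(rbind, lapply(rows, function(r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1L]])))
    fam <- if (!is.null(family_map) && id %in% names(family_map))
      family_map[[id]] else NULL
    pwms[[length(pwms) + 1L]] <- pwm(id, mat, background = bg, family = fam)
  }
  pwms
}

#' Write PWMs in MEME minimal motif format
#'
#' @param pwms list of [pwm()] objects.
#' @param path output path.
#' @export
write_meme <- function(pwms, path) {
  bg <- pwms[[1L]]$background
  lines <- c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -", "",
             "Background letter frequencies",
             sprintf("A %.5f C %.5f G %.5f T %.5f", bg["A"], bg["C"], bg["G"], bg["T"]),
             "")
  for (p in pwms) {
    lines <- c(lines,
               sprintf("MOTIF %s", p$motif_id),
               sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                       nrow(p$matrix)),
               apply(p$matrix, 1, function(r) sprintf(" %.6f %.6f %.6f %.6f",
                                                      r[1], r[2], r[3], r[4])),
               "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Extract peak sequences from a genome
#'
#' @param peaks a named `GRanges`.
#' @param genome a `DNAStringSet` keyed by chromosome.
#' @return Named character vector of sequences.
#' @export
get_peak_sequences <- function(peaks, genome) {
  if (is.null(names(peaks))) stop("peaks need names")
  out <- vapply(seq_along(peaks), function(i) {
    ch <- as.character(seqnames(peaks))[i]
    if (!ch %in% names(genome)) stop(sprintf("chromosome %s not in genome", ch))
    n <- length(genome[[ch]])
    s <- max(1L, start(peaks)[i]); e <- min(n, end(peaks)[i])
    as.character(Biostrings::subseq(genome[[ch]], s, e))
  }, "")
  setNames(out, names(peaks))
}
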