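suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

# random interval set on a small genome (1-based closed GRanges)
random_peaks <- function(n, max_pos = 1000, chroms = "chr1", width_max = 50) {
  s <- sample.int(max_pos, n, replace = TRUE)
  w <- sample.int(width_max, n, replace = TRUE)
  GRanges(sample(chroms, n, replace = TRUE), IRanges(s, s + w - 1L))
}

# boolean-mask oracle: covered bases of a peak set per chromosome
coverage_mask <- function(gr, max_pos = 2000) {
  masks <- list()
  for (ch in unique(as.character(seqnames(gr)))) {
    m <- logical(max_pos)
    sub <- gr[seqnames(gr) == ch]
    for (i in seq_along(sub)) m[start(sub)[i]:end(sub)[i]] <- TRUE
    masks[[ch]] <- m
  }
  masks
}

# naive O(n*k) convolution with reflective boundary (oracle for smoothing)
naive_smooth <- function(v, bandwidth, truncation = 4) {
  h <- ceiling(bandwidth * truncation)
  k <- dnorm(seq.int(-h, h), sd = bandwidth)
  k <- k / sum(k)
  n <- length(v)
  xp <- c(v[h:1], v, v[n:(n - h + 1L)])
  out <- numeric(n)
  for (i in seq_len(n)) out[i] <- sum(xp[i:(i + 2 * h)] * k)
  out
}

# reference BH step-up, written as the literal definition: walk from the
# largest p-value down, scaling by m/rank and taking a running minimum
reference_bh <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  adj <- numeric(m)
  prev <- 1
  for (i in seq_len(m)) {
    rank <- m - i + 1L
    prev <- min(prev, p[o[i]] * m / rank)
    adj[o[i]] <- prev
  }
  adj
}

# toy two-gene annotation used by several quantification tests
toy_gene_models <- function() {
  genes <- GRanges("chr1", IRanges(c(1001, 5001), c(3000, 6200)),
                   strand = c("+", "-"))
  names(genes) <- c("gA", "gB")
  transcripts <- list(gA = IRanges(1001, 3000), gB = IRanges(5001, 6200))
  promoters <- list(gA = GRanges("chr1", IRanges(501, 1000)))
  gene_models(genes, transcripts, promoters)
}

# consensus-style PWM with a dominant base per position
consensus_pwm <- function(id, consensus, dominant = 0.985, family = NULL) {
  L <- nchar(consensus)
  bases <- c("A", "C", "G", "T")
  m <- matrix((1 - dominant) / 3, L, 4, dimnames = list(NULL, bases))
  for (i in seq_len(L)) m[i, substr(consensus, i, i)] <- dominant
  pwm(id, m, family = family)
}

# brute-force exact PWM p-value by enumerating all 4^L words; with
# discretize = TRUE the word scores are binned exactly like the
# implementation (1e-3 log2-odds units), making the comparison exact
enumerate_pwm_pvalue <- function(p, scores, bg = rep(0.25, 4),
                                 discretize = FALSE) {
  mat <- pmax(p$matrix, 1e-4)
  mat <- mat / rowSums(mat)
  lo <- log2(sweep(mat, 2, bg, "/"))
  if (discretize) lo <- round(lo / 1e-3)
  L <- nrow(lo)
  words <- as.matrix(expand.grid(rep(list(1:4), L)))
  wscore <- numeric(nrow(words))
  wprob <- rep(1, nrow(words))
  for (j in seq_len(L)) {
    wscore <- wscore + lo[j, words[, j]]
    wprob <- wprob * bg[words[, j]]
  }
  if (discretize) scores <- round(scores / 1e-3)
  vapply(scores, function(s) sum(wprob[wscore >= s - 1e-6]), numeric(1))
}
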