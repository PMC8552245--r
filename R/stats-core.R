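# var/median/quantile come in through the IRanges generics (same defaults)
#' @importFrom stats dnorm pnorm pt ppois rnbinom rpois runif setNames
#'   rlnorm rgamma rbeta
#' @importFrom utils head tail
NULL

# log(sum(exp(x))) without overflow; used by the exact tail sums
logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

log_hyper_pmf <- function(N, K, n, k) {
  lchoose(K, k) + lchoose(N - K, n - k) - lchoose(N, n)
}

#' Upper-tail hypergeometric probability
#'
#' Exact P(X >= k) for X ~ Hypergeometric(N, K, n): the probability of drawing
#' at least `k` successes in `n` draws without replacement from a universe of
#' `N` items of which `K` are successes. Computed in log space so that
#' astronomically small overlap p-values (the kind gene-set enrichment tests
#' produce) do not underflow to zero prematurely.
#'
#' @param N universe size.
#' @param K number of successes in the universe.
#' @param n number of draws.
#' @param k observed number of successes among the draws.
#' @return The exact upper-tail probability, a single number in (0, 1].
#' @export
hypergeom_upper_tail <- function(N, K, n, k) {
  stopifnot(length(N) == 1L, length(K) == 1L, length(n) == 1L, length(k) == 1L)
  if (any(c(N, K, n, k) < 0) || K > N || n > N)
    stop("inconsistent hypergeometric parameters")
  if (k > min(K, n)) stop("k exceeds min(K, n): inconsistent parameters")
  if (k <= max(0L, K + n - N)) return(1)
  i <- seq.int(k, min(K, n))
  exp(logsumexp(log_hyper_pmf(N, K, n, i)))
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Enumerates all tables with the observed margins and sums the probabilities
#' of those no more likely than the observed one (the standard two-sided
#' definition). The reported odds ratio is the sample odds ratio
#' (a*d)/(b*c), not the conditional MLE.
#'
#' @param a,b,c,d cell counts of the table rbind(c(a, b), c(c, d)).
#' @return list with `odds_ratio` (may be `Inf` or `NaN` for zero margins,
#'   flagged by `degenerate`) and `p`.
#' @export
fisher_exact_two_sided <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  stopifnot(length(cells) == 4L, all(cells >= 0), all(cells == round(cells)))
  if (sum(cells) == 0L) stop("empty table")
  r1 <- a + b; c1 <- a + c; N <- sum(cells)
  degenerate <- (b * c == 0) || (a * d == 0 && b * c == 0)
  or <- if (b * c == 0) {
    if (a * d == 0) NaN else Inf
  } else (a * d) / (b * c)
  if (r1 == 0 || r1 == N || c1 == 0 || c1 == N)
    return(list(odds_ratio = or, p = 1, degenerate = TRUE))
  lo <- max(0L, r1 + c1 - N); hi <- min(r1, c1)
  ii <- seq.int(lo, hi)
  lp <- log_hyper_pmf(N, c1, r1, ii)
  lobs <- log_hyper_pmf(N, c1, r1, a)
  keep <- lp <= lobs + 1e-7  # numerical slack on the equal-probability rule
  p <- min(1, exp(logsumexp(lp[keep])))
  list(odds_ratio = or, p = p, degenerate = degenerate)
}

# number of ways to choose `n` distinct ranks from 1..N with a given rank sum,
# as a vector over all attainable sums (exact Wilcoxon null by DP)
rank_sum_counts <- function(n, N) {
  smin <- n * (n + 1) / 2
  smax <- n * (2 * N - n + 1) / 2
  width <- smax - smin + 1
  # f[j+1, s] = ways to pick j ranks among 1..i summing to s (offset by smin_j)
  f <- vector("list", n + 1L)
  f[[1L]] <- 1  # empty selection, sum 0
  offs <- c(0, cumsum(seq_len(n)))  # minimal sum for j chosen of smallest ranks
  for (j in seq_len(n)) f[[j + 1L]] <- numeric(0)
  for (i in seq_len(N)) {
    for (j in rev(seq_len(min(i, n)))) {
      prev <- f[[j]]
      if (length(prev) == 0L) next
      # adding rank i to selections of size j-1
      lo_prev <- offs[j]
      newsums <- seq.int(lo_prev, lo_prev + length(prev) - 1L) + i
      cur <- f[[j + 1L]]
      lo_cur <- offs[j + 1L]
      need <- max(newsums) - lo_cur + 1L
      if (length(cur) < need) cur <- c(cur, numeric(need - length(cur)))
      idx <- newsums - lo_cur + 1L
      cur[idx] <- cur[idx] + prev
      f[[j + 1L]] <- cur
    }
  }
  counts <- f[[n + 1L]]
  full <- numeric(width)
  full[seq_along(counts)] <- counts
  list(sums = seq.int(smin, smax), counts = full)
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact permutation null (via dynamic programming over rank sums) when the
#' smaller group has at most `exact_max` observations and there are no ties;
#' otherwise the normal approximation with tie-corrected variance and
#' continuity correction.
#'
#' @param x,y numeric samples.
#' @param exact_max largest min(n) for which the exact null is used.
#' @return list with `U` (Mann-Whitney statistic for `x`), `p` (two-sided),
#'   and `method` ("exact" or "normal").
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max = 10L) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L) stop("empty input sample")
  n <- length(x); m <- length(y); N <- n + m
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n)])
  U <- W - n * (n + 1) / 2
  has_ties <- anyDuplicated(c(x, y)) > 0L
  if (!has_ties && min(n, m) <= exact_max) {
    dp <- rank_sum_counts(n, N)
    total <- choose(N, n)
    lower <- sum(dp$counts[dp$sums <= W]) / total
    upper <- sum(dp$counts[dp$sums >= W]) / total
    p <- min(1, 2 * min(lower, upper))
    return(list(U = U, p = p, method = "exact"))
  }
  mu <- n * m / 2
  tie_tab <- table(r)
  tie_term <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
  v <- n * m / 12 * ((N + 1) - tie_term)
  if (v <= 0) return(list(U = U, p = 1, method = "normal"))
  z <- (U - mu - sign(U - mu) * 0.5) / sqrt(v)
  list(U = U, p = min(1, 2 * pnorm(-abs(z))), method = "normal")
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom and a
#' two-sided p-value. Degenerate inputs (both variances zero) give p = 1 when
#' the means agree and p = 0, flagged, when they differ.
#'
#' @param x,y numeric samples, each of length >= 2.
#' @return list with `t`, `df`, `p`, and `degenerate`.
#' @export
welch_t <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2L || length(y) < 2L) stop("need >= 2 observations per sample")
  mx <- mean(x); my <- mean(y)
  vx <- var(x); vy <- var(y)
  nx <- length(x); ny <- length(y)
  if (vx == 0 && vy == 0) {
    if (mx == my) return(list(t = 0, df = NA_real_, p = 1, degenerate = TRUE))
    return(list(t = sign(mx - my) * Inf, df = NA_real_, p = 0, degenerate = TRUE))
  }
  se2 <- vx / nx + vy / ny
  tt <- (mx - my) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = tt, df = df, p = 2 * pt(-abs(tt), df), degenerate = FALSE)
}
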