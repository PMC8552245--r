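# Peak detection: candidate peaks are concave regions (negative second
# difference) of Gaussian-smoothed coverage; candidates are then filtered by
# replicate support. Broad enriched domains (for repressive histone marks)
# are called by a local-Poisson sliding-window test.

#' Smoothing configuration
#'
#' @param bandwidth Gaussian sigma in bp. Default 75 bp, on the order of the
#'   ChIP fragment scale (~250 bp fragments).
#' @param truncation kernel half-width in sigmas (>= 2).
#' @export
smoothing_config <- function(bandwidth = 75, truncation = 4) {
  stopifnot(bandwidth > 0, truncation >= 2)
  structure(list(bandwidth = bandwidth, truncation = truncation),
            class = "smoothing_config")
}

gaussian_kernel <- function(config) {
  h <- ceiling(config$bandwidth * config$truncation)
  k <- dnorm(seq.int(-h, h), sd = config$bandwidth)
  k / sum(k)
}

# linear convolution via FFT: c[m] = sum_j x[j] k[m - j + 1]
fft_convolve <- function(x, k) {
  n_out <- length(x) + length(k) - 1L
  nf <- stats::nextn(n_out, 2)
  xf <- stats::fft(c(x, numeric(nf - length(x))))
  kf <- stats::fft(c(k, numeric(nf - length(k))))
  out <- Re(stats::fft(xf * kf, inverse = TRUE)) / nf
  out[seq_len(n_out)]
}

#' Gaussian smoothing of a coverage track
#'
#' Discrete Gaussian convolution with a reflective boundary; output length
#' equals input length and interior-supported signal mass is conserved.
#'
#' @param track a [coverage_track()].
#' @param config a [smoothing_config()].
#' @return A smoothed [coverage_track()].
#' @export
smooth_coverage <- function(track, config = smoothing_config()) {
  if (!inherits(config, "smoothing_config")) stop("config must be a smoothing_config")
  v <- track$values
  n <- length(v)
  kern <- gaussian_kernel(config)
  h <- (length(kern) - 1L) %/% 2L
  if (n <= h) stop("track shorter than the smoothing kernel half-width")
  xp <- c(v[h:1], v, v[n:(n - h + 1L)])  # reflective padding
  sm <- fft_convolve(xp, kern)[seq_len(n) + 2L * h]
  sm[sm < 0] <- 0  # clip FFT ringing at tiny negative values
  coverage_track(track$chrom, sm, track$resolution)
}

#' Call candidate peaks as concave regions of smoothed coverage
#'
#' A base belongs to a candidate peak when the central second difference of
#' the smoothed track is negative and the smoothed value is at least
#' `min_height`. Maximal such runs (>= 3 bp) become peaks, scored by their
#' maximum smoothed height.
#'
#' @param track a [coverage_track()].
#' @param config a [smoothing_config()].
#' @param min_height minimum smoothed signal for a base to qualify.
#' @return A `GRanges` of peaks with a `score` column.
#' @export
call_concave_peaks <- function(track, config = smoothing_config(), min_height = 0) {
  sm <- smooth_coverage(track, config)
  s <- sm$values
  n <- length(s)
  if (n < 3L) return(GRanges())
  d2 <- s[1:(n - 2L)] - 2 * s[2:(n - 1L)] + s[3:n]  # centred at 2..(n-1)
  # relative epsilon absorbs FFT rounding ripple on flat stretches while
  # keeping calls invariant to amplitude scaling
  eps <- 1e-9 * max(1, max(s))
  mask <- logical(n)
  mask[2:(n - 1L)] <- (d2 < -eps) & (s[2:(n - 1L)] >= min_height)
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= 3L
  if (!any(keep)) return(GRanges())
  starts <- starts[keep]; ends <- ends[keep]
  score <- vapply(seq_along(starts),
                  function(i) max(s[starts[i]:ends[i]]), numeric(1))
  gr <- GRanges(track$chrom, IRanges(starts, ends), score = score)
  names(gr) <- sprintf("%s_peak_%d", track$chrom, seq_along(gr))
  gr
}

#' Replicate-reproducibility filter for candidate peaks
#'
#' Candidate peaks are the merged union of all replicate peak sets; a
#' candidate is kept when it overlaps (>= 1 bp) peaks from at least
#' `min_support` distinct replicates. A documented, simpler stand-in for IDR.
#'
#' @param replicate_sets list (length >= 2) of `GRanges` peak sets.
#' @param min_support minimum number of supporting replicates.
#' @return A `GRanges` of reproducible merged peaks with a `support` column.
#' @export
reproducible_peaks <- function(replicate_sets, min_support = 2L) {
  stopifnot(is.list(replicate_sets), length(replicate_sets) >= 2L)
  if (min_support > length(replicate_sets))
    stop("min_support exceeds the number of replicates")
  if (min_support < 1L) stop("min_support must be >= 1")
  pooled <- do.call(c, unname(lapply(replicate_sets, granges)))
  cand <- merge_intervals(pooled)
  if (length(cand) == 0L) return(cand)
  support <- Reduce(`+`, lapply(replicate_sets, function(r)
    as.integer(countOverlaps(cand, r, ignore.strand = TRUE) > 0)))
  out <- cand[support >= min_support]
  mcols(out)$support <- support[support >= min_support]
  names(out) <- sprintf("rep_peak_%d", seq_along(out))
  out
}

#' Domain-calling configuration
#'
#' Defaults: 50 kb local background window, 2-fold enrichment, 500 bp
#' minimum domain length, Poisson upper-tail p < 1e-5. A documented
#' stand-in for broad-mark peak calling with MACS "standard settings".
#' The local window guards against broad regional background variation; it
#' must stay large relative to the domains being called, or genuine
#' enrichment masks itself (hence the 50 kb default for up-to-5 kb
#' domains).
#'
#' @param window bp of local background.
#' @param fold_threshold required enrichment over background.
#' @param min_length bp; shorter domains are dropped (also the sliding test
#'   window size).
#' @param pvalue_threshold Poisson upper-tail cutoff.
#' @export
domain_call_config <- function(window = 50000, fold_threshold = 2,
                               min_length = 500, pvalue_threshold = 1e-5) {
  stopifnot(window > 0, fold_threshold > 0, min_length > 0, pvalue_threshold > 0)
  structure(list(window = window, fold_threshold = fold_threshold,
                 min_length = min_length, pvalue_threshold = pvalue_threshold),
            class = "domain_call_config")
}

rolling_clipped_mean <- function(cs, n, half) {
  centers <- seq_len(n)
  lo <- pmax(centers - half, 1L)
  hi <- pmin(centers + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Call broad enriched domains by a local-Poisson test
#'
#' Slides a `min_length`-bp window over the track; the window sum is tested
#' against a Poisson rate of max(global mean, local mean over `window`) x
#' window size. Qualifying windows (upper-tail p below threshold and fold at
#' least `fold_threshold`) are unioned; domains shorter than `min_length`
#' are dropped.
#'
#' @param track a [coverage_track()].
#' @param config a [domain_call_config()].
#' @return A `GRanges` of domains.
#' @export
call_enriched_domains <- function(track, config = domain_call_config()) {
  v <- track$values
  n <- length(v)
  if (n == 0L) stop("empty track")
  g <- mean(v)
  if (g == 0) return(GRanges())
  w <- min(as.integer(config$min_length), n)
  cs <- c(0, cumsum(v))
  n_win <- n - w + 1L
  wsum <- cs[(w + 1L):(n + 1L)] - cs[1L:n_win]
  local_mean <- rolling_clipped_mean(cs, n, as.integer(config$window) %/% 2L)
  centers <- pmin(seq_len(n_win) + w %/% 2L, n)
  lambda <- pmax(g, local_mean[centers]) * w
  p <- ppois(wsum - 1, lambda, lower.tail = FALSE)
  hit <- (p < config$pvalue_threshold) & (wsum / lambda >= config$fold_threshold)
  if (!any(hit)) return(GRanges())
  starts <- which(hit)
  dom <- reduce(GRanges(track$chrom, IRanges(starts, starts + w - 1L)))
  dom <- dom[width(dom) >= config$min_length]
  if (length(dom)) names(dom) <- sprintf("domain_%d", seq_along(dom))
  dom
}
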