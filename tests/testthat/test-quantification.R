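# Window construction (gene bodies, promoter peaks) and coverage
# quantification into signal tables.

test_that("gene-body windows advance the TSS 500 bp strand-aware", {
  # + strand gene, 0-based TSS 1000, TTS 3000 -> window [1500,3000)
  genes <- GRanges("chr1", IRanges(1001, 3000), strand = "+")
  names(genes) <- "gplus"
  gm <- gene_models(genes, list(gplus = IRanges(1001, 3000)))
  w <- gene_body_windows(gm)
  expect_equal(start(w), 1501L)
  expect_equal(end(w), 3000L)

  # - strand gene, 0-based TSS 3000, TTS 1000 -> window [1000,2500)
  genes2 <- GRanges("chr1", IRanges(1001, 3000), strand = "-")
  names(genes2) <- "gminus"
  gm2 <- gene_models(genes2, list(gminus = IRanges(1001, 3000)))
  w2 <- gene_body_windows(gm2)
  expect_equal(start(w2), 1001L)
  expect_equal(end(w2), 2500L)

  # genes shorter than 500 bp are excluded
  short <- GRanges("chr1", IRanges(100, 499), strand = "+")
  names(short) <- "gshort"
  gm3 <- gene_models(short, list(gshort = IRanges(100, 499)))
  expect_length(gene_body_windows(gm3), 0L)
})

test_that("gene-body windows use the most upstream TSS and are order-invariant", {
  genes <- GRanges("chr1", IRanges(c(1001, 9001), c(3000, 12000)),
                   strand = c("+", "-"))
  names(genes) <- c("a", "b")
  tx <- list(a = IRanges(c(1001, 1101), c(3000, 2900)),
             b = IRanges(c(9001, 9051), c(12000, 11800)))
  gm <- gene_models(genes, tx)
  w <- gene_body_windows(gm)
  expect_equal(start(w["a"]), 1501L)  # 5'-most TSS = 1001
  expect_equal(end(w["b"]), 11500L)  # 5'-most TSS on minus = end 12000
  gm_r <- gene_models(rev(genes), rev(tx))
  w_r <- gene_body_windows(gm_r)
  expect_equal(sort(names(w_r)), sort(names(w)))
  expect_equal(ranges(w_r[names(w)]), ranges(w))
})

test_that("promoter peak windows keep peaks touching a [TSS-500,TSS) region", {
  gm <- toy_gene_models()  # gA: + strand TSS 1001 -> promoter [501,1000]
  peaks <- GRanges("chr1", IRanges(c(901, 1201), c(1100, 1400)))
  names(peaks) <- c("pk_in", "pk_out")
  w <- promoter_peak_windows(peaks, gm)
  expect_equal(names(w), "pk_in")
  expect_equal(w$gene_ids, "gA")
  expect_equal(w$kind, "promoter_peak")
})

test_that("promoter peak windows match a brute-force oracle on random annotation", {
  set.seed(71)
  n <- 30
  starts <- sort(sample.int(5e4, n)) + seq_len(n) * 2500L
  genes <- GRanges("chr1", IRanges(starts, starts + 900L),
                   strand = sample(c("+", "-"), n, TRUE))
  ids <- sprintf("g%02d", seq_len(n))
  names(genes) <- ids
  tx <- setNames(lapply(seq_len(n), function(i) IRanges(starts[i], starts[i] + 900L)), ids)
  gm <- gene_models(genes, tx)
  peaks <- random_peaks(200, max_pos = max(end(genes)) + 1000, width_max = 300)
  names(peaks) <- sprintf("pk%03d", seq_along(peaks))
  w <- promoter_peak_windows(peaks, gm, upstream = 500)
  # oracle: strand-aware promoter intervals, any >= 1 bp overlap
  prom_s <- ifelse(strand(genes) == "+", starts - 500L, starts + 901L)
  prom_e <- ifelse(strand(genes) == "+", starts - 1L, starts + 1400L)
  keep <- vapply(seq_along(peaks), function(i)
    any(start(peaks)[i] <= prom_e & end(peaks)[i] >= prom_s), logical(1))
  expect_setequal(names(w), names(peaks)[keep])
})

test_that("quantify sums and averages per-base signal", {
  tr <- coverage_track("chr1", rep(2, 1000))
  w <- GRanges("chr1", IRanges(101, 200))
  names(w) <- "f1"
  expect_equal(quantify(list(s1 = tr), w, "sum")["f1", "s1"], 200)
  expect_equal(quantify(list(s1 = tr), w, "mean")["f1", "s1"], 2)
  expect_error(quantify(list(s1 = tr), GRanges("chrZ", IRanges(1, 5))),
               "lacks chromosome")
})

test_that("quantify matches a per-base loop and is additive over partitions", {
  set.seed(81)
  v <- rpois(2000, 3)
  tr <- coverage_track("chr1", v)
  w <- random_peaks(50, max_pos = 1900, width_max = 80)
  names(w) <- sprintf("w%02d", seq_along(w))
  got <- quantify(list(s = tr), w, "sum")[, "s"]
  want <- vapply(seq_along(w), function(i) sum(v[start(w)[i]:end(w)[i]]), numeric(1))
  expect_equal(unname(got), want)

  whole <- GRanges("chr1", IRanges(301, 900)); names(whole) <- "whole"
  parts <- GRanges("chr1", IRanges(c(301, 501, 701), c(500, 700, 900)))
  names(parts) <- c("p1", "p2", "p3")
  expect_equal(sum(quantify(list(s = tr), parts, "sum")[, "s"]),
               quantify(list(s = tr), whole, "sum")["whole", "s"])
})

test_that("top-quantile filter keeps the top 90% with ties retained", {
  tab <- cbind(N2 = c(10, 1, 2, 3, 4, 5, 6, 7, 8, 9), other = 1:10)
  rownames(tab) <- letters[1:10]
  kept <- top_quantile_filter(tab, "N2", 0.90)
  expect_equal(nrow(kept), 9L)
  expect_false("b" %in% rownames(kept))  # lowest value dropped
  expect_equal(rownames(kept), setdiff(letters[1:10], "b"))  # order preserved

  expect_identical(top_quantile_filter(tab, "N2", 1), tab)

  # ties at the cutoff retained; equals a sort-and-slice >= cutoff oracle
  set.seed(91)
  for (rep in 1:20) {
    ref <- sample(1:8, 40, replace = TRUE)
    tab2 <- cbind(N2 = ref)
    rownames(tab2) <- sprintf("r%02d", 1:40)
    kf <- runif(1, 0.3, 1)
    kept2 <- top_quantile_filter(tab2, "N2", kf)
    cutoff <- quantile(ref, 1 - kf, type = 7, names = FALSE)
    expect_equal(rownames(kept2), rownames(tab2)[ref >= cutoff])
  }
})

test_that("top-quantile filter is monotone in keep_fraction", {
  set.seed(92)
  tab <- cbind(N2 = rlnorm(100, 3, 1))
  rownames(tab) <- sprintf("g%03d", 1:100)
  prev <- character(0)
  for (kf in c(0.2, 0.5, 0.8, 1)) {
    cur <- rownames(top_quantile_filter(tab, "N2", kf))
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})
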