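# Interval data model and I/O: BED/GFF3/bedGraph boundary conventions,
# merge/rescale/overlap algebra, and round-trip fidelity.

test_that("load_intervals maps BED coordinates and columns", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t10\t20", f)
  gr <- load_intervals(f)
  expect_equal(as.character(seqnames(gr)), "chr1")
  expect_equal(start(gr), 11L)  # BED 0-based half-open -> 1-based closed
  expect_equal(end(gr), 20L)
  expect_equal(as.character(strand(gr)), "*")

  writeLines(character(0), f)
  expect_length(load_intervals(f), 0L)

  writeLines(c("# comment", "track name=x", "chr1\t5\t9\tpk\t7\t-"), f)
  gr <- load_intervals(f)
  expect_equal(mcols(gr)$name, "pk")
  expect_equal(mcols(gr)$score, 7)
  expect_equal(as.character(strand(gr)), "-")
})

test_that("malformed BED lines are rejected with their line number", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t1\t5", "chr1\t3"), f)
  expect_error(load_intervals(f), "line 2")
  writeLines(c("chr1\t9\t4"), f)
  expect_error(load_intervals(f), "start >= end")
})

test_that("BED write/load round-trips byte-identically", {
  set.seed(11)
  gr <- random_peaks(100)
  mcols(gr)$name <- sprintf("pk_%03d", seq_along(gr))
  mcols(gr)$score <- sample(0:1000, 100, replace = TRUE)
  strand(gr) <- sample(c("+", "-", "*"), 100, replace = TRUE)
  f1 <- withr::local_tempfile(fileext = ".bed")
  f2 <- withr::local_tempfile(fileext = ".bed")
  write_intervals(gr, f1)
  back <- load_intervals(f1)
  expect_equal(start(back), start(gr))
  expect_equal(end(back), end(gr))
  expect_equal(mcols(back)$name, mcols(gr)$name)
  write_intervals(back, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("GFF3 gene models convert coordinates and strand-reflect TSS/TTS", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t4\t10\t.\t+\t.\tID=g1",
               "chr1\tsrc\tmRNA\t4\t10\t.\t+\t.\tID=g1.t1;Parent=g1",
               "chr1\tsrc\tgene\t4\t10\t.\t-\t.\tID=g2",
               "chr1\tsrc\tmRNA\t4\t10\t.\t-\t.\tID=g2.t1;Parent=g2"), f)
  gm <- load_gene_models(f)
  expect_equal(length(gm), 2L)
  expect_equal(start(gm$genes["g1"]), 4L)  # 1-based closed = 0-based (3,10)
  expect_equal(end(gm$genes["g1"]), 10L)
  # minus-strand TSS is the larger coordinate (internal base 10 = 0-based 9)
  expect_equal(dreamtargets:::tss_positions(gm, "g2"), 10L)
  expect_equal(dreamtargets:::tss_positions(gm, "g1"), 4L)
})

test_that("orphan mRNAs are skipped with a warning", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t4\t10\t.\t+\t.\tID=g1",
               "chr1\tsrc\tmRNA\t20\t30\t.\t+\t.\tID=x.t1;Parent=ghost"), f)
  expect_warning(gm <- load_gene_models(f), "without a parent gene")
  expect_equal(length(gm), 1L)
})

test_that("gene models survive a GFF3 round-trip", {
  set.seed(7)
  n <- 50
  starts <- sort(sample.int(1e5, n)) * 10L
  genes <- GRanges("chrX", IRanges(starts, starts + sample(500:2000, n, TRUE)),
                   strand = sample(c("+", "-"), n, TRUE))
  ids <- sprintf("g%02d", seq_len(n))
  names(genes) <- ids
  tx <- lapply(seq_len(n), function(i) {
    k <- sample(1:3, 1)
    IRanges(start(genes)[i] + c(0L, sample(0:100, k - 1, TRUE)),
            end(genes)[i] - c(0L, sample(0:100, k - 1, TRUE)))
  })
  names(tx) <- ids
  gm <- gene_models(genes, tx)
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gene_models(gm, f)
  back <- load_gene_models(f)
  expect_equal(gene_ids <- names(back$genes), ids)
  expect_equal(start(back$genes), start(genes))
  expect_equal(end(back$genes), end(genes))
  for (g in ids) {
    expect_setequal(dreamtargets:::tss_positions(back, g),
                    dreamtargets:::tss_positions(gm, g))
  }
})

test_that("bedGraph expansion, zero fill, and validation", {
  f <- withr::local_tempfile(fileext = ".bedgraph")
  writeLines("chr1\t0\t3\t2.0", f)
  tr <- load_coverage(f)
  expect_equal(tr$values, c(2, 2, 2))

  tr <- load_coverage(f, chrom = "chr2", length = 5)
  expect_equal(tr$values, rep(0, 5))

  writeLines(c("chr1\t0\t3\t2", "chr1\t2\t5\t1"), f)
  expect_error(load_coverage(f), "overlapping")
  writeLines("chr1\t0\t3\t-1", f)
  expect_error(load_coverage(f), "negative")
})

test_that("coverage totals equal the record-length-weighted sums", {
  set.seed(3)
  for (rep in 1:20) {
    n_rec <- sample(1:20, 1)
    bounds <- sort(sample(0:500, n_rec + 1))
    vals <- round(runif(n_rec, 0, 10), 3)
    f <- withr::local_tempfile(fileext = ".bedgraph")
    writeLines(sprintf("chr1\t%d\t%d\t%g", bounds[-(n_rec + 1)], bounds[-1], vals), f)
    tr <- load_coverage(f, length = 600)
    expect_equal(sum(tr$values), sum((bounds[-1] - bounds[-(n_rec + 1)]) * vals))
  }
})

test_that("coverage write/load round-trips", {
  set.seed(4)
  v <- rpois(300, 2)
  f <- withr::local_tempfile(fileext = ".bedgraph")
  write_coverage(coverage_track("chr1", v), f)
  expect_equal(load_coverage(f, "chr1", 300)$values, as.numeric(v))
})

test_that("merge_intervals joins overlapping and book-ended peaks", {
  # 0-based [10,20) + [15,30) = 1-based 11-20 + 16-30 -> 11-30
  gr <- GRanges("chr1", IRanges(c(11, 16), c(20, 30)))
  m <- merge_intervals(gr)
  expect_equal(start(m), 11L)
  expect_equal(end(m), 30L)
  # book-ended: [1,5) + [5,9) merge
  m2 <- merge_intervals(GRanges("chr1", IRanges(c(1, 6), c(5, 9))))
  expect_length(m2, 1L)
  # disjoint inputs come back sorted and unchanged
  gr3 <- GRanges("chr1", IRanges(c(50, 10), c(60, 20)))
  m3 <- merge_intervals(gr3)
  expect_equal(start(m3), c(10L, 50L))
  expect_length(merge_intervals(GRanges()), 0L)
})

test_that("merge conserves covered bases and is idempotent (mask oracle)", {
  set.seed(21)
  for (rep in 1:40) {
    gr <- random_peaks(25, chroms = c("chr1", "chr2"))
    m <- merge_intervals(gr)
    expect_true(isDisjoint(m))
    expect_identical(coverage_mask(m), coverage_mask(gr))
    expect_identical(merge_intervals(m), m)
  }
})

test_that("rescale_to_midpoint applies the +/-100 bp rule with left-biased midpoints", {
  # 0-based [100,300): midpoint 200 -> fixed point
  gr <- GRanges("chr1", IRanges(101, 300))
  r <- rescale_to_midpoint(gr, 100)
  expect_equal(start(r), 101L)
  expect_equal(end(r), 300L)
  # 0-based [0,10): midpoint 5, clipped at chromosome start -> [0,105)
  r2 <- rescale_to_midpoint(GRanges("chr1", IRanges(1, 10)), 100)
  expect_equal(start(r2), 1L)
  expect_equal(end(r2), 105L)
  # property: all outputs have width 200 when midpoints are >= 100,
  # and rescaling is a fixed point of itself (midpoint preserved)
  set.seed(5)
  gr3 <- shift(random_peaks(200), 200L)
  r3 <- rescale_to_midpoint(gr3, 100)
  expect_true(all(width(r3) == 200L))
  mid0 <- function(g) floor((start(g) - 1 + end(g)) / 2)
  expect_equal(mid0(r3), mid0(gr3))
})

test_that("overlap_fraction matches the all-pairs oracle", {
  a <- GRanges("chr1", IRanges(c(1, 100), c(10, 120)))
  expect_equal(overlap_fraction(a, a), 1)
  b <- GRanges("chr1", IRanges(500, 600))
  expect_equal(overlap_fraction(a, b), 0)
  expect_warning(z <- overlap_fraction(GRanges(), a), "empty query")
  expect_equal(z, 0)

  set.seed(9)
  q <- random_peaks(500, max_pos = 800)
  r <- random_peaks(200, max_pos = 800)
  brute <- mean(vapply(seq_along(q), function(i) {
    any(as.character(seqnames(r)) == as.character(seqnames(q))[i] &
          start(r) <= end(q)[i] & end(r) >= start(q)[i])
  }, logical(1)))
  expect_equal(overlap_fraction(q, r), brute)
})
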