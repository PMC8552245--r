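# PWM scanning with exact p-values, overlap-hierarchy resolution,
# inclusion filtering, and differential motif association.

test_that("a near-consensus PWM hits exactly its literal matches at p = 4^-8", {
  p <- consensus_pwm("E2F-test", "TTTCGCGC", family = "E2F")
  seq <- paste0("ACGTACGT", "TTTCGCGC", "ACGTACGTA")
  hits <- scan_pwm(seq, p, 1e-4, peak_id = "pk")
  fwd <- hits[hits$strand == "+", ]
  expect_equal(nrow(fwd), 1L)
  expect_equal(fwd$offset, 9L)
  expect_equal(fwd$pvalue, 0.25^8, tolerance = 1e-9)

  expect_equal(nrow(scan_pwm(strrep("N", 60), p, 1e-4)), 0L)
  # motif longer than the sequence -> empty result
  expect_equal(nrow(scan_pwm("ACGT", p, 1e-4)), 0L)
})

test_that("exact p-values match exhaustive word enumeration (L <= 8)", {
  set.seed(121)
  for (rep in 1:4) {
    L <- sample(4:6, 1)
    m <- matrix(rgamma(4 * L, 1), L, 4)
    m <- m / rowSums(m)
    p <- pwm(sprintf("rand%d", rep), m, family = "other")
    seq <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
    hits <- scan_pwm(seq, p, pvalue_cutoff = 1, peak_id = "pk")
    fwd <- hits[hits$strand == "+", ]
    # exact agreement with enumeration on the discretised score grid
    expect_equal(fwd$pvalue,
                 enumerate_pwm_pvalue(p, fwd$score, discretize = TRUE),
                 tolerance = 1e-12)
    # discretisation at 1e-3 is the only approximation vs continuous scores
    expect_lt(max(abs(fwd$pvalue - enumerate_pwm_pvalue(p, fwd$score))), 0.005)
  }
  # and for the 8-mer consensus case the top p-value is exact
  p8 <- consensus_pwm("c8", "ACGTACGT", family = "other")
  expect_equal(enumerate_pwm_pvalue(p8, max(scan_pwm("ACGTACGT", p8, 1)$score)),
               0.25^8)
})

test_that("scanning a sequence and its reverse complement mirrors hits", {
  p <- consensus_pwm("CDE-CHR-t", "GGCGGGATTTGAA")
  seq <- paste0("TTTTT", "GGCGGGATTTGAA", "CCCCCTTTTTAAAAA")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  h1 <- scan_pwm(seq, p, 1e-4, "fwd_pk")
  h2 <- scan_pwm(rc, p, 1e-4, "rc_pk")
  expect_equal(nrow(h1), nrow(h2))
  expect_setequal(h1$score, h2$score)
  expect_setequal(nchar(seq) - (h1$offset + h1$width - 1L) + 1L, h2$offset)
})

test_that("lowering the cutoff never adds hits; p is monotone in score", {
  set.seed(122)
  p <- consensus_pwm("E2F-x", "TTTCCCGC", dominant = 0.9)
  seq <- paste(sample(c("A", "C", "G", "T"), 4000, TRUE), collapse = "")
  loose <- scan_pwm(seq, p, 1e-3)
  tight <- scan_pwm(seq, p, 1e-5)
  key <- function(h) paste(h$offset, h$strand)
  expect_true(all(key(tight) %in% key(loose)))
  o <- order(loose$score)
  expect_true(all(diff(loose$pvalue[o]) <= 1e-12))
})

test_that("overlap resolution follows the CDE-CHR > LONG > E2F hierarchy", {
  mk <- function(motif, family, offset, p, peak = "pk1", width = 8L) {
    data.frame(peak_id = peak, motif_id = motif, family = family,
               offset = offset, width = width, strand = "+",
               score = 10, pvalue = p)
  }
  hits <- rbind(mk("CDE-CHR-a", "CDE-CHR", 10, 1e-5),
                mk("E2F-a1", "E2F", 12, 1e-9))
  expect_equal(resolve_overlaps(hits)$motif_id, "CDE-CHR-a")

  hits2 <- rbind(mk("LONG-a", "LONG", 10, 1e-5),
                 mk("E2F-a1", "E2F", 12, 1e-9))
  expect_equal(resolve_overlaps(hits2)$motif_id, "LONG-a")

  # within a family the lowest p wins
  hits3 <- rbind(mk("E2F-a1", "E2F", 10, 1e-5),
                 mk("E2F-b", "E2F", 12, 1e-9))
  expect_equal(resolve_overlaps(hits3)$motif_id, "E2F-b")

  # disjoint hits are untouched; resolution is idempotent
  hits4 <- rbind(mk("CDE-CHR-a", "CDE-CHR", 10, 1e-5),
                 mk("E2F-a1", "E2F", 50, 1e-9),
                 mk("LONG-a", "LONG", 100, 1e-4, peak = "pk2"))
  r <- resolve_overlaps(hits4)
  expect_equal(nrow(r), 3L)
  expect_identical(resolve_overlaps(r), r)

  bad <- mk("X", "mystery", 10, 1e-5)
  expect_error(resolve_overlaps(bad), "unknown motif family")
})

test_that("inclusion filter applies a strict > 30% rule per class", {
  mk_hits <- function(motif, peaks) {
    data.frame(peak_id = peaks, motif_id = motif, family = "E2F",
               offset = 1L, width = 8L, strand = "+", score = 1,
               pvalue = 1e-5)
  }
  classA <- sprintf("a%02d", 1:10)
  classB <- sprintf("b%02d", 1:10)
  hits <- rbind(mk_hits("m4of10", classA[1:4]),     # 0.4 in A -> kept
                mk_hits("m3of10", c(classA[1:3], classB[1:3])))  # 0.3 -> dropped
  kept <- inclusion_filter(hits, list(A = classA, B = classB), 0.30)
  expect_equal(kept, "m4of10")
  expect_warning(
    inclusion_filter(hits, list(A = classA, empty = character(0)), 0.30),
    "empty peak set")
})

test_that("association test builds the 2x2 tables and BH-corrects", {
  hits <- data.frame(peak_id = c("a1", "a2"), motif_id = "m1", family = "E2F",
                     offset = 1L, width = 8L, strand = "+", score = 1,
                     pvalue = 1e-5)
  # contains/lacks x A/B = [[2,0],[0,2]] -> two-sided p = 1/3
  res <- association_test(c("a1", "a2"), c("b1", "b2"), hits)
  expect_equal(res$p, 1 / 3)
  expect_equal(res$padj, 1 / 3)

  # identical motif fractions give OR = 1
  hits2 <- rbind(hits, within(hits, peak_id <- c("b1", "b2")))
  hits2 <- rbind(hits2, data.frame(peak_id = c("a3", "b3"), motif_id = "m1",
                                   family = "E2F", offset = 1L, width = 8L,
                                   strand = "+", score = 1, pvalue = 1e-5))
  res2 <- association_test(c("a1", "a2", "a3", "a4"),
                           c("b1", "b2", "b3", "b4"), hits2)
  expect_equal(res2$odds_ratio, 1)
  expect_error(association_test(c("a1"), c("a1", "b1"), hits), "disjoint")
})

test_that("MEME minimal format round-trips and carries families", {
  pwms <- default_pwms()
  expect_length(pwms, 7L)
  fams <- vapply(pwms, function(p) p$family, "")
  expect_setequal(unique(fams), c("E2F", "CDE-CHR", "LONG"))
  f <- withr::local_tempfile(fileext = ".meme")
  write_meme(pwms, f)
  back <- read_meme(f)
  expect_equal(vapply(back, function(p) p$motif_id, ""),
               vapply(pwms, function(p) p$motif_id, ""))
  for (i in seq_along(pwms)) {
    expect_equal(back[[i]]$matrix, pwms[[i]]$matrix, tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})

test_that("pwm construction validates shape, sums, and families", {
  m <- matrix(0.25, 8, 4)
  expect_s3_class(pwm("ok", m), "pwm")
  expect_error(pwm("short", m[1:3, ]), ">= 4")
  bad <- m; bad[1, ] <- c(0.5, 0.5, 0.5, 0.5)
  expect_error(pwm("sum", bad), "sum to 1")
  expect_error(pwm("fam", m, family = "weird"), "unknown motif family")
})
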