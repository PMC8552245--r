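# Synthetic-data generators: determinism, structural guarantees, and
# consistency of the planted ground truth with the emitted files.

small_config <- function(seed = 5, ...) {
  scenario_config(seed = seed, n_genes = 120L, chrom_length = 4e5,
                  n_lin36_shared = 20L, n_lin15B_shared = 8L,
                  n_lin35_only = 12L, ...)
}

test_that("generators are deterministic given the seed", {
  cfg <- small_config()
  a1 <- generate_annotation(cfg)
  a2 <- generate_annotation(cfg)
  expect_identical(a1$classes, a2$classes)
  expect_equal(a1$gm$genes, a2$gm$genes)
  expect_identical(as.character(a1$genome[[1]]), as.character(a2$genome[[1]]))

  c1 <- generate_counts(cfg, a1)
  c2 <- generate_counts(cfg, a2)
  expect_identical(c1$rna$counts, c2$rna$counts)
  expect_identical(c1$tpm, c2$tpm)
})

test_that("annotation writes n_genes GFF records that reload with invariants intact", {
  cfg <- small_config(seed = 6)
  out <- withr::local_tempdir()
  ann <- generate_annotation(cfg, out)
  gff <- readLines(file.path(out, "genes.gff3"))
  expect_equal(sum(grepl("\tgene\t", gff)), 120L)

  gm <- load_gene_models(file.path(out, "genes.gff3"),
                         file.path(out, "promoters.bed"))
  expect_equal(length(gm), 120L)
  expect_equal(start(gm$genes), start(ann$gm$genes))
  # genes are non-overlapping and promoters sit 5' of the TSS
  expect_true(isDisjoint(gm$genes, ignore.strand = TRUE))
  for (g in names(gm$promoters)) {
    p <- gm$promoters[[g]]
    if (as.character(strand(gm$genes[g])) == "+") {
      expect_equal(end(p), start(gm$genes[g]) - 1L)
    } else {
      expect_equal(start(p), end(gm$genes[g]) + 1L)
    }
  }
})

test_that("ChIP generator plants recoverable peaks with the configured co-binding", {
  cfg <- small_config(seed = 7, cobinding = c(lin36 = 1, lin15B = 0.72))
  ann <- generate_annotation(cfg)
  chip <- generate_chip(cfg, ann)
  # co-binding rate 1.0 -> every LIN-36 true peak overlaps a LIN-35 peak
  expect_equal(overlap_fraction(chip$true_peaks[["LIN-36"]],
                                chip$true_peaks[["LIN-35"]]), 1)

  # every planted peak mode is recovered by concave calling on a replicate
  tr <- chip$tracks[["LIN-35"]][["wt"]][[1]]
  called <- call_concave_peaks(tr, smoothing_config(), min_height = 3)
  hitrate <- overlap_fraction(chip$true_peaks[["LIN-35"]], called)
  expect_gte(hitrate, 0.95)

  # planted decreases lower the mutant coverage at affected peaks
  bt <- chip$binding_truth
  dec <- bt[bt$direction == "decreased", ]
  expect_gt(nrow(dec), 0)
  f <- dec$factor[1]; mut <- dec$mutant[1]
  wt_q <- quantify(list(wt = chip$tracks[[f]][["wt"]][[1]]),
                   chip$true_peaks[[f]], "sum")
  mut_q <- quantify(list(mut = chip$tracks[[f]][[mut]][[1]]),
                    chip$true_peaks[[f]], "sum")
  aff <- dec$peak_id
  expect_true(mean(mut_q[aff, 1] < wt_q[aff, 1]) > 0.95)
})

test_that("null counts give uniform p-values and planted classes get their effects", {
  cfg <- small_config(seed = 8, effect_lfc = 0)
  ann <- generate_annotation(cfg)
  cnt <- generate_counts(cfg, ann)
  res <- nb_test(cnt$rna$counts, cnt$rna$condition, "lin-35", "N2")
  ks <- suppressWarnings(ks.test(res$pvalue, "punif"))
  expect_gt(ks$p.value, 0.01)

  cfg2 <- small_config(seed = 9)
  ann2 <- generate_annotation(cfg2)
  cnt2 <- generate_counts(cfg2, ann2)
  # germline specificity concentrates on LIN-15B-shared genes
  sc <- germline_specificity(cnt2$tpm, "germline")
  s15 <- sc$score[ann2$classes[sc$gene_id] == "lin15B_shared"]
  rest <- sc$score[ann2$classes[sc$gene_id] == "null"]
  expect_gt(mean(s15 > 0.5), 0.9)
  expect_gt(median(s15), 0.7)
  expect_lt(median(rest), 0.5)
  # gbHTZ-1 loss is planted exactly on LIN-36-shared gene bodies
  expect_setequal(cnt2$truth$gene_id[cnt2$truth$gbhtz_loss_lin35],
                  names(ann2$classes)[ann2$classes == "lin36_shared"])
})

test_that("motif planting at rate 1 gives full, exactly-positioned recall", {
  cfg <- small_config(seed = 10,
                      motif_rates = list(lin36_shared = c("CDE-CHR-a" = 1),
                                         lin15B_shared = c("LONG-a" = 1)))
  set.seed(99)
  seqs <- setNames(replicate(12, paste(sample(c("A", "C", "G", "T"), 200, TRUE),
                                       collapse = "")),
                   sprintf("pk%02d", 1:12))
  classes <- setNames(rep(c("lin36_shared", "lin15B_shared"), each = 6),
                      names(seqs))
  planted <- plant_motifs(cfg, seqs, classes)
  expect_equal(nrow(planted$truth), 12L)

  pwms <- default_pwms()
  hits <- scan_peaks(planted$sequences, pwms, 1e-4)
  for (i in seq_len(nrow(planted$truth))) {
    row <- planted$truth[i, ]
    match <- hits[hits$peak_id == row$peak_id & hits$motif_id == row$motif_id &
                    hits$offset == row$offset, ]
    expect_gte(nrow(match), 1L)
  }

  # rate 0 -> only chance hits, bounded by 3x the expected false-positive count
  cfg0 <- small_config(seed = 11,
                       motif_rates = list(lin36_shared = c("CDE-CHR-a" = 0),
                                          lin15B_shared = c("CDE-CHR-a" = 0)))
  planted0 <- plant_motifs(cfg0, seqs, classes)
  expect_equal(nrow(planted0$truth), 0L)
  hits0 <- scan_peaks(planted0$sequences, pwms, 1e-4)
  n_windows <- sum(nchar(seqs) - 14 + 1) * 2 * length(pwms)
  expect_lte(nrow(hits0), max(3, 3 * n_windows * 1e-4))
})

test_that("stronger planted effects never reduce end-to-end detectability", {
  recovered <- vapply(c(0.5, 1, 2), function(eff) {
    cfg <- small_config(seed = 12, effect_lfc = eff)
    ann <- generate_annotation(cfg)
    cnt <- generate_counts(cfg, ann)
    res <- nb_test(cnt$rna$counts, cnt$rna$condition, "lin-36", "N2")
    lab <- classify_de(res)
    planted <- names(ann$classes)[ann$classes == "lin36_shared"]
    mean(planted %in% res$feature_id[lab == "up"])
  }, numeric(1))
  expect_true(all(diff(recovered) >= 0))
})
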