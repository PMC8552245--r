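# Synthetic-data generators with planted, machine-readable ground truth: a
# toy genome with genes and promoters, three co-binding factors with
# Gaussian-shaped promoter peaks, NB count matrices with planted
# derepression and mark-loss effects, a germline-vs-soma TPM table, and
# planted motif instances. Each generator draws from its own RNG stream
# (seed + a fixed stage offset), so reordering stages never changes outputs.

STAGE_SEED_OFFSETS <- c(annotation = 101L, chip = 202L, counts = 303L,
                        motifs = 404L)

stage_seed <- function(config, stage) {
  config$seed + STAGE_SEED_OFFSETS[[stage]]
}

#' Scenario configuration for the synthetic-data generators
#'
#' The defaults state the simulated world: 1,000 genes on a 3 Mb
#' chromosome; 150 planted LIN-36-shared, 50 LIN-15B-shared and 100
#' LIN-35-only target genes (echoing the relative class proportions of the
#' biological taxonomy without claiming to reproduce them); derepression
#' log2 fold change 2 with NB dispersion 0.1 and 4 replicates per RNA
#' condition; factor co-binding rates 0.95 (LIN-36 vs LIN-35) and 0.72
#' (LIN-15B vs LIN-35); gene-body H2A.Z enrichment fold 3 with loss fold
#' 0.5 in the relevant mutants; promoter H3K9me2 fold 3 with loss fold 0.5;
#' germline TPM fraction 0.8 for LIN-15B-shared genes; and class-specific
#' motif planting rates.
#'
#' @param seed RNG seed for all generators.
#' @param n_genes number of genes.
#' @param chrom chromosome name.
#' @param chrom_length chromosome length in bp (>= n_genes x 3 kb).
#' @param n_replicates RNA/count replicates per condition.
#' @param n_chip_replicates ChIP coverage replicates per factor/condition.
#' @param n_lin36_shared,n_lin15B_shared,n_lin35_only planted class sizes.
#' @param effect_lfc planted derepression log2 fold change.
#' @param nb_dispersion NB dispersion alpha (variance mu + alpha mu^2) for
#'   RNA counts.
#' @param promoter_prob probability a gene gets a promoter annotation.
#' @param cobinding co-binding rates, named `lin36` and `lin15B`.
#' @param peak_sigma Gaussian peak sd in bp.
#' @param background_rate flat Poisson coverage background.
#' @param peak_amp named peak amplitudes per planted context.
#' @param binding_changes list of planted differential-binding effects,
#'   each list(factor, mutant, class, fold).
#' @param gbhtz_enrichment,gbhtz_loss_fold,gbhtz_dispersion gene-body H2A.Z
#'   world: enrichment of LIN-36-shared gene bodies, loss fold in lin-35 /
#'   lin-36 mutants, count dispersion.
#' @param k9_fold,k9_loss_fold,k9_dispersion,k9_domain_halfwidth promoter
#'   H3K9me2 world (domains planted around LIN-15B-shared promoters).
#' @param germline_fraction germline share of total TPM for LIN-15B-shared
#'   genes.
#' @param motif_rates per-class planting rates, named by motif id.
#' @param rna_meanlog,rna_sdlog lognormal base-mean model for RNA counts.
#' @param include_met2 also simulate a met-2 mutant RNA condition in which
#'   LIN-15B-shared genes are derepressed.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(seed = 1L,
                            n_genes = 1000L,
                            chrom = "chrI",
                            chrom_length = 3e6,
                            n_replicates = 4L,
                            n_chip_replicates = 2L,
                            n_lin36_shared = 150L,
                            n_lin15B_shared = 50L,
                            n_lin35_only = 100L,
                            effect_lfc = 2,
                            nb_dispersion = 0.1,
                            promoter_prob = 0.9,
                            cobinding = c(lin36 = 0.95, lin15B = 0.72),
                            peak_sigma = 75,
                            background_rate = 1,
                            peak_amp = c(lin36_shared = 60, lin15B_shared = 30,
                                         lin35_only = 45, specific = 40),
                            binding_changes = list(
                              list(factor = "LIN-35", mutant = "lin-36",
                                   class = "lin36_shared", fold = 0.4),
                              list(factor = "LIN-35", mutant = "lin-15B",
                                   class = "lin15B_shared", fold = 2.5)),
                            gbhtz_enrichment = 3,
                            gbhtz_loss_fold = 0.5,
                            gbhtz_dispersion = 0.02,
                            k9_fold = 3,
                            k9_loss_fold = 0.5,
                            k9_dispersion = 0.02,
                            k9_domain_halfwidth = 1000L,
                            germline_fraction = 0.8,
                            motif_rates = list(
                              lin36_shared = c("CDE-CHR-a" = 0.6, "E2F-a1" = 0.5),
                              lin15B_shared = c("E2F-b" = 0.7, "LONG-a" = 0.6)),
                            rna_meanlog = log(100),
                            rna_sdlog = 1,
                            include_met2 = TRUE) {
  stopifnot(chrom_length >= n_genes * 3000,
            n_lin36_shared + n_lin15B_shared + n_lin35_only <= n_genes,
            effect_lfc >= 0, nb_dispersion > 0,
            all(cobinding > 0 & cobinding <= 1),
            promoter_prob >= 0, promoter_prob <= 1)
  cfg <- as.list(environment())
  structure(cfg, class = "scenario_config")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate the toy annotation: genes, promoters, genome sequence
#'
#' Places non-overlapping genes (600-1200 bp, 1-3 transcripts, random
#' strand) in equal slots along the chromosome with >= 600 bp margins;
#' each gene gets, with probability `promoter_prob`, one promoter interval
#' covering the 500 bp immediately 5' of its TSS. The background sequence
#' is i.i.d. uniform bases. Gene class labels (the planted ground truth of
#' the target taxonomy) are drawn here. Deterministic given the seed.
#'
#' @param config a [scenario_config()].
#' @param outdir optional directory; writes genes.gff3, promoters.bed and
#'   genome.fa when given.
#' @return list with `gm` ([gene_models()]), `genome` (`DNAStringSet`),
#'   `classes` (named character: lin36_shared / lin15B_shared / lin35_only /
#'   null per gene) and `paths`.
#' @export
generate_annotation <- function(config, outdir = NULL) {
  set.seed(stage_seed(config, "annotation"))
  n <- config$n_genes
  slot <- floor(config$chrom_length / n)
  stopifnot(slot >= 3000)
  ids <- sprintf("gene_%04d", seq_len(n))
  glen <- sample(600:1200, n, replace = TRUE)
  margin <- 600L
  starts <- vapply(seq_len(n), function(i) {
    lo <- (i - 1L) * slot + margin + 1L
    hi <- i * slot - margin - glen[i]
    sample(lo:hi, 1L)
  }, integer(1))
  ends <- starts + glen - 1L
  strands <- sample(c("+", "-"), n, replace = TRUE)
  genes <- GRanges(config$chrom, IRanges(starts, ends), strand = strands)
  names(genes) <- ids
  transcripts <- list()
  for (i in seq_len(n)) {
    ntx <- sample(1:3, 1L)
    tx_s <- starts[i]; tx_e <- ends[i]
    if (ntx > 1L) {
      # extra transcripts start/end slightly inside the span
      js <- sample(0:150, ntx - 1L, replace = TRUE)
      je <- sample(0:150, ntx - 1L, replace = TRUE)
      tx_s <- c(tx_s, starts[i] + js)
      tx_e <- c(tx_e, ends[i] - je)
    }
    transcripts[[ids[i]]] <- IRanges(tx_s, tx_e)
  }
  has_prom <- runif(n) < config$promoter_prob
  promoters <- list()
  for (i in which(has_prom)) {
    if (strands[i] == "+") {
      p <- GRanges(config$chrom, IRanges(max(1L, starts[i] - 500L), starts[i] - 1L))
    } else {
      p <- GRanges(config$chrom, IRanges(ends[i] + 1L, ends[i] + 500L))
    }
    promoters[[ids[i]]] <- p
  }
  gm <- gene_models(genes, transcripts, promoters)
  lab <- rep("null", n)
  picked <- sample(n, config$n_lin36_shared + config$n_lin15B_shared + config$n_lin35_only)
  lab[picked[seq_len(config$n_lin36_shared)]] <- "lin36_shared"
  lab[picked[config$n_lin36_shared + seq_len(config$n_lin15B_shared)]] <- "lin15B_shared"
  lab[picked[config$n_lin36_shared + config$n_lin15B_shared +
               seq_len(config$n_lin35_only)]] <- "lin35_only"
  classes <- setNames(lab, ids)
  genome <- Biostrings::DNAStringSet(setNames(random_dna(config$chrom_length),
                                              config$chrom))
  paths <- list()
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    paths$gff <- file.path(outdir, "genes.gff3")
    paths$promoter_bed <- file.path(outdir, "promoters.bed")
    write_gene_models(gm, paths$gff, paths$promoter_bed)
    # the genome FASTA is written by simulate_scenario after motif planting
  }
  list(gm = gm, genome = genome, classes = classes, paths = paths)
}

# strand-aware planted peak centre for a gene: mid-promoter when a promoter
# is annotated, else just inside the gene 5' end (so the span-fallback
# assignment rule can recover the binding)
peak_center_for_gene <- function(ann, g) {
  sp <- ann$gm$genes[g]
  str <- as.character(strand(sp))
  has_prom <- !is.null(ann$gm$promoters[[g]]) && length(ann$gm$promoters[[g]]) > 0
  if (has_prom) {
    if (str == "+") start(sp) - 250L else end(sp) + 250L
  } else {
    if (str == "+") start(sp) + 150L else end(sp) - 150L
  }
}

add_gaussian <- function(lambda, center, amp, sigma) {
  lo <- max(1L, center - 4L * sigma)
  hi <- min(length(lambda), center + 4L * sigma)
  x <- lo:hi
  lambda[x] <- lambda[x] + amp * exp(-(x - center)^2 / (2 * sigma^2))
  lambda
}

#' Generate ChIP coverage tracks and true peaks
#'
#' Plants Gaussian-shaped factor peaks (sd `peak_sigma`) at the promoters of
#' class genes over a flat Poisson background: LIN-35 binds all planted
#' target classes, LIN-36 the LIN-36-shared class, LIN-15B the
#' LIN-15B-shared class; extra factor-specific peaks at null genes tune the
#' co-binding rates. Replicate tracks are independent Poisson draws from
#' the expected coverage. Mutant-condition tracks apply the configured
#' binding-change folds. Also emits a wild-type H3K9me2 track with broad
#' domains planted around LIN-15B-shared promoters.
#'
#' @param config a [scenario_config()].
#' @param ann output of [generate_annotation()].
#' @param outdir optional; writes per-track bedGraphs and true-peak BEDs.
#' @return list with `true_peaks` (named list of `GRanges` by factor),
#'   `tracks` (`tracks[[factor]][[condition]]` = list of
#'   [coverage_track()]), `k9_track`, `binding_truth` (`data.frame`),
#'   `peak_genes` (named list factor -> gene ids), and `paths`.
#' @export
generate_chip <- function(config, ann, outdir = NULL) {
  set.seed(stage_seed(config, "chip"))
  classes <- ann$classes
  ids <- names(classes)
  g36 <- ids[classes == "lin36_shared"]
  g15 <- ids[classes == "lin15B_shared"]
  g35o <- ids[classes == "lin35_only"]
  nulls <- ids[classes == "null"]
  n_spec36 <- round(length(g36) * (1 - config$cobinding[["lin36"]]) /
                      config$cobinding[["lin36"]])
  n_spec15 <- round(length(g15) * (1 - config$cobinding[["lin15B"]]) /
                      config$cobinding[["lin15B"]])
  extra <- sample(nulls, n_spec36 + n_spec15)
  spec36 <- extra[seq_len(n_spec36)]
  spec15 <- extra[n_spec36 + seq_len(n_spec15)]
  amp <- config$peak_amp
  factor_genes <- list(
    "LIN-35" = c(g36, g15, g35o),
    "LIN-36" = c(g36, spec36),
    "LIN-15B" = c(g15, spec15))
  gene_amp <- function(f, g) {
    cl <- classes[[g]]
    if (cl == "lin36_shared") amp[["lin36_shared"]]
    else if (cl == "lin15B_shared") amp[["lin15B_shared"]]
    else if (cl == "lin35_only") amp[["lin35_only"]]
    else amp[["specific"]]
  }
  centers <- vapply(ids, function(g) peak_center_for_gene(ann, g), integer(1))
  true_peaks <- list()
  for (f in names(factor_genes)) {
    gs <- factor_genes[[f]]
    gr <- GRanges(config$chrom,
                  IRanges(pmax(1L, centers[gs] - 100L), centers[gs] + 100L),
                  gene_id = gs)
    names(gr) <- sprintf("true_%s_%s", gsub("-", "", f), gs)
    true_peaks[[f]] <- gr
  }
  n_bp <- as.integer(config$chrom_length)
  make_lambda <- function(f, fold_by_gene = NULL) {
    lambda <- rep(config$background_rate, n_bp)
    for (g in factor_genes[[f]]) {
      a <- gene_amp(f, g)
      if (!is.null(fold_by_gene) && !is.na(fold_by_gene[g])) a <- a * fold_by_gene[g]
      lambda <- add_gaussian(lambda, centers[[g]], a, config$peak_sigma)
    }
    lambda
  }
  tracks <- list()
  binding_truth <- list()
  conditions_by_factor <- lapply(names(factor_genes), function(f) "wt")
  names(conditions_by_factor) <- names(factor_genes)
  for (bc in config$binding_changes)
    conditions_by_factor[[bc$factor]] <- union(conditions_by_factor[[bc$factor]], bc$mutant)
  for (f in names(factor_genes)) {
    tracks[[f]] <- list()
    for (cond in conditions_by_factor[[f]]) {
      fold_by_gene <- NULL
      if (cond != "wt") {
        fold_by_gene <- setNames(rep(NA_real_, length(ids)), ids)
        for (bc in config$binding_changes) {
          if (bc$factor != f || bc$mutant != cond) next
          aff <- intersect(factor_genes[[f]], ids[classes == bc$class])
          fold_by_gene[aff] <- bc$fold
          binding_truth[[length(binding_truth) + 1L]] <- data.frame(
            factor = f, mutant = cond, gene_id = aff,
            peak_id = names(true_peaks[[f]])[match(aff, true_peaks[[f]]$gene_id)],
            fold = bc$fold,
            direction = if (bc$fold < 1) "decreased" else "increased",
            stringsAsFactors = FALSE)
        }
      }
      lambda <- make_lambda(f, fold_by_gene)
      tracks[[f]][[cond]] <- lapply(seq_len(config$n_chip_replicates), function(i)
        coverage_track(config$chrom, rpois(n_bp, lambda)))
    }
  }
  # broad repressive-mark domains around LIN-15B-shared promoters
  k9_lambda <- rep(2 * config$background_rate, n_bp)
  for (g in g15) {
    c0 <- centers[[g]]
    lo <- max(1L, c0 - config$k9_domain_halfwidth)
    hi <- min(n_bp, c0 + config$k9_domain_halfwidth)
    k9_lambda[lo:hi] <- k9_lambda[lo:hi] * config$k9_fold
  }
  k9_track <- coverage_track(config$chrom, rpois(n_bp, k9_lambda))
  binding_truth <- if (length(binding_truth)) do.call(rbind, binding_truth)
    else data.frame(factor = character(0), mutant = character(0),
                    gene_id = character(0), peak_id = character(0),
                    fold = numeric(0), direction = character(0))
  paths <- list()
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    paths$chip <- list()
    for (f in names(tracks)) {
      fkey <- gsub("-", "", f)
      paths$chip[[f]] <- list()
      for (cond in names(tracks[[f]])) {
        reps <- vapply(seq_along(tracks[[f]][[cond]]), function(i) {
          pth <- file.path(outdir, sprintf("chip_%s_%s_rep%d.bedgraph", fkey, cond, i))
          write_coverage(tracks[[f]][[cond]][[i]], pth)
          pth
        }, "")
        paths$chip[[f]][[cond]] <- reps
      }
      pb <- file.path(outdir, sprintf("true_peaks_%s.bed", fkey))
      tp <- true_peaks[[f]]
      mcols(tp)$name <- names(tp)
      write_intervals(tp, pb)
      paths$true_peaks[[f]] <- pb
    }
    paths$k9 <- file.path(outdir, "k9_wt.bedgraph")
    write_coverage(k9_track, paths$k9)
  }
  list(true_peaks = true_peaks, tracks = tracks, k9_track = k9_track,
       binding_truth = binding_truth, peak_genes = factor_genes,
       paths = paths)
}

write_count_tsv <- function(mat, condition, path_counts, path_samples) {
  dt <- data.table::data.table(feature_id = rownames(mat))
  for (j in seq_len(ncol(mat))) dt[[colnames(mat)[j]]] <- mat[, j]
  data.table::fwrite(dt, path_counts, sep = "\t")
  data.table::fwrite(data.table::data.table(sample = colnames(mat),
                                            condition = condition),
                     path_samples, sep = "\t")
}

nb_matrix <- function(mu_mat, dispersion) {
  out <- matrix(rnbinom(length(mu_mat), mu = mu_mat, size = 1 / dispersion),
                nrow = nrow(mu_mat), dimnames = dimnames(mu_mat))
  out
}

#' Generate count matrices and the cell-type TPM table
#'
#' RNA counts: NB(mean, dispersion) with lognormal base means; planted
#' classes are derepressed (`effect_lfc`) in their designated mutants
#' (LIN-36-shared in lin-35 and lin-36; LIN-15B-shared in lin-35, lin-15B
#' and, optionally, met-2; LIN-35-only in lin-35 only). Gene-body H2A.Z
#' counts: LIN-36-shared gene bodies are enriched in wild type and lose
#' signal (fold `gbhtz_loss_fold`) in lin-35 / lin-36. Promoter H3K9me2
#' counts (one row per annotated promoter, id `prom_<gene>`):
#' LIN-15B-shared promoters are enriched and lose signal in lin-35 /
#' lin-15B. The TPM table concentrates germline expression on
#' LIN-15B-shared genes.
#'
#' @param config a [scenario_config()].
#' @param ann output of [generate_annotation()].
#' @param outdir optional; writes the TSVs.
#' @return list with `rna` (list(counts, condition)), `gbhtz`, `k9`
#'   (same shape), `tpm` (matrix genes x cell types), `truth`
#'   (per-gene planted flags), and `paths`.
#' @export
generate_counts <- function(config, ann, outdir = NULL) {
  set.seed(stage_seed(config, "counts"))
  classes <- ann$classes
  ids <- names(classes)
  n <- length(ids)
  nrep <- config$n_replicates
  eff <- 2^config$effect_lfc
  rna_conditions <- c("N2", "lin-35", "lin-36", "lin-15B",
                      if (config$include_met2) "met-2")
  base <- stats::rlnorm(n, config$rna_meanlog, config$rna_sdlog)
  up_in <- function(cond) {
    up <- rep(FALSE, n)
    if (cond == "lin-35") up <- classes %in% c("lin36_shared", "lin15B_shared", "lin35_only")
    if (cond == "lin-36") up <- classes == "lin36_shared"
    if (cond %in% c("lin-15B", "met-2")) up <- classes == "lin15B_shared"
    up
  }
  cols <- unlist(lapply(rna_conditions, function(cc) sprintf("%s_rep%d", cc, seq_len(nrep))))
  cond_vec <- rep(rna_conditions, each = nrep)
  mu <- matrix(0, n, length(cols), dimnames = list(ids, cols))
  for (j in seq_along(cols)) {
    cc <- cond_vec[j]
    mu[, j] <- base * ifelse(up_in(cc), eff, 1)
  }
  rna <- list(counts = nb_matrix(mu, config$nb_dispersion), condition = cond_vec)

  gb_conditions <- c("N2", "lin-35", "lin-36", "lin-15B")
  gb_base <- stats::rlnorm(n, log(500), 0.5) *
    ifelse(classes == "lin36_shared", config$gbhtz_enrichment, 1)
  gb_cols <- unlist(lapply(gb_conditions, function(cc) sprintf("%s_rep%d", cc, seq_len(nrep))))
  gb_cond <- rep(gb_conditions, each = nrep)
  gb_mu <- matrix(0, n, length(gb_cols), dimnames = list(ids, gb_cols))
  gb_loss <- classes == "lin36_shared"
  for (j in seq_along(gb_cols)) {
    cc <- gb_cond[j]
    fold <- ifelse(gb_loss & cc %in% c("lin-35", "lin-36"), config$gbhtz_loss_fold, 1)
    gb_mu[, j] <- gb_base * fold
  }
  gbhtz <- list(counts = nb_matrix(gb_mu, config$gbhtz_dispersion), condition = gb_cond)

  with_prom <- ids[vapply(ids, function(g)
    !is.null(ann$gm$promoters[[g]]) && length(ann$gm$promoters[[g]]) > 0, logical(1))]
  k9_ids <- sprintf("prom_%s", with_prom)
  k9_conditions <- c("N2", "lin-35", "lin-15B")
  k9_base <- stats::rlnorm(length(with_prom), log(300), 0.5) *
    ifelse(classes[with_prom] == "lin15B_shared", config$k9_fold, 1)
  k9_cols <- unlist(lapply(k9_conditions, function(cc) sprintf("%s_rep%d", cc, seq_len(nrep))))
  k9_cond <- rep(k9_conditions, each = nrep)
  k9_mu <- matrix(0, length(with_prom), length(k9_cols), dimnames = list(k9_ids, k9_cols))
  k9_loss <- classes[with_prom] == "lin15B_shared"
  for (j in seq_along(k9_cols)) {
    cc <- k9_cond[j]
    fold <- ifelse(k9_loss & cc %in% c("lin-35", "lin-15B"), config$k9_loss_fold, 1)
    k9_mu[, j] <- k9_base * fold
  }
  k9 <- list(counts = nb_matrix(k9_mu, config$k9_dispersion), condition = k9_cond)

  celltypes <- c("germline", "neuron", "muscle", "hypodermis", "intestine",
                 "pharynx", "glia")
  total <- stats::rlnorm(n, log(50), 1)
  shares <- matrix(stats::rgamma(n * length(celltypes), shape = 1), n)
  shares <- shares / rowSums(shares)
  is15 <- classes == "lin15B_shared"
  if (any(is15)) {
    gf <- config$germline_fraction
    gshare <- stats::rbeta(sum(is15), gf * 30, (1 - gf) * 30)
    rest <- shares[is15, -1, drop = FALSE]
    rest <- rest / rowSums(rest) * (1 - gshare)
    shares[is15, ] <- cbind(gshare, rest)
  }
  tpm <- shares * total
  dimnames(tpm) <- list(ids, celltypes)

  truth <- data.frame(
    gene_id = ids,
    class = unname(classes),
    gbhtz_loss_lin35 = unname(gb_loss), gbhtz_loss_lin36 = unname(gb_loss),
    k9_loss_lin35 = ids %in% with_prom[k9_loss],
    k9_loss_lin15B = ids %in% with_prom[k9_loss],
    stringsAsFactors = FALSE)

  paths <- list()
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    paths$rna_counts <- file.path(outdir, "rna_counts.tsv")
    paths$rna_samples <- file.path(outdir, "rna_samples.tsv")
    write_count_tsv(rna$counts, rna$condition, paths$rna_counts, paths$rna_samples)
    paths$gbhtz_counts <- file.path(outdir, "gbhtz_counts.tsv")
    paths$gbhtz_samples <- file.path(outdir, "gbhtz_samples.tsv")
    write_count_tsv(gbhtz$counts, gbhtz$condition, paths$gbhtz_counts, paths$gbhtz_samples)
    paths$k9_counts <- file.path(outdir, "k9_counts.tsv")
    paths$k9_samples <- file.path(outdir, "k9_samples.tsv")
    write_count_tsv(k9$counts, k9$condition, paths$k9_counts, paths$k9_samples)
    paths$tpm <- file.path(outdir, "celltype_tpm.tsv")
    dt <- data.table::data.table(gene_id = rownames(tpm))
    for (j in seq_len(ncol(tpm))) dt[[colnames(tpm)[j]]] <- tpm[, j]
    data.table::fwrite(dt, paths$tpm, sep = "\t")
  }
  list(rna = rna, gbhtz = gbhtz, k9 = k9, tpm = tpm, truth = truth,
       paths = paths)
}

consensus_string <- function(p) {
  paste(pwm_bases[apply(p$matrix, 1, which.max)], collapse = "")
}

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Plant motif consensus instances into peak sequences
#'
#' For each peak sequence and each motif with a planting rate configured for
#' the peak's class, inserts the PWM consensus (random strand, random
#' offset) with the configured probability and records the insertion.
#'
#' @param config a [scenario_config()].
#' @param sequences named character vector of peak sequences.
#' @param classes named character vector: class per peak id (names matching
#'   `sequences`).
#' @param pwms list of [pwm()] objects (defaults to the bundled synthetic
#'   motif set).
#' @return list with `sequences` (modified) and `truth` (data.frame:
#'   peak_id, motif_id, offset, strand).
#' @export
plant_motifs <- function(config, sequences, classes, pwms = default_pwms()) {
  set.seed(stage_seed(config, "motifs"))
  by_id <- setNames(pwms, vapply(pwms, function(p) p$motif_id, ""))
  truth <- list()
  for (pk in names(sequences)) {
    cls <- classes[[pk]]
    rates <- config$motif_rates[[cls]]
    if (is.null(rates)) next
    for (m in names(rates)) {
      if (runif(1) >= rates[[m]]) next
      p <- by_id[[m]]
      if (is.null(p)) stop(sprintf("no PWM for configured motif %s", m))
      cons <- consensus_string(p)
      L <- nchar(cons)
      slen <- nchar(sequences[[pk]])
      if (L > slen) {
        warning(sprintf("motif %s longer than peak %s; skipped", m, pk))
        next
      }
      off <- sample.int(slen - L + 1L, 1L)
      strand <- sample(c("+", "-"), 1L)
      ins <- if (strand == "+") cons else revcomp_chr(cons)
      substr(sequences[[pk]], off, off + L - 1L) <- ins
      truth[[length(truth) + 1L]] <- data.frame(
        peak_id = pk, motif_id = m, offset = off, strand = strand,
        stringsAsFactors = FALSE)
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth)
    else data.frame(peak_id = character(0), motif_id = character(0),
                    offset = integer(0), strand = character(0))
  list(sequences = sequences, truth = truth)
}

#' Bundled synthetic DREAM-associated motif set
#'
#' Seven small synthetic PWMs named after the motif families of the target
#' taxonomy (E2F-a1/a2/b, CDE-CHR-a/b, LONG-a/b). These are stand-ins
#' constructed for simulation and testing, not the published matrices.
#'
#' @return List of [pwm()] objects.
#' @export
default_pwms <- function() {
  read_meme(system.file("extdata", "synthetic_dream_motifs.meme",
                        package = "dreamtargets"))
}

#' Simulate a complete scenario to disk
#'
#' Runs all generators, plants motifs into the promoter-peak windows of the
#' genome sequence, and writes every pipeline input plus
#' `ground_truth.json` and a `manifest.json` naming all files.
#'
#' @param config a [scenario_config()].
#' @param outdir output directory (created).
#' @return list with the in-memory objects and `manifest` (paths).
#' @export
simulate_scenario <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ann <- generate_annotation(config, outdir)
  chip <- generate_chip(config, ann, outdir)
  # plant motifs in +/-80 bp windows around planted peak centres of shared
  # classes, inside the +/-100 bp windows the pipeline will later cut out
  classes <- ann$classes
  shared <- names(classes)[classes %in% c("lin36_shared", "lin15B_shared")]
  centers <- vapply(shared, function(g) peak_center_for_gene(ann, g), integer(1))
  win <- GRanges(config$chrom, IRanges(pmax(1L, centers - 80L), centers + 80L))
  names(win) <- shared
  seqs <- get_peak_sequences(win, ann$genome)
  planted <- plant_motifs(config, seqs, classes[shared])
  genome_chr <- as.character(ann$genome[[config$chrom]])
  for (g in shared) {
    substr(genome_chr, start(win[g]), end(win[g])) <- planted$sequences[[g]]
  }
  ann$genome <- Biostrings::DNAStringSet(setNames(genome_chr, config$chrom))
  fasta <- file.path(outdir, "genome.fa")
  Biostrings::writeXStringSet(ann$genome, fasta)
  counts <- generate_counts(config, ann, outdir)
  meme_path <- file.path(outdir, "motifs.meme")
  write_meme(default_pwms(), meme_path)

  motif_truth <- planted$truth
  if (nrow(motif_truth)) {
    motif_truth$gene_id <- motif_truth$peak_id
    motif_truth$genome_offset <- start(win[motif_truth$peak_id]) + motif_truth$offset - 1L
  }
  ground_truth <- list(
    classes = as.list(classes),
    gbhtz_loss = counts$truth$gene_id[counts$truth$gbhtz_loss_lin35],
    k9_loss = counts$truth$gene_id[counts$truth$k9_loss_lin35],
    binding_changes = chip$binding_truth,
    planted_motifs = motif_truth,
    scenario = list(seed = config$seed, n_genes = config$n_genes,
                    effect_lfc = config$effect_lfc,
                    nb_dispersion = config$nb_dispersion))
  gt_path <- file.path(outdir, "ground_truth.json")
  jsonlite::write_json(ground_truth, gt_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  manifest <- list(
    chrom = config$chrom, chrom_length = config$chrom_length,
    gff = ann$paths$gff, promoter_bed = ann$paths$promoter_bed,
    genome_fasta = fasta, chip = chip$paths$chip, k9_track = chip$paths$k9,
    rna_counts = counts$paths$rna_counts, rna_samples = counts$paths$rna_samples,
    gbhtz_counts = counts$paths$gbhtz_counts, gbhtz_samples = counts$paths$gbhtz_samples,
    k9_counts = counts$paths$k9_counts, k9_samples = counts$paths$k9_samples,
    tpm = counts$paths$tpm, motifs_meme = meme_path,
    ground_truth = gt_path)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  list(config = config, ann = ann, chip = chip, counts = counts,
       planted_motifs = motif_truth, manifest = manifest,
       manifest_path = file.path(outdir, "manifest.json"))
}
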