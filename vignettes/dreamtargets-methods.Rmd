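---
title: "Classifying DREAM-complex targets from ChIP-seq and RNA-seq: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying DREAM-complex targets from ChIP-seq and RNA-seq: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The biological question

The DREAM complex (DP, Rb-like, E2F and MuvB) silences cell-cycle and
germline genes in quiescent cells. In starved first-stage *C. elegans*
larvae, the pocket protein LIN-35/Rb cooperates with two THAP-domain
proteins, LIN-36 and LIN-15B, and the two appear to repress largely
distinct gene sets through different chromatin mechanisms: gene-body
enrichment of the histone variant H2A.Z/HTZ-1 at one class, and promoter
H3K9me2 (deposited by MET-2) at a germline-biased class.

`dreamtargets` implements the full computational taxonomy behind that
picture as a reusable, tested pipeline:

1. call candidate peaks per factor as concave regions of smoothed coverage
   and keep those reproduced across replicates;
2. merge peaks across factors and rescale to ±100 bp around midpoints;
3. assign peaks to genes through promoter-anchored windows (gene-span
   fallback for promoter-less genes);
4. test differential expression per mutant with a negative-binomial Wald
   test; call genes up at FDR < 0.01 and LFC > 0.5849 (log2 1.5), down at
   FDR < 0.01 and LFC < −1;
5. define direct targets (up in the factor's mutant AND bound), then
   LIN-36-shared = direct for LIN-35 and LIN-36 but not up in *lin-15B*,
   and LIN-15B-shared = direct for LIN-35 and LIN-15B but not up in
   *lin-36*;
6. quantify gene-body H2A.Z (TSS+500 bp to TTS, genes ≥ 500 bp, top 90% of
   wild-type coverage) and promoter H3K9me2 (peaks over −500–0 bp promoter
   windows, restricted to wild-type H3K9me2 domains), and flag losses at
   padj < 0.001 and < 0.01 respectively with LFC < 0;
7. test differential binding of peak windows (padj < 0.001, sign of LFC);
8. score germline expression specificity (germline TPM over summed TPM
   across cell types) and compare classes by Wilcoxon rank-sum;
9. scan peak sequences with PWMs at exact p ≤ 1e-4, resolve overlapping
   hits by the CDE-CHR > LONG > E2F hierarchy, keep motifs present in
   > 30% of a class, and test class association by Fisher's exact test
   with BH correction.

Because the real datasets require reprocessing deposited sequencing data,
every stage is exercised instead on a synthetic world with planted,
machine-readable ground truth (`simulate_scenario()`); the pipeline never
sees the truth, and the report scores recovery against it.

## Statistical methods

### Peak calling

Coverage is smoothed by discrete Gaussian convolution (default sigma 75 bp,
on the order of ChIP fragment size; kernel truncated at 4 sigma; reflective
boundary; FFT implementation checked against direct convolution in the
tests). Candidate peaks are maximal runs (≥ 3 bp) where the central second
difference of the smoothed track is negative and the smoothed height
reaches `min_height`. A relative epsilon (1e-9 × track maximum) on the
second difference absorbs FFT rounding on flat stretches; since it scales
with amplitude, calls remain invariant under scaling, and adding a
constant to a track leaves boundaries unchanged when `min_height` is
shifted accordingly.

Replicate reproducibility replaces IDR (an external published method) with
a declared, simpler filter: candidates are the merged union of replicate
calls, kept when ≥ 1 bp overlaps peaks from at least `min_support = 2`
replicates.

Broad-domain calling replaces MACS: a `min_length` (500 bp) window slides
over the track and its sum is tested against a Poisson rate of
max(global mean, local mean) × window, requiring upper-tail p < 1e-5 and
fold ≥ 2; qualifying windows are unioned and short domains dropped. The
local-background window defaults to 50 kb: it exists to guard against
regional background drift, and it must stay large relative to the domains
being called — a 5 kb domain inside a 10 kb local window contributes half
of its own "background" and masks itself.

### The negative-binomial test

Counts are normalised by median-of-ratios size factors (computed over
features with all-positive counts; an `sf` argument accepts externally
derived factors, e.g. spike-in based). The variance model is
Var = μ + αμ². Per-feature method-of-moments dispersion estimates are
smoothed fully to the mean-dispersion trend — the average of the unfloored
moment estimates over features with normalised mean > 5, floored at 1e-8 —
i.e. a common-dispersion model in the edgeR tradition. At 4 vs 4
replicates the per-feature estimate has ~6 degrees of freedom; carrying
its noise into the Wald denominator either inflates type-I error (when
used directly) or sacrifices power (when floored at the trend). Both
alternatives were evaluated by simulation during development; the common
dispersion is the only variant that was simultaneously calibrated
(type-I fraction at p < 0.05 within [0.04, 0.06] across seeds for 5,000
null genes at mean 100, α 0.1) and near-optimally powered. The trade-off
is that genuinely dispersion-heterogeneous features are tested against an
averaged α — acceptable for the designed worlds here, and declared.

The log2 fold change uses a 0.5 pseudo-count; the Wald statistic uses the
delta-method standard error on the log2 scale with a normal reference;
all-zero features report lfc 0 and p 1. There is no fold-change shrinkage
and no outlier handling: acceptance is calibration and power on synthetic
data, not numeric identity with DESeq2 (which the test suite uses only as
an independent cross-check on strong planted effects).

For the H3K9me2 loss test the pipeline computes size factors on the *full*
promoter-peak table and tests the domain-filtered subset: the filtered
subset is dominated by mark-losing promoters (as it is biologically —
H3K9me2 domains concentrate at the germline-biased class), so normalising
within it would absorb the signal being tested.

ChIP-derived integer counts for peak windows are pseudo-counts:
round(window coverage sum / 200 bp fragment length), the declared stand-in
given that the pipeline starts from normalised tracks rather than
alignments.

### Exact set statistics

The hypergeometric upper tail, two-sided Fisher exact test (sum of tables
no more probable than observed; sample odds ratio reported), Wilcoxon
rank-sum (exact permutation null by dynamic programming when the smaller
group has ≤ 10 observations and no ties; otherwise tie-corrected normal
approximation with continuity correction) and Welch's t are implemented
self-contained in log space — overlap p-values in this problem regime can
be far below double underflow if computed naively. Base R's
`phyper`/`fisher.test`/`wilcox.test`/`t.test` appear in the tests as
independent cross-checks only. Where the underlying study says only
"a t test", Welch's unequal-variance form was chosen.

### Motif scanning

Scores are log2 odds against a background model (default uniform; the
underlying scanning tool's background is not recoverable, so it is a
config input). Zero probabilities are floored at 1e-4 and rows
renormalised. P-values are exact under the background model, computed by
dynamic programming over the score distribution discretised at 1e-3 log2
units — the only approximation, validated in the tests against exhaustive
4^L enumeration. Both strands are scanned; windows containing N are
skipped. Overlap resolution keeps the highest-priority family
(CDE-CHR > LONG > E2F > other), breaking ties within a family by lowest
p-value, as a greedy sweep (idempotent). "Present in more than 30% of a
class" is strict, as printed. The bundled
`inst/extdata/synthetic_dream_motifs.meme` matrices are *synthetic
stand-ins* named after the motif families, constructed for simulation and
testing; they are not the published matrices.

## The synthetic world

`scenario_config()` states the world once; its defaults are the conditions
everything downstream is tested under:

- 1,000 genes (600–1,200 bp, 1–3 transcripts, random strand) in equal
  slots on a 3 Mb chromosome (the generator requires ≥ 3 kb per gene);
  promoter annotated with probability 0.9, covering the 500 bp 5' of the
  TSS.
- Planted classes: 150 LIN-36-shared, 50 LIN-15B-shared, 100 LIN-35-only,
  the rest null — echoing the relative class proportions of the real
  taxonomy without claiming to reproduce its counts.
- RNA counts: NB with lognormal base means (meanlog log 100, sdlog 1),
  dispersion 0.1, 4 replicates per condition; planted classes are
  derepressed at log2 fold change 2 in their designated mutants
  (LIN-36-shared in *lin-35* and *lin-36*; LIN-15B-shared in *lin-35*,
  *lin-15B* and *met-2*; LIN-35-only in *lin-35*).
- ChIP coverage: Gaussian peaks (sigma 75 bp) at promoter centres over a
  flat Poisson background of 1; amplitudes 60/30/45/40 for
  LIN-36-shared / LIN-15B-shared / LIN-35-only / factor-specific peaks —
  a strong-peak regime (tens of fold over background, as in
  BEADS-normalised tracks) chosen so that peak-window pseudo-counts carry
  enough reads for the differential-binding demonstration at desk scale.
  Factor-specific peaks at null genes tune the co-binding rates (defaults
  0.95 for LIN-36 vs LIN-35 and 0.72 for LIN-15B vs LIN-35, as tunable
  rates, not fixed truths). Promoter-less target genes get their peak just
  inside the gene 5' end, so binding is recoverable under the span-fallback
  assignment rule. Planted binding changes: LIN-35 signal ×0.4 at
  LIN-36-shared peaks in *lin-36*, ×2.5 at LIN-15B-shared peaks in
  *lin-15B* (facilitation vs mutual inhibition).
- Gene-body H2A.Z counts: 3-fold enrichment on LIN-36-shared gene bodies,
  loss fold 0.5 in *lin-35*/*lin-36*, dispersion 0.02 (window-level ChIP
  counts are much less dispersed than gene-level RNA). Promoter H3K9me2:
  3-fold enrichment and 2 kb coverage domains at LIN-15B-shared promoters,
  loss fold 0.5 in *lin-35*/*lin-15B*.
- Cell-type TPM over 7 types; LIN-15B-shared genes draw their germline
  share from Beta(24, 6) (mean 0.8), others are symmetric-Dirichlet.
- Motif planting per class: CDE-CHR-a at 0.6 and E2F-a1 at 0.5 on
  LIN-36-shared peaks; E2F-b at 0.7 and LONG-a at 0.6 on LIN-15B-shared
  peaks.

Each generator draws from its own stream (seed + fixed stage offset), so
stage order never changes outputs and everything is bit-reproducible from
the seed.

What the generator does *not* emulate: mappability and GC structure,
fragment-length effects, read-level noise, overlapping genes, operons,
chromatin-domain autocorrelation, and mitochondrial/unplaced contigs
(which the source analyses partly exclude; the toy genome simply has
none). A green end-to-end test therefore establishes that the
implementation of the rules is correct and calibrated under the stated
world — not that the biological conclusions of the source study are
reproduced.

## Numerical and design choices

- Internally all intervals are `GRanges` (1-based closed); BED/bedGraph
  and GFF3 are converted at the I/O boundary. One convention everywhere
  kills off-by-one bugs.
- Midpoints of even-length peaks are left-biased (floor of the mean of the
  0-based bounds); book-ended intervals merge; peaks are clipped at the
  chromosome start at parse time, right-clipping deferred to operations
  that know the chromosome length.
- Gene-body windows follow the boundary-coordinate arithmetic of the
  assignment rules exactly; the plus- and minus-strand formulas are
  mirror images under coordinate reflection of half-open intervals.
- Quantiles use linear interpolation (type 7); ties at the top-90% cutoff
  are retained.
- The expression universe for enrichment tests defaults to all genes in
  the count table (configurable); the source leaves the universe
  unstated.
- A peak assigned to several genes counts toward each gene's binding
  status; when promoters flank both gene ends, only the 5' side extends
  the assignment window.
- The pipeline orchestrator (`run_pipeline()` over a `pipeline_config()`)
  is a library function rather than a shell tool; every published
  threshold is a named config key defaulting to its printed value, and
  stages toggle independently.

## Known limitations

- The NB test's common dispersion is a deliberate simplification; data
  with strong dispersion heterogeneity deserve per-feature shrinkage
  (DESeq2/edgeR) rather than this package's test.
- Differential binding from coverage pseudo-counts discards read-level
  information; with shallow peaks (low amplitude × 2 replicates) the
  binding stage is underpowered, which the report shows honestly rather
  than masking.
- The domain caller is a stand-in: no control track, no model building,
  and a single window scale.
- Motif inclusion/association operate on the bundled synthetic matrices
  unless real PWMs are supplied in MEME minimal format.
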