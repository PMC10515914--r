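---
title: "Nuclear speckle state, speckle targeting motifs, and DNA-speckle association: methods"
author: "speckletools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nuclear speckle analysis methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(speckletools)
```

# Scope

Nuclear speckles are membrane-less nuclear bodies enriched in RNA
processing and export factors, marked by the SON and SRRM2 proteins. Two
coupled observations motivate this package: (i) the RNA expression of
speckle-resident-protein genes varies across tumors along a reproducible
axis ("speckle signature"), and in clear cell renal cell carcinoma this
axis correlates with survival and with the nuclear radial position of SON
by immunofluorescence; (ii) transcription factors such as p53 and
HIF-2alpha physically recruit a subset of their target genes to speckles
through a short proline-spaced protein region, the speckle targeting motif
(STM), and disrupting this recruitment selectively blunts induction of the
speckle-associating targets.

`speckletools` implements the computational side of that program as five
units, each paired with a synthetic-data generator that plants a known
truth:

1. a multi-cohort **speckle signature** pipeline (PCA weights, sign
   anchoring, concordance, gene selection, scoring, survival testing);
2. an **STM scanner** (candidate rule plus five residue-composition
   criteria) and a Waterman-Eggert style **best local alignment**;
3. a sliding-window **differential DNA-speckle association** caller over
   SON proximity coverage (TSA-seq / Cut&Run style), with domain merging
   and gene classification;
4. **n-tile integration** of speckle association against expression
   responses;
5. per-nucleus **radial-distribution imaging** measurements with
   median-split survival ranking.

The drivers under `analysis/` run these units in order on the synthetic
data and write their tables under `results/`.

# Speckle signature

For each cohort, expression of the designated speckle genes is
log2(x + 1)-transformed, each gene centered and scaled to unit variance,
and the first principal component computed with samples as observations
(`pc1_weights()`). Whether expression should be log-transformed or scaled
before this PCA is genuinely open; we default to both, because the
downstream score is z-score based and unscaled PCA would be dominated by
a handful of high-variance genes. Both choices are arguments.

PC1 of a correlation-like matrix is defined up to sign, so each cohort's
rotation is anchored by forcing the weight of *SON* to be non-positive.
Concordance between cohorts is the Pearson correlation of the anchored
weight vectors over shared genes; the concordant block is found by
average-linkage clustering on `1 - r`, cutting at `r = 0.5` (configurable)
and keeping the largest cluster whose mean off-diagonal correlation clears
the same threshold. Genes whose anchored weights are strictly nonzero with
a consistent sign across every cohort of the block enter the signature:
positive weights become "Signature I-high", negative (SON-like) weights
"Signature II-high". The class orientation follows the score formula below
and the observation that normal tissues display the Signature II pattern.

The per-sample score is

```
score_s = mean(z of Signature-I genes) - mean(z of Signature-II genes)
```

with per-gene z-scores computed within cohort across the scored samples by
default; scores then sum to exactly zero per cohort, a property the tests
assert at 1e-9 x n. A frozen-reference mode (`z_reference`) supports
scoring normals against tumor-fit parameters. Groups are assigned either
by top/bottom quartile (ties broken by stable sample order) or by score
sign, and tested by Kaplan-Meier/log-rank per cohort (`survival` package;
no cross-cohort multiplicity correction, matching per-cancer reporting).
Cohorts under 50 samples are excluded by default.

# STM scanner

A candidate is every 62-residue window `x(30)-[TSED]-P-x(30)`: a central
threonine, serine, glutamate or aspartate immediately followed by proline,
with 30 residues of context on each side. The central residue class is
taken from the bracket notation `[TSED]`; the package exposes it as an
argument for users who prefer a different class. Five criteria filter
candidates (0-based window indexes; the central pair sits at 30-31):

1. no run of more than 4 consecutive prolines in the window;
2. at least 3 prolines at the seven positions spaced every 5 residues from
   the center (indexes 11, 16, 21, 26, 36, 41, 46);
3. at least 5 of T/S/E/D among the C-terminal 30 residues;
4. at least 7 of A/M/V/F/L/I/G among the N-terminal 30 residues;
5. fewer than 16 R/H/K in the whole window.

Criterion 1 is evaluated within the window only, and "any 3 of the 7"
spaced prolines are accepted regardless of side. Non-standard residues
(X, U, B, Z) satisfy no residue class and break proline runs. Overlapping
passing windows are all reported; proteins are counted once.

`best_local_match()` computes the optimal affine-gap local alignment
(the top Waterman-Eggert alignment) via `Biostrings::pairwiseAlignment`,
with EMBOSS-Matcher-style defaults: BLOSUM62, gap open 14, gap extend 4
(a gap of length L costs `open + L * extend`). Among equal-scoring optima
the minimal alignment is reported: boundary columns contributing zero
score are trimmed, which is how Matcher prints its spans. Percent
similarity is the fraction of alignment columns whose substitution score
is positive. On the vendored p53 (P04637) and HIF-2alpha (NP_001421.2)
sequences this yields a gapless 29-column match, p53 residues 62-90
against HIF-2alpha 450-478, 55.2% similarity — the region containing the
p53 transactivation-domain proline repeat and HIF-2alpha's first STM. The
vendored HIF-2alpha fixture carries its C-terminal 270 residues masked as
X (see the FASTA header); all coordinates used by the analyses lie in the
unmasked region.

# Differential DNA-speckle association

SON proximity coverage is quantified over sliding windows of 50 and
100 kb, stepped by one tenth of the window size, so each interior base is
covered by exactly 10 windows of each size. Per replicate, bin counts are
scaled to counts-per-million, the matched background track (input for
TSA-seq, IgG for Cut&Run) is subtracted in cpm and clamped at zero, and
the per-bin signal summed over each window.

Differential testing uses a self-contained moderated two-sample t on
`log2(signal + 1)`: the per-window pooled variance is shrunk toward the
**global median** variance with prior degrees of freedom `d0 = 10`, and
the statistic referred to a t distribution with `d0 + n1 + n2 - 2`
degrees of freedom. The median, not the mean, is the shrinkage target:
under clamped background subtraction, windows straddling domain
boundaries flip between zero and positive signal across replicates and
their log-scale variances are orders of magnitude above typical windows;
a mean target would absorb those outliers and destroy power genome-wide.
Windows below a minimum mean signal (default 1 cpm) are removed before
testing, and Benjamini-Hochberg adjustment is applied per window size.
The engine deliberately replaces the original occupancy-analysis stack
(negative-binomial peak-set modeling): the scientific content here is the
window/merge/threshold semantics, not the count model.

Windows passing `padj < 0.01` with the requested direction are pooled
across the two sizes and merged when overlapping or book-ended
(`IRanges::reduce`); a domain's padj is its best member window. Genes are
classified by overlap (>= 1 bp of the gene span, or the TSS in `tss`
mode): *associating* if a decreasing domain with `padj < 0.01` overlaps in
either assay, *non-associating* if every overlap has `padj > 0.1` in both
assays or there is no overlap, otherwise *ambiguous*. Per-gene SON signal
is the mean background-subtracted cpm over the gene span (flank
configurable; the exact footprint of the original per-gene protocol is
not restated in our sources, so the gene span is the default).

Target-gene sets are plain set algebra over differential-expression
tables with the stated thresholds (e.g. decreasing at `padj < 0.1` at any
timepoint — a union across timepoint tables; a tumor-up filter at
`p < 0.05` and `log2FC > 0.3` applied by intersection). `ntile_integration()`
ranks genes by one measurement (ties broken by gene id), cuts them into n
bins differing in size by at most one, and tests each bin's paired metric
against zero (Wilcoxon signed-rank by default; t-test optionally).

# Imaging

Nuclei are segmented from the DAPI channel by Gaussian smoothing, global
Otsu threshold, hole filling and connected components, discarding objects
below `min_area` or touching the border (EBImage primitives). For the
radial distribution, each pixel receives a normalized radial coordinate
`r = 1 - d_edge / max(d_edge)` from the Euclidean distance-to-background
transform of its nucleus mask — a definition that extends cleanly to
non-circular nuclei — and the nucleus is cut into four concentric bins of
equal normalized-distance width, bin 1 most central. The reported
fractions f1..f4 are the SON-intensity shares per bin; they sum to 1 and
are invariant to intensity scaling. On an ideal uniform disk the bins
approach the annulus areas (1/16, 3/16, 5/16, 7/16); the tests verify
convergence at radii 25-100 px with error below 0.02. Equal-area rings
would be an alternative binning; equal normalized distance was fixed
because it makes this analytic check exact.

Speckle objects are called by a per-nucleus Otsu threshold on SON within
the mask (vector histogram implementation, since the pixel set is not
rectangular); components of at least 2 px count, and "extra-large"
speckles exceed a 50 px area threshold at the synthetic scale (no
physical value is prescribed; configurable). A per-nucleus SON
coefficient of variation stands in as the only texture measurement; full
Haralick textures are out of scope. Per-sample summaries are medians over
nuclei. `median_split_survival()` splits the cohort at the median of each
measurement, log-rank tests the halves, and ranks measurements by
`-log2 p`; constant or degenerate-split measurements are skipped with a
warning.

# Synthetic data: what is emulated, and what is not

All generators are deterministic given a seed and validate their planted
truth before returning.

**Expression panels** (`gen_expression_panel()`): per cohort, a latent
sample score `a_s ~ N(0,1)` shifts log2 expression by `+beta_expr * a_s`
for Signature-I-planted genes and `-beta_expr * a_s` for
Signature-II-planted genes (SON is planted in the Signature II block, so
anchoring recovers the intended orientation). Discordant cohorts re-sign
the per-gene weights at random, which destroys cross-cohort weight
concordance without removing within-cohort structure. Survival is
exponential with hazard `baseline * exp(beta_haz * a_s)` in a single
designated cohort and independent of `a_s` elsewhere; censoring is
administrative uniform on `[0, T_max]` with `T_max` solved so the expected
censored fraction matches `censor_frac` — the simplest mechanism
independent of the score. Defaults: 5 concordant + 2 discordant cohorts
of 100 samples, 60 speckle genes (20 + 30 planted), 140 background genes,
`beta_expr = 2`, noise sd 1, `beta_haz = 1`, 30% censoring.

**Proteomes** (`gen_proteome()`): background residues follow a fixed
human-like amino-acid frequency table (built-in, not configurable, for
test stability). Planted windows are constructed to satisfy all five
criteria and decoys mutated from passing windows to fail exactly their
designated criterion; both constructions are re-validated against the
criteria implementation at build time, and rejection sampling guarantees
background and decoy proteins contain no passing window at all.

**SON tracks** (`gen_track_truth()` / `gen_son_tracks()`): six
non-overlapping 1 Mb domains on a 12 Mb single-chromosome genome at 5x
the background rate, three of them depleted to `d = 0.4` in the treatment
condition; counts are Poisson per 5 kb bin (a negative-binomial size
knob adds overdispersion for robustness experiments), with uniform
Poisson background tracks. Megabase domains mirror the megabase-scale
speckle-associated neighborhoods the biology suggests; they also matter
numerically, because merged window calls inevitably over-extend true
domains by up to one window size per side, which caps the achievable
recovery Jaccard for short domains regardless of depth.

**Nuclei images** (`gen_nuclei_images()` / `gen_imaging_cohort()`):
non-overlapping ellipses by rejection sampling (segmentation is not the
object under test), Gaussian speckle spots with centers drawn at
normalized elliptical radius `0.92 * U^((1+b)/2)` — area-uniform at bias
`b = 0`, increasingly central as `b` grows — plus Gaussian noise. Cohorts
draw a per-sample bias from `[0, 2]` and pair it with survival through
`gen_survival_from_scores()`. Per-sample medians need a realistic nucleus
count to stabilize; the cohort default is 12 nuclei per sample (the
tissue arrays this emulates are scanned in full, with far more), and the
rank-recovery checks use 24.

The generators do not emulate read-level sequencing artifacts, copy
number or batch effects, multi-channel PSF optics, or FFPE autofluorescence;
passing recovery tests on them demonstrates correctness of the analysis
logic under the stated noise models, not robustness to every artifact of
real data.

# Numerical choices and degenerate inputs

* Upper-quartile normalization scales each sample so the 75th percentile
  of its nonzero values (type-7 quantile) equals 1000; all-zero samples
  are an error.
* Zero-variance genes are dropped from PCA with a warning; a
  zero-variance anchor is an error. Constant reference genes contribute
  zero to z-scores rather than NaN.
* Zero-variance windows with zero fold change get `t = 0, p = 1`;
  with nonzero fold change the statistic is infinite.
* Quartile ties and ranking ties break by stable input order / gene id.
* Nuclei with zero SON are flagged rather than dividing by zero; uniform
  SON yields a low-contrast flag from the speckle caller; constant or
  degenerate-median measurements are skipped in survival ranking.
* All analysis-facing problem sizes used by the tests and the acceptance
  script (12 Mb genome, 700-sample panels, 80-sample imaging cohorts,
  10-20 simulation seeds) were chosen as the smallest sizes at which the
  recovery criteria are comfortably inside their design bounds.

# Known limitations

* The signature pipeline treats cohorts as given and does not model
  batch or purity; the concordant-block heuristic (average linkage at
  `r = 0.5`) is a reasonable resolution of an under-specified step and is
  configurable.
* The moderated-t window engine is a deliberate, documented substitute
  for negative-binomial occupancy modeling; absolute p-values differ from
  such engines even though threshold semantics match.
* Percent similarity depends on the substitution matrix's positive
  entries; matrices other than BLOSUM62 will print different
  similarities for the same alignment.
* The radial measurement assumes one connected mask per nucleus; touching
  nuclei that survive segmentation as one object bias f1 downward.
* The vendored HIF-2alpha sequence is masked beyond residue 600; scans
  of the masked region report nothing there by construction.
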