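# speckletools

Nuclear speckles are membrane-less nuclear bodies, marked by the SON
protein, that concentrate RNA processing and export factors. Tumors vary
along a reproducible "speckle signature" axis of speckle-resident-protein
gene expression, and in clear cell renal cell carcinoma this axis — and
the nuclear radial position of SON by immunofluorescence — tracks patient
survival. Mechanistically, transcription factors such as p53 and
HIF-2alpha recruit a subset of their target genes to speckles through a
short proline-spaced **speckle targeting motif (STM)**, boosting those
genes' expression.

`speckletools` is an R package plus analysis workflow for the
computational layer of that biology, aimed at genomics analysts who want
to score speckle state in expression cohorts, scan proteomes for STMs,
call differential DNA-speckle association from SON proximity sequencing,
and quantify speckle radial phenotypes in images. Every analysis ships
with a synthetic-data generator that plants a known truth, so the whole
pipeline is testable end to end without external downloads.

## The five components

1. **Speckle signature** — per-cohort PCA of speckle-gene expression
   (genes log2-transformed, centered, scaled; samples as observations),
   PC1 weights sign-anchored so SON is negative, Pearson concordance of
   weights across cohorts, selection of consistently signed genes into
   Signature I (positive) and Signature II (SON-like, negative), and the
   per-sample score

   `score = mean(z SigI genes) − mean(z SigII genes)`

   with z-scores per gene within cohort. Groups (top/bottom quartile or
   score sign) feed Kaplan–Meier / log-rank survival tests.
2. **STM scanner** — candidates are 62-mers `x(30)-[TSED]-P-x(30)`;
   five criteria filter them (≤4 consecutive prolines; ≥3 of 7 prolines
   spaced every 5 residues from the center; ≥5 T/S/E/D C-terminal; ≥7
   A/M/V/F/L/I/G N-terminal; <16 R/H/K total). `best_local_match()` is a
   Waterman–Eggert-style local alignment (BLOSUM62, gap open 14 /
   extend 4) with EMBOSS-Matcher span semantics.
3. **Differential speckle association** — SON coverage quantified over
   50/100 kb windows slid by 1/10 window size, background-subtracted in
   cpm, tested with a moderated t (variance shrunk toward the global
   median, prior df 10), BH-adjusted per window size; significant windows
   merged into domains; genes classified associating (padj < 0.01 in
   either assay) / non-associating (padj > 0.1 in both) / ambiguous.
4. **Integration** — thresholded target-gene set algebra and n-tile
   analyses of per-gene SON signal against expression responses.
5. **Imaging** — nucleus segmentation from DAPI, per-nucleus SON
   intensity and speckle objects, 4-bin radial distribution (bin 1 most
   central; uniform disk gives 1/16, 3/16, 5/16, 7/16), per-sample
   medians, and median-split survival ranking of all measurements.

## Worked example

The alignment that motivated the STM definition, on the vendored p53 and
HIF-2alpha sequences:

```r
library(speckletools)
p53 <- read_proteome(system.file("extdata", "p53_P04637.fasta",
                                 package = "speckletools"))
hif <- read_proteome(system.file("extdata", "hif2a_NP_001421.2.fasta",
                                 package = "speckletools"))
best_local_match(as.character(p53[[1]]), as.character(hif[[1]]))
#> Local alignment: score 49, 29 columns
#>   A 62-90  EAPRMPEAAPPVAPAPAAPTPAAPAPAPS
#>   B 450-478  EAGSLPAFTVPQAAAPGSTTPSATSSSSS
#>   identity 37.9%, similarity 55.2%
```

The 29-residue match pairs the p53 transactivation-domain proline repeat
(residues 62–90) with HIF-2alpha residues 450–478 — the region containing
its first STM — at 55.2% similarity (16 of 29 columns score positively
under BLOSUM62). Scanning the same two sequences finds one STM window in
each:

```r
scan_proteome(c(p53, hif))$windows[, c("protein_id", "start_1based")]
#>   protein_id start_1based
#> 1     P04637           51
#> 2 NP_001421.2          439
```

i.e. the p53 window covering residues 51–112 (central TP at 81–82) and
the HIF-2alpha window 439–500 (central TP at 469–470).

The full synthetic workflow runs as numbered drivers:

```sh
Rscript analysis/01_simulate.R     # all synthetic inputs + truth sidecars
Rscript analysis/02_stm_scan.R     # alignment + proteome scans
Rscript analysis/03_signature.R    # signature derivation, scores, survival
Rscript analysis/04_association.R  # differential domains, gene classes
Rscript analysis/05_imaging.R      # radial measurements, survival ranking
```

Each driver prints what it found (e.g. `03_signature.R` reports the
recovered 20 + 30 signature genes and a log-rank p < 0.01 only in the
survival-coupled cohort; `04_association.R` reports the merged decreasing
domains and their Jaccard ≈ 0.84 against the planted depletions) and
writes its tables under `results/`.

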