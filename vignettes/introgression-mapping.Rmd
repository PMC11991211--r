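---
title: "Mapping terminal alien introgressions and designing KASP markers"
author: "IntroKASP authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping terminal alien introgressions and designing KASP markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(IntroKASP)
```

## The problem

Polyploid wheat breeding routinely moves chromosome segments between
relatives: a distal segment of an alien donor chromosome (here the short arm
of chromosome 2D from *Aegilops tauschii*, carrying the dominant wax
inhibitor *Iw2*) replaces the homoeologous distal segment of a recipient
chromosome (2AS of durum wheat). Characterising such a line requires three
computational steps, which this package implements end to end:

1. **Breakpoint identification from windowed read depth.** Resequencing
   reads aligned against a *merged* recipient+donor reference show depth
   close to the genome-wide mean wherever a segment is present and close to
   zero wherever it is absent. Segmenting per-window depth into
   present/absent runs locates the translocation breakpoints and sizes the
   added and deleted fragments.
2. **Bulked-segregant candidate-region mapping.** An F2 population
   segregating the dominant inhibitor is split into phenotypically
   contrasting bulks; the difference in per-SNP donor-allele read fraction
   between bulks (the Delta SNP index) peaks at the causal locus.
3. **Marker pre-selection and KASP design.** SNPs inside the implicated
   interval pass a six-criterion filter cascade and are converted into
   kompetitive allele-specific PCR (KASP) primer sets for routine
   genotyping.

Because the raw sequencing of such studies is rarely re-analysable at the
desk, the package ships a first-class synthetic-data module that emulates
the statistical structure each stage assumes, so every stage is tested
against known truth.

## Depth model and segmentation

Each chromosome is tiled with fixed windows (default 100 kb, matching the
reporting granularity of depth plots in resequencing studies). Window depth
is modelled as Poisson: mean `meanDepth` (default 35x) where the underlying
segment is present, `backgroundNoise` (default 0.5x) where it is absent, and
the length-weighted mixture in the single window containing a breakpoint.
The background term emulates residual homoeologous mismapping; it is
deliberately non-zero so that thresholding is a real decision rather than a
trivial zero test.

Calling proceeds in three steps:

* `normalizeDepth()` divides all depths by the *median* window depth over
  fully present control chromosomes, so present windows have expectation
  1.0. The median is robust to the handful of atypical windows real
  references contain.
* `classifyWindows()` calls a window absent when its normalized depth is
  strictly below `absentThreshold = 0.25`. At 35x this sits many Poisson
  standard deviations from both states: P(Poisson(35) < 8.75) and
  P(Poisson(0.5) >= 8.75) are both negligible, so single-window
  misclassification is rare; a window exactly at the threshold is present.
* `segmentStates()` enforces a minimum run length (`minRun = 3` windows) by
  *minimal-change smoothing*: the output is the state sequence with every
  maximal run at least `minRun` long that differs from the input in the
  fewest windows, computed exactly by dynamic programming. Among equally
  close solutions the one agreeing with the input at the earliest positions
  is returned, which reproduces the intuitive "absorb a short run into its
  neighbours, ties to the preceding segment" behaviour and makes the result
  deterministic. An exhaustive-search oracle in the test suite pins this
  semantics for every string of up to 20 windows. We chose plain
  threshold-plus-smoothing over an HMM because at 35x the two states are
  essentially non-overlapping and an HMM would add parameters without
  adding power.

`detectTranslocation()` composes the three steps and reports the distal
(position-0) present segment on the donor chromosome and the distal absent
segment on the recipient, named by the `T<donor>S-<recipient>S.<recipient>L`
convention. Breakpoints are reported at window boundaries: precision is
inherently +/- one window, which matches the 0.1 Mb granularity at which
segment sizes are rounded (`size_mb`). A chromosome whose distal segment has
the wrong state, or that consists of a single segment, yields an explicit
no-call object rather than an error. Coordinates are 0-based half-open in
TSV/BED files and 1-based inside `GRanges`/VCF/GFF3, converted only at the
I/O boundary.

```{r depth-example, eval = FALSE}
prof <- simulateDepthProfile(GenomeSpec(), DepthSimParams(seed = 7))
detectTranslocation(prof, donorChrom = "2D", recipientChrom = "2A")
```

## F2 bulk model and Delta SNP index

`simulateF2Bulks()` builds each F2 individual from two gametes whose
parental origin switches along the chromosome with the Haldane map function
at `cmPerMb` (default 1 cM/Mb — a typical distal-wheat figure; any monotone
map would do for recovery testing, and the map density only rescales
linkage decay). The causal genotype determines the phenotype under complete
dominance: one donor (inhibitor) copy suppresses wax, so the expected
phenotype ratio is 3:1 non-glaucous:glaucous. Bulks of `bulkSize = 30` per
phenotype mirror common BSA designs; parental bulks are fixed for opposite
alleles. Read counts per SNP and bulk are Binomial over a Poisson
(`bulkDepth = 50`) total — the study's per-SNP bulk depth is not published,
so this is a one-time realistic choice, as are the SNP count (200 over the
distal 20 Mb), the per-sample missing-call rate (0.05) and the flank GC
(0.5).

At the causal locus, enumerating the 1:2:1 F2 classes under dominance gives
a donor-allele frequency of 0 in the glaucous bulk and 2/3 in the
non-glaucous bulk, hence an expected Delta SNP index of 2/3; at unlinked
loci the expectation is 0. `deltaSnpIndex()` polarises the alt allele to the
donor parent first and drops SNPs whose parental bulks are not near-fixed
for opposite alleles (index >= 0.9 / <= 0.1), since such sites carry no
mapping information. A zero-depth bulk yields a missing index, never 0.

Significance is assessed against `nullEnvelope()`: for each read depth,
unlinked F2 loci are simulated by drawing each bulk's allele frequency from
its 2 x 30 gametes and then binomial read sampling, and the two-sided 95%
quantile of |Delta| is taken. This simulation-based envelope is the standard
QTL-seq procedure; the original study names neither its mapping statistic
nor thresholds, so we adopt this as the field's default and state it
prominently as an interpretation. `windowDelta()` smooths per-SNP values
over 1 Mb windows stepped by 0.25 Mb — chosen so a region of the size seen
in practice (~16 Mb) spans >= 60 windows — and `callCandidateRegion()`
reports maximal runs of windows exceeding the envelope, bridging single
dropped windows and coalescing bp-overlapping runs, each with its peak.
Because only containment was checkable against the published interval, the
recovery tests assert that the called region contains the causal position,
not its exact ends.

## The six-criterion filter cascade

`filterCascade()` applies, as an order-independent conjunction with a
per-SNP audit trail:

| # | Criterion | Rule (defaults) | Boundary convention |
|---|-----------|-----------------|---------------------|
| 1 | Missing rate | exclude if > 20% | exactly 20% kept ("exceeding" is strict) |
| 2 | MAF | exclude if < 0.05 | exactly 0.05 kept |
| 3 | Spacing | exclude if another SNP within 50 bp | 51 bp kept |
| 4 | PIC | exclude if < 0.2 | exactly 0.2 kept |
| 5 | Flank GC | keep if within 40-60% over 150 bp per side | inclusive |
| 6 | Even distribution | one SNP per equal bin, nearest midpoint | tie: lower coordinate |

MAF and PIC are computed from read depths pooled across the four bulk
samples (the source protocol does not say whether individuals or bulks were
used; bulks are what the data contain). PIC uses the classical Botstein
formula `1 - sum(p_i^2) - sum_{i<j} 2 p_i^2 p_j^2`; for biallelic loci
PIC >= 0.2 implies MAF >= 0.12946, so criterion 4 strictly dominates
criterion 2 at the defaults — both are still applied, and the audit trail
records the first failing criterion per SNP. The spacing filter compares
against the *full* candidate set rather than cascade survivors: a
neighbouring variant disturbs primer annealing whether or not it survives
the other filters. GC is measured over the 150 bp immediately each side of
the SNP, excluding the variant base itself. `selectEven()` splits the target
interval into `targetCount = 34` equal bins and takes the passing SNP
nearest each bin midpoint.

## KASP construction and cluster calling

`designKasp()` emits two allele-specific forward primers ending 3' at the
SNP base. Primer length is fixed once on the shared upstream context —
extended 5' until the estimated Tm reaches 57 °C or 30 nt — so the two
allele primers are colinear and differ only at the terminal base. The
standard LGC reporter tails (FAM `GAAGGTGACCAAGTTCATGCT` on the ref-allele
primer, HEX `GAAGGTCGGAGTCAACGGATT` on the alt) are prepended; these are an
industry convention, not data from any particular study. The common reverse
primer is the 18-25-mer on the opposite strand whose 5' end lies 50-150 bp
downstream (bounding the amplicon to 50-150 bp) with Tm nearest the target.
Tm is estimated by the Wallace rule below 14 nt and
`64.9 + 41 (nGC - 16.4)/len` otherwise — adequate for these length/GC
constraints; thermodynamic nearest-neighbour models, secondary-structure and
off-target screening are out of scope.

`classifyKaspSignals()` interprets endpoint fluorescence: points within a
noise radius of the no-template-control centroid are no-calls; the rest are
assigned to the nearest of the three canonical directions (FAM axis, HEX
axis, diagonal) after per-axis normalisation against the control centroid.

## What the simulations do and do not show

The generator reproduces the *statistical* structure the analysis assumes:
Poisson window depths with a realistic background, Mendelian segregation
with distance-dependent linkage, binomial read sampling, and flank
composition. It deliberately omits read-level artefacts — mapping-quality
structure, homoeologous mismapping hot-spots, indel-induced depth dips,
reference errors, multi-allelic sites and sequencing-error miscalls. Passing
recovery tests therefore demonstrates that the *algorithms* recover truth
under their stated model at the study's scale (35x depth, 100 kb windows,
30+30 bulks, 2,000 F2), not that any particular real dataset is free of
those artefacts. Default chromosome lengths (recipient 780 Mb, donor
650 Mb, one 300 Mb control) are placeholders of realistic wheat magnitude;
the true reference lengths are not part of the model.

## Problem sizes and reproducibility

All generators and the null envelope take explicit integer seeds and are
byte-reproducible under them; `simulateInputs()` records seed, parameters
and file checksums in a manifest. The test suite runs the breakpoint
recovery at 100 seeded replicates of ~17,000 windows, the BSA recovery at
100 replicates of 2,000 F2 individuals x 200 SNPs, the filter-cascade
oracle on 1,000 random SNPs, and the segmentation oracle on 10,000 random
window-state strings — sizes at which the binomial/Poisson expectations
above are sharp while a full run stays comfortable on a laptop.

## Known limitations

* Present/absent are the only copy states; heterozygous dosage (e.g. a
  segment present on one homologue) is not modelled.
* The depth caller assumes the translocation is terminal; interstitial
  events would appear as internal segments and are reported in the segment
  track but not named.
* The envelope treats SNPs as independent; linkage between nearby SNPs
  makes the windowed track smoother than the per-SNP envelope assumes, which
  is conservative for containment but not for region width.
* Primer design checks composition constraints only; it does not validate
  assays thermodynamically.
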