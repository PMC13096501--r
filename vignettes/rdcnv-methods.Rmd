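---
title: "Detecting replication-stress CNVs at recurrent DNA-break clusters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting replication-stress CNVs at recurrent DNA-break clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdcnv)
```

## The problem

Mild replication stress (classically, low-dose aphidicolin) produces
double-strand breaks at recurrent DNA-break clusters (RDCs) — intervals
inside long, actively transcribed, mostly late-replicating genes. Some of
these breaks are resolved into copy-number variants: shallow, subclonal
losses visible as coverage erosion in bulk sequencing, and focal or
multi-megabase haplotype losses visible in single cells. `rdcnv` implements
the four quantitative analyses this picture rests on, plus generators that
simulate each analysis's inputs with known ground truth:

1. **Coverage erosion** — per-RDC mean log2 read-depth ratio of treated vs
   control, scored against a length-preserving shuffled-region null
   (`compute_log2_ratio()`, `shuffle_regions()`, `erosion_table()`), with a
   hypergeometric test for CNV-in-RDC enrichment and a chi-square test for
   association with lamina-associated domains (LADs).
2. **Strand-seq CNV calling** — gene-level and genome-wide copy number from
   per-cell Watson/Crick template-strand counts, compared across conditions
   by a Welch-t label-permutation test (`gene_cn_profile()`,
   `genome_cn_profile()`, `welch_label_permutation()`).
3. **Breakpoint enrichment** — a clustered per-cell, per-chromosome
   permutation test asking whether single-cell breakpoints fall in RDCs
   (and their timing-transition subset) more often than chance
   (`clustered_permutation_test()`, `ttr_subset_test()`).
4. **Translocation-junction metrics** — DSB density, microhomology and
   bait-length statistics from LAM-HTGTS junction tables (`jptm()`,
   `microhomology()`, `bait_length()`, `mh_spectrum()`), with binwise and
   paired tests.

All coordinates are 0-based half-open (the BED convention); 1-based sources
are converted at the reader boundary. Intervals, count tables and junction
tables are plain tibbles, so every stage composes with dplyr pipelines.

## Coverage erosion against a shuffled null

For raw-count tracks $t$, $c$ on a shared bin grid, the per-bin ratio is

$$r_i = \log_2\!\frac{t_i/\bar t + \epsilon}{c_i/\bar c + \epsilon},$$

where $\bar t$, $\bar c$ are genome-wide mean per-bin depths (the scale
normalisation) and $\epsilon$ is a pseudocount on the depth-normalised
scale (default 0.5). The pseudocount bounds the ratio for near-empty bins;
it shrinks both signal and noise, so deviations in null-SD units are nearly
unaffected. A region's score is the **unweighted** mean of all bins its span
intersects — a partially overlapped bin counts fully, matching a
per-overlapping-bin average rather than a base-pair-weighted one.

The null repositions each region `n_sets` times (default 10): chromosome
drawn with probability proportional to length, start uniform, rejection
against an exclusion set (typically the regions themselves, plus any
blacklist). The null is summarised by the *pooled* mean and SD of all
shuffled per-region means — a single band, not a per-rank envelope — and
each region's deviation is $(\bar r - \mu_0)/\sigma_0$, flagged at
$\le -3$.

One consequence worth knowing: with heterogeneous region lengths, the
pooled $\sigma_0$ is a mixture, so the shortest regions (whose own
per-region variance is largest) have a tail probability at $-3$ SD somewhat
above the nominal $1.35\times10^{-3}$. Single false flags just past the
threshold are therefore expected occasionally even on a null genome; the
planted-deletion signal (clone fraction 0.8 gives an expected bin value of
$\log_2 0.6 \approx -0.74$, ten-plus null SDs at 30-read bins) is never in
that regime.

Gene-level enrichment is the upper-tail hypergeometric probability
(`hypergeom_rdc_enrichment()`); the LAD association is a Pearson chi-square
on a 2×2 table **without** Yates continuity correction
(`lad_association_test()`) — on the published table the corrected variant
gives a three-fold larger p, so the uncorrected form is pinned.

## Strand-seq copy-number calling

Strand-seq reads only template strands, so a chromosome's inheritance state
per cell is WW, CC or WC (expected 1/4 : 1/4 : 1/2). Only WC ("mixed")
segments are informative for CN calling: there each homolog reports on its
own strand, and strand-specific coverage acts as an internal reference.

Per 200-kb bin the state is `NO_SIGNAL` below `min_reads` (default 10)
total reads, `MIXED` when the minor strand holds at least `minor_frac`
(default 0.1) of reads, else Watson- or Crick-only. Segmentation collapses
runs shorter than `min_run` (default 5) bins into their neighbours, and then
applies a coverage criterion to distinguish the two events that produce
single-strand runs inside a WC chromosome:

* a **sister-chromatid exchange** switches one homolog's template —
  total coverage is conserved;
* a **haplotype deletion** silences one homolog — total coverage drops to
  about half.

A single-strand run flanked by mixed segments whose mean total coverage is
below `dropout_ratio` (default 0.75) of its mixed neighbours is therefore
folded back into the mixed segment, where the CN caller sees it as a
copy-number-1 region. Without this rule, any deletion longer than
`min_run` bins would masquerade as an inheritance block and be silently
excluded.

Gene CN pools Watson and Crick counts over QC-passing mixed-segment bins
overlapping the gene: CN 2 if both pooled strands pass the presence test,
CN 1 if exactly one does, missing if no eligible bins (cells without
informative bins are excluded per gene, not errored). The genome-wide mean
CN applies the same presence test per bin and averages; cells with mean
below 1.92 are flagged as carrying substantial loss.

Conditions are compared per gene by a Welch-t label permutation: observed
unequal-variance t, labels shuffled with group sizes preserved, one-sided
p with the add-one convention $p = (1 + \#\{t^\ast \le t\})/(1 + N)$, so
the floor at $N = 10^4$ permutations is $9.999\times10^{-5} \approx 10^{-4}$
and ties count as extreme. Two design limits are worth stating plainly:
calls are binary (1 or 2), and a gene is informative only in the roughly
half of cells where its chromosome is WC — so the smallest attainable
permutation p with $k$ CN-1 cells among $m$ callable of $n$ total values is
about $\binom{m}{k}/\binom{n}{k}$. Deletions present in only a few cells
of a cohort cannot reach $\alpha = 0.05$ regardless of permutation count;
the power-style tests in this package therefore plant hotspots at
frequencies (18–26 of 40 cells) where that bound is far below $\alpha$,
while call *accuracy* is checked at lower, hotspot-like frequencies
(14/7/4 of 40) where power is not the question.

## Clustered breakpoint permutation

Each breakpoint expands into a symmetric window (default half-width 1 Mb,
i.e. 2-Mb windows, reflecting single-cell mapping resolution), clipped at
chromosome ends. The statistic is the number of windows intersecting at
least one region — binary per window, so a window crossing several RDCs
counts once. The null redraws every breakpoint uniformly on its own
chromosome, keeping cell and chromosome assignments fixed (the clustered
structure controls for non-uniform per-cell variant loads); uniform redraw
is the minimal law consistent with within-chromosome shuffling. One-sided
p uses the add-one convention; the z-score standardises the observed count
against the permutation null. The timing-transition subset test first
restricts to breakpoints whose windows hit any RDC, then permutes only
those against the TTR-class subset.

Because hit counts are discrete and ties count as extreme, the test is
slightly conservative; its type-I error at $\alpha = 0.05$ sits a little
below nominal, which the calibration test brackets.

## Junction metrics

With 1-based inclusive read-internal coordinates, microhomology is
$\mathrm{MH} = -(Q_\mathrm{start} - B_{Q\mathrm{end}} - 1)$: 0 is a direct
join, positive is microhomology, negative is inserted nucleotides. Spectra
are per-library relative frequencies over MH 0–10 bp (insertions excluded
from the denominator by default; a flag pools them into a sentinel bin for
sensitivity analysis), summarised as mean ± SEM across libraries.

Bait length is the distance from the nested primer start to the recovered
bait end, orientation-aware:
$B_{R\mathrm{end}} - \mathrm{PrimStartCo} + 1$ on plus baits,
$\mathrm{PrimStartCo} - B_{R\mathrm{start}} + 1$ on minus. DSB density is
junctions per thousand (of the library's non-bait-chromosome total) per
megabase of region (JPTM). Conditions are compared per bin by two-sided
Welch t-tests with Benjamini–Hochberg correction across bins, and per
region by a paired two-sided t-test.

## What the generators emulate — and what they do not

The simulated genome defaults to 5 chromosomes × 60 Mb carrying 40
non-overlapping RDCs of 200–550 kb (≈5% of the genome, the territory used
by the breakpoint power analyses), labelled TTR with probability 0.6
(roughly the timing-transition share among classified RDCs). These reduced
scales keep the full test suite and the acceptance script within minutes on
one CPU while preserving each analysis's statistical structure; the tests
state their own problem sizes (50 erosion replicates, 500/200 calibration
replicates, 10⁵ junctions, 20 cohort replicates).

* **Coverage pairs**: independent Poisson bins; a deletion at clone
  fraction $f$ scales treated means by $1 - f\,o/2$ with $o$ the bin's
  overlap fraction. No GC/mappability waves, no overdispersion, no
  correlated replicates — so the shuffled-null SD on synthetic data is
  purely sampling noise, smaller than on real genomes.
* **Strand-seq cohorts**: per-chromosome template draws, Poisson SCE counts
  at uniform positions switching one homolog downstream, Poisson strand
  counts (default 40 reads per 200-kb bin, a medium-depth library; a
  default at or below `min_reads` would make half the bins read as
  no-signal), haplotype deletions zeroing one homolog. No variable library
  quality (the `qc_pass` flag is consumed, not modelled), no background
  strand contamination.
* **Breakpoints**: planted in-RDC with a set probability, otherwise
  uniform outside; no clustering of breakpoints *within* a cell beyond the
  cell label itself.
* **Junctions**: prey positions genome-wide with RDC territory upweighted;
  MH drawn from a configurable spectrum and encoded exactly in read
  coordinates; bait ends normally distributed with an optional mean
  shortening. No sequence-level realism.

Passing tests on these inputs show the estimators and tests recover planted
truth under their stated noise model; they do not certify behaviour under
real-data artefacts (mappability structure, library-quality gradients,
reference errors), which is what the `exclude` list, the `qc_pass` flag and
the tunable thresholds are for.

## Numerical and design choices

* Missing bins are an explicit `NA`, never zero; a region covered only by
  missing bins scores missing.
* Permutation p-values use the add-one convention everywhere, so reported
  values never reach 0 and identical seeds reproduce identical p-values
  (every stochastic function takes an explicit `seed`).
* Zero-variance degenerate cases are conventions, not errors: all-tied
  permutations give p = 1; all-zero paired differences give p = 1 with a
  warning; a saturated permutation null reports an undefined z-score with
  a warning but a valid p.
* `shuffle_regions` rejects placements overlapping the exclusion set in
  bounded batch rounds and errors if the exclusion set is too dense, rather
  than silently relaxing the constraint.
* The hypergeometric test is upper-tail by definition; when draws equal
  observed successes the tail equals the point mass, but the convention
  matters for general inputs.

## Known limitations

* The pooled single null band slightly over-flags the shortest regions (see
  above); a per-length or per-rank envelope would calibrate exactly but is
  deliberately not implemented, to keep the scoring identical to the
  single-band method it mirrors.
* Strand-logic CN calling is blind to deletions on WW/CC-inherited
  chromosomes and to events smaller than a bin; binary calls cap the power
  of the per-gene permutation test at low per-cohort frequencies.
* The clustered permutation's uniform redraw ignores any within-cell
  spacing structure of real breakpoints; a block-preserving shuffle would
  be stricter but needs an explicit model of that structure.
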