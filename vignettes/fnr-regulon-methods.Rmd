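---
title: "Methods: dissecting a bacterial TF regulon from ChIP and expression data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dissecting a bacterial TF regulon from ChIP and expression data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fnrregulon)
```

## The problem

FNR is the oxygen-sensing global regulator of *Escherichia coli*: under
anaerobiosis it acquires a [4Fe-4S] cluster, dimerizes, and binds
TTGATnnnnATCAA-like sites to switch the cell onto anaerobic metabolism.
Genome-wide, three observations complicate the textbook picture of a TF
finding its best-matching sites:

1. ChIP peak height does not track the quality of the motif match — most
   accessible sites are saturated for binding at the cellular dimer
   concentration (~2.5 µM), and peak-height variation mostly reflects
   cross-linking/immunoprecipitation efficiency;
2. most high-scoring predicted sites produce **no** ChIP peak ("silent"
   sites), and these are overwhelmingly co-occupied by
   nucleoid-associated proteins (NAPs: H-NS, IHF, Fis) that occlude TF
   binding — deleting *hns*/*stpA* unmasks many of them;
3. binding and regulation overlap only partially: fewer than half of the
   differentially expressed (DE) operons have an upstream peak, and most
   peaks have no expression consequence under a single growth condition.

This package implements the complete analytical machinery needed to make
and test those claims — PWM scanning with exact p-values,
precision-recall (PR) threshold selection, per-peak multi-site calling,
occupancy normalization, NAP-occlusion statistics, operon-level DE
consensus, and a seven-category regulon classifier — together with a
synthetic-data generator that reproduces the statistical structure the
analysis assumes, so every step is testable against a known ground
truth.

## Motif model and exact p-values

A PWM is built from aligned sites with a Hertz–Stormo small-sample
correction: a total pseudocount (default 1) distributed by the
background,

$$f_{b,i} = \frac{c_{b,i} + s\,p_b}{N + s}, \qquad
  w_{b,i} = \ln \frac{f_{b,i}}{p_b},$$

and a window scores $\sum_i w_{x_i,i}$. Following PatSer semantics,
significance is the natural-log tail probability of that score under an
i.i.d. background model. We compute it **exactly** by discretizing each
column's weights on a grid (default resolution 0.01 natural-log units,
configurable) and convolving position by position; windows are scored
with the same discretized weights, so the reported ln p-values are exact
for the discretized matrix rather than approximate for the continuous
one. A brute-force enumeration over all $4^w$ sequences reproduces the
dynamic-programming tail to machine precision for widths up to 6 (this
is a standing oracle test).

Both strands are scanned; because the motif is quasi-palindromic, a
window where both strands pass threshold is reported once with the
better-scoring strand, so downstream logic sees one site per locus. The
default background is the genome mononucleotide composition (uniform by
flag). The published operating threshold, ln p = −10.75, ships as
`fnr_default_ln_p()` for reproduction runs; analysis runs derive their
own threshold from a PR curve.

## Precision-recall threshold selection

Against a set of ChIP peaks, a threshold's true positives are peaks
containing at least one prediction, false positives are predictions in
no peak, and false negatives are peaks with no prediction. Precision is
defined as 0 when no predictions exist (avoiding 0/0). The operating
point maximizes F1 — the published curve marks its optimum with an
arrow but no criterion, so the harmonic mean is our explicit choice —
with ties broken toward the stricter threshold.

On synthetic data one structural fact matters: occluded (silent) planted
sites are *correct predictions without peaks*, so with 20% occlusion the
PR precision at full recall is exactly 0.8 by construction. The
parameter-recovery tests therefore measure recovery precision against
the planted truth (what fraction of selected predictions are real
planted sites), while the PR definitions themselves are pinned by worked
examples.

## Per-peak multi-site calling

Within a 200-bp window around each peak summit (summit ± 100 bp, clipped
at contig ends — the anchor is our reading of an ambiguous published
window), the top four window scores $s_1 \ge s_2 \ge s_3 \ge s_4$ are
recorded. If $s_1 - s_2$ exceeds the sample (n−1) standard deviation of
the four, the peak has one site. Otherwise a Grubbs outlier screen is
applied **once** with the fixed critical value Z = 1.04 at α = 0.15 —
taken verbatim as a constant because the printed value does not match
standard Grubbs tables for n = 4, and fidelity to the published
procedure wins over table arithmetic. If an outlier is removed, the SD
is recomputed over the remaining three and the gap re-tested; peaks
still unseparated carry two sites. Four equal scores (SD 0) fall in the
"not separated" branch: two sites, flagged as degenerate.

Site positions are reported as half-integer offsets of the site center
from the TSS (+1), mirrored on the minus strand, e.g. −41.5 for the
canonical Class II activation geometry. Tallying activated promoters in
a window around −41.5 is ambiguous at the boundary (± 4 vs ± 4.5 nt,
inclusive vs exclusive); `summarise_site_positions()` reports both
tallies and the package asserts neither against external claims.

## Occupancy normalization and comparisons

The occupancy statistic for probe tracks is the **peak average**: probes
in ~1500-bp flanks on each side of the peak (excluding probes inside any
other called peak — a choice the published text leaves open) define a
background whose median is subtracted from the region; the average of
the shifted values over the central 50% of the region (kept interval
rounded outward to probe positions) is the peak average. The procedure
is idempotent and invariant to adding a constant to the whole track.

**Titration.** Across dimer concentrations (the study series is 0.45,
0.7, 1.9, 2.5 µM), one-sided paired t-tests (pairing on probes) compare
consecutive concentrations. Saturation is decided on the top pair. A
literal "not significantly different AND relative increase < 5%" rule is
self-defeating on good data: a site with Kd far below the lowest
concentration still has a real ~1% step between 1.9 and 2.5 µM, and a
paired t detects any real step as noise shrinks, so nothing genuinely
saturating would ever qualify. We therefore test whether the step
significantly **exceeds** the 5% tolerance band (H0: mean step ≤ 0.05 ×
|lower average|) and call a region saturated when the point estimate is
inside the band and no significant excess is shown. Identical tracks are
saturated; a Kd = 0.2 µM Langmuir site (step ratio ≈ 1.02) is
saturated; a Kd = 2 µM site (ratio ≈ 1.14) is not. Note the exact
boundary: at Kd = 0.5 µM the noiseless ratio is 1.0526, just outside
the 5% band, so the saturated regime effectively ends slightly below
Kd = 0.5 at these concentrations.

**Strain comparison.** The union of peaks from two strains is classified
`wt_only` / `mut_only` (unmasked) / `shared_unchanged` /
`shared_increased`. A shared peak is increased only when the
Bonferroni-corrected one-sided paired t (family = all peaks in the run)
passes at 0.05 **and** the mutant peak average exceeds the WT average by
more than the WT peak SD.

**σ⁷⁰ differential occupancy.** Read-density tracks are shifted by the
median of positions outside all peaks; a one-sided paired t over the
100 bp around each summit, in the direction of the observed mean
difference and Bonferroni-corrected over peaks, yields `+`/`−`/`none`
at α = 0.01. Zero-variance difference vectors are called significant
iff the common difference is nonzero in the tested direction (logged as
degenerate).

A deliberately simple threshold-run peak caller (`simple_peak_caller()`)
serves the synthetic tracks; the published peak callers (CMARRT,
CisGenome, NCIS, MOSAiCS) are out of scope and their peak lists are
inputs in reproduction mode.

## Occlusion statistics

A site overlaps a NAP region on any ≥ 1 bp intersection. Silent and
peak-confirmed predictions are compared per NAP and for any NAP with a
pooled two-proportion z-test without continuity correction; because the
published direction of the test is unstated, both one- and two-sided
p-values are emitted. H-NS regions longer than 1 kb (strictly) are
"extended" — the filament proxy — and a one-sided Welch t contrasts
per-bp H-NS vs RNAP signal inside extended regions, the transcription-
silencing signature. The published proportions (111/124 silent vs 14/63
confirmed NAP-occupied) reject at p < 0.05 under this test.

## Expression rules

Microarray-style matrices are quantile-normalized (all columns forced to
the mean order-statistic vector, ties averaged; delegated to limma).
Sequencing data enter as tag densities (tags per kb of gene). A gene is
DE when both |log2 fold| ≥ 1 and p < 0.01; the default test is a
moderated t that shrinks per-gene pooled variances toward the global
mean variance with 4 prior degrees of freedom — a deliberately simple
empirical-Bayes moderation (Welch per-gene tests are available). An
operon is DE when **at least one** member gene is DE — the published
sentence "if only one gene…" is ambiguous between at-least-one and
exactly-one; contrasting usage supports the former, and the strict
reading is available by flag. Conflicting member directions resolve to
the smallest-p member with a conflict flag. The consensus set keeps
operons DE with a consistent direction in ≥ 2 of the datasets.

Quantile normalization assumes most genes are unchanged: in simulations
where a majority of genes carry the planted shift, normalization
(correctly) removes it. The synthetic benchmark therefore keeps
regulated genes a minority, as in real regulons.

## The seven-category classifier

Evidence order: (1) peak + consensus DE up → direct activation; (2)
peak + consensus DE down → direct repression; (3) peak, no DE,
co-activator annotation (NarL/NarP/CRP-like) → conditional
co-activation; (4) peak, no DE, repressor annotation (Fur-like) →
masked by another TF; (5) peak, no DE, otherwise → other mechanisms;
(6) DE, no peak → indirect, **unless** a scan of the 500 nt upstream of
the first-gene translation start at the operating threshold finds a
site, in which case the operon is flagged a direct candidate instead
(the *hmp* case: 70 peakless DE operons minus 1 candidate leaves 69
indirect); (7) no WT peak, mutant-only peak, and an O₂-dependent
change only in the Δ*hns*/Δ*stpA* background. Everything else is
unclassified; each operon receives exactly one label per run.

Annotations are data (operon, tag, role), never code. Where an operon
carries both repressor and co-activator tags the repressor wins by a
configurable precedence — the *feoA* convention, which appears in both
the nitrate co-activation and the Fur tables but is counted with the
Fur group. The 500-nt association window is measured from any base of
the peak region to the translation start (the published text does not
say whether the summit or the edge anchors the distance; we chose the
region edge), and one peak between divergent operons serves both.

## The synthetic generator

The generator emulates exactly the structure the analysis assumes:

- i.i.d. background genome at a stated GC fraction (default 0.5,
  500 kb for benchmarks);
- 60 planted sites sampled from the PWM within 1.5 natural-log units of
  the maximum score, ≥ 2 kb apart, on random strands;
- a single-site Langmuir occupancy law θ([TF], Kd) = [TF]/([TF]+Kd)
  with dimer concentration as the input variable — the published data
  show saturation but no functional form, so the simplest saturating
  law is used, without cooperativity;
- Kd = Kd_ref · exp(−β(score − score_ref)) with Kd_ref = 0.05 µM and
  β = 0.5, so every planted site is ≥ 95% occupied at 2.5 µM, matching
  the observed saturation at the cellular dimer level; the map is a
  test harness, not a biological claim (the data argue occupancy is
  saturated regardless of score);
- lognormal capture efficiency (default SD 0.5; SD 1.0 reproduces the
  "peak height does not track motif score" regime, |r| < 0.3);
- binary occlusion: a site inside an occluding NAP region contributes
  nothing (a fractional knob exists but defaults off — the published
  evidence is presence/absence of peaks); 20% of sites are occluded,
  each covered by an H-NS/IHF/Fis region (0.5/0.25/0.25), with region
  lengths mixing the short (≤ 1 kb) and extended (> 1 kb) classes;
- signal = baseline + Σ E_i · triangular kernel (half-width 200 bp) +
  Gaussian noise; read-density tracks are per-bp, probe tracks sampled
  every ~12 bp like the tiled arrays;
- expression: Gaussian log2 intensities (array-like) or
  negative-binomial counts (seq-like), replicated, with operon-shared
  fold-4 effects in the WT−O₂ vs Δfnr contrast.

Not emulated: read sampling and mapping artifacts, fragment-length
effects, GC bias, circular-chromosome wrap-around, probe-specific
effects, and co-operative or partial occlusion. Passing tests on this
generator therefore demonstrate procedure correctness and statistical
calibration, not robustness to the full messiness of real ChIP data.

## Problem sizes and numerical choices

The test suite and the acceptance script run desk-scale versions of the
analyses: 500-kb genomes with 60 planted sites for the benchmark (the
pipeline driver defaults to 100 kb/20 sites), 20 seeds for the
occlusion z-test calibration, 50 operons × 3 replicates × 3 datasets
for the consensus recovery, and 70 upstream sequences for the
indirect-regulon screen. Score grids use a 0.01 natural-log resolution;
a hard cap on grid size rejects pathological resolutions with a
suggested alternative. All generators take explicit seeds and are
bit-reproducible; the pipeline driver derives per-stage seeds from the
run seed so stages can be re-run in isolation. Degenerate cases are
decided, not left to chance: zero-SD top-four scores → two sites
(flagged); zero-variance paired differences → significant iff nonzero
in the tested direction; empty prediction sets → precision 0.

## Known limitations

The classifier's Categories 3–5 are only as good as the curated
annotation table, exactly as in the original analysis. The upstream
screen inherits the scan threshold's false-positive rate — at very
permissive thresholds a random 500-nt window can contain a spurious
match. The moderated t is a fixed-prior stand-in, not the full
empirical-Bayes machinery, and the seq-like DE path substitutes the
same fold + p rule for a count-model test; externally computed DE
tables can be supplied to bypass both. Real chromosomes are circular;
peaks spanning the origin are treated linearly.
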