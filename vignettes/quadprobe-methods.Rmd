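---
title: "quadprobe: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{quadprobe: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

quadprobe re-implements, as a tested and reusable pipeline, the
computational layer of a G4-probe ChIP study: genome-wide identification of
putative G-quadruplex sequences (PQS) of four structural classes plus
hybrid-G4 motifs, signal profiling of probe enrichment around TSSs and
motifs, peak-motif overlap and stratification statistics, and the
quantitative binding formulas (two-population EMSA isotherm, double-delta-Ct
qPCR).  This vignette records the models, the tunable parameters, and the
choices we made where the design was genuinely open.

All coordinates in the package are 0-based half-open (BED convention); a
dedicated test feeds 1-based-looking input and asserts that it is not
silently shifted.

## The motif classes and the scanner

A canonical PQS ("4G") follows the consensus G≥3(N1–7G≥3)≥3: four or more
tracts of at least three guanines separated by loops of one to seven
nucleotides.  `find_4g()` is a bespoke backtracking matcher that reproduces,
character for character, what a Perl-compatible regex engine does with the
pattern `G{3,}(.{1,7}?G{3,}){3,}`: G-runs are matched greedily, loops
lazily, matches are leftmost and non-overlapping, and scanning resumes at
the base after each match.  The backtracking matters: a run of fifteen
guanines is a valid motif (three-G tracts joined by single-G loops), and
only an engine-faithful matcher finds the same spans a regex would.  The
test suite holds the matcher against base R's PCRE engine (`gregexpr`) on
tens of thousands of random sequences.

Three non-canonical classes are defined by predicates on a four-tract
parse:

* **4GL15** – four intact tracts, exactly one loop of 8–15 nt, the rest
  1–7 nt;
* **GVBQ** (G-vacancy) – exactly one tract of exactly two guanines at the
  first or last position, three intact tracts, loops 1–7 nt;
* **Bulge** – exactly one tract of three guanines interrupted by a single
  non-G base (`G·B·GG` or `GG·B·G`, B ∈ {A,C,T}), three intact tracts,
  loops 1–7 nt.

The search runs in two rounds, as the original method describes: a first
round enumerates every span admitting a valid parse (a dynamic program over
tract/loop structure), then filtering rounds discard any candidate
overlapping a canonical 4G span by one or more nucleotides — the published
flow chart for this step is not reproduced legibly anywhere we could
consult, so overlap-with-canonical is our declared reconstruction; the
threshold is configurable (`overlap_nt`).  Survivors are reported left to
right, non-overlapping within a subtype, the shortest candidate winning at
a shared start (mirroring the lazy loops of the canonical pattern).

Open points we had to decide:

* whether a G-vacancy may sit in an interior tract: we restrict it to the
  terminal quartet positions, the defining case of the vacancy literature;
* whether loops may contain N: the printed `.` would match N, but reporting
  motifs over unknown bases is indefensible, so N truncates candidates
  everywhere (tract, loop, bulge);
* hybrid motifs ("Hybrid2"/"Hybrid3") are maximal groups of two or three
  intact tracts with loops 1–7 nt that do not overlap any four-tract motif
  span; a three-tract group is one Hybrid3, never two Hybrid2s.

The brute-force oracle used in the tests enumerates all substrings and
tests them with anchored alternation regexes — a mechanically independent
route that must agree with the scanner exactly, on every class.

Minus-strand motifs are found by scanning the reverse complement and
mirroring coordinates (`start' = L − end`); `tracts`/`loops`/`bulge_offset`
always describe the motif 5'→3' on its own strand.  Overlapping calls of
different subtypes can be merged with `merge_subtype_calls()` to tabulate
Venn-style subtype combinations.

## Genome partition and region statistics

`partition_regions()` divides every chromosome into promoter (TSS ± flank,
default 2000 bp), TES flank, intragenic and intergenic, with precedence
promoter > TES flank > intragenic where windows collide.  The source
figures report four mutually exclusive percentages without stating a
precedence; promoter priority matches their framing of promoters as the hot
sites of G4 formation, and the choice is configurable by reordering the set
operations.  Windows are anchored on the TSS/TES interval coordinate (the
start of a plus-strand gene, the end of a minus-strand gene, and vice
versa), so a plus gene [4000, 7000) with flank 2000 yields promoter
[2000, 6000) and TES window [5000, 9000).  The partition is exact: property
tests assert every base carries exactly one label and fractions sum to 1
for random gene sets.

Peaks are assigned to regions by midpoint (each peak counts once; fractions
sum to 1); read-style accounting can use `any_overlap`.  Motif-to-window
overlap (`pqs_load()`, TSS ± 3 kb by default) counts one-nucleotide
overlaps, and the per-subtype columns support the "TSSs carrying only one
subtype" stratification.

## Signal profiling

`CoverageTrack`s hold base-resolution signal per chromosome.  RPKM
normalisation converts summed base coverage to read equivalents (sum /
read length) per bin and divides by bin kilobases × million mapped reads.
Track comparison is per-base subtraction or ratio with a pseudocount
(default 1.0; the source states none).

Reference-point matrices average the track per bin over
[anchor − half_width, anchor + half_width); rows of minus-strand anchors
are column-reversed so downstream is always rightward.  Bases outside the
chromosome contribute zero — the alternative (masking) changes profile
tails, and zero-fill is what the field's matrix tools do by default.  Bin
values are means (sum / bin size) computed with the same accumulation order
as the per-base oracle in the tests, so agreement is exact, not
approximate.  Bin size defaults to 50 bp and half-widths to 1.5–3 kb
depending on the figure being emulated; the source never states its bin
size.  Scaled-region matrices rescale gene bodies onto a fixed number of
bins by fractional (weighted) binning, so genes shorter than the bin count
still contribute every base and preserve their mean.

Heatmap scaling maps the global matrix minimum/maximum onto 0–255 (per
heatmap, not per row, following the figure legends); a constant matrix maps
to zero.  Row sorting (by row maximum or mean, descending) is stable and
returns the permutation so several heatmaps can share one row order.

`shuffle_intervals()` relocates each interval uniformly at random on its
own chromosome, avoiding the exclusion set (typically all PQS spans) and
previously placed intervals, preserving lengths, deterministic given a
seed.  The original tool can move intervals across chromosomes; staying on
the same chromosome keeps per-chromosome composition and simplifies the
feasibility search, and is configurable in principle by relabelling input
chromosomes.

## Binding quantitation

The EMSA model is the two-population isotherm

Y = F1 · X/(Kd1 + X) + (1 − F1) · X/(Kd2 + X)

fit by nonlinear least squares (`optim`, L-BFGS-B) over (F1, log10 Kd1,
log10 Kd2) from a grid of start points: F1 ∈ {0.25, 0.5, 0.75} and Kd
pairs drawn from the quantiles of the observed concentration range; the
best-RSS solution is kept and Kds are reported in canonical order.  The
collapse rule follows the source's figure legend: when the two Kds agree
within 0.05 log10 units, or Kd2 exceeds 1 M, the fit is degenerate and a
single-Kd one-site model is refit (1-D Brent) and reported.  Whether the
original fits constrained F1 or weighted points is not stated; we leave
points unweighted and F1 free in [0, 1].

Recovery behaviour, measured in the test suite: noiseless titrations on a
14-point log grid return all three parameters to ~10⁻⁶ relative error;
with Gaussian noise of sd 0.05 on Y a *single* titration is
information-limited (median Kd errors near 30% even when started at the
truth), so the replicate design averages 20 replicate series before
fitting — as replicate gels are treated in practice — giving median errors
of a few percent.

ΔΔCt enrichment is `efficiency^−[(Ct_chip,target − Ct_chip,ref) −
(Ct_input,target − Ct_input,ref)]` with a PQS-negative region as the
reference; efficiency defaults to 2.0 (classic double-delta-Ct) and is
configurable because no standard-curve correction is stated.  Pull-down
enrichment double-ratios target and internal-control quantities against the
input and normalises to the mutant-template condition.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes — it
is a designed fixture, not a genome model:

* **Background** is i.i.d. sequence post-processed so no G or C run reaches
  length 3.  Real genomes are not G-run-suppressed; the suppression
  guarantees planted motifs are the only PQS sources, which makes
  planted-truth tests exact.  Consequences for realism: background base
  composition is mildly distorted, and the scanner's false-positive rate on
  real sequence is *not* measured by these tests (the random-sequence
  oracle-equivalence tests cover correctness on arbitrary sequence
  instead).
* **Planted motifs** (default 120 across all six classes on a 2 × 500 kb
  genome) are built with A/T-only loops, intact tracts of exactly three
  guanines in the non-canonical classes, interior bulge positions, and
  12-bp A/T pads on both flanks.  These constraints make each planted
  sequence parse as its own subtype and no other, so the truth table is
  exact; real PQS loops are of course not A/T-only, and real motifs do
  carry multiple subtype labels (which `merge_subtype_calls()` is for).
  A post-check rescans the genome and errors on any deviation.
* **Genes** are laid out deterministically (equal slots, alternating
  strands, expression tiers cycling through 1, 2, 4 by default).
* **Placement** puts 70% of motifs near TSSs, alternating per subtype
  between the downstream and upstream side in fixed offset slots
  (300–600 bp and 1200–1400 bp) so each subtype and tier is represented
  evenly on both sides — a balanced design, chosen so the aggregate
  downstream/upstream contrast estimates the configured asymmetry factor
  rather than the accident of which subtypes landed where.  Slots and the
  6-sigma center separation also keep enrichment bumps from overlapping,
  making each planted amplitude exact at its motif center.
* **Tracks**: input = background level 1.0 + Gaussian noise (sd 0.2,
  floored at 0); the G4P track adds a Gaussian bump per motif, amplitude =
  subtype amplitude × host-gene tier × asymmetry (1.5) when downstream of
  the TSS.  Subtype amplitudes default to 4G = 4 > Bulge = 3 > 4GL15 = 2 >
  GVBQ = 1 (the enrichment order the study reports for real data; here it
  is an input, so the pipeline's recovery of the ordering checks the
  measurement, not the biology), with hybrids at 0.5.  The bump sd is
  100 bp: with 120 motifs on 1 Mb this keeps the planted enrichment
  footprint near 3% of the genome, so the shuffle null sits well below the
  planted signal; wider bumps would blur the null contrast at this fixture
  scale.  The enrichment shape itself is a choice — the source implies
  none.
* **Peaks** are emitted at planted motifs (peak calling is out of scope)
  with fold enrichment defined as the local G4P/input mean ratio over the
  motif center ± 250 bp.

Everything is deterministic given the config seed: reruns produce
byte-identical FASTA, BED, bedGraph and report files.

What passing fixture tests does and does not show: they verify the
pipeline's bookkeeping and statistics end to end (exact motif recovery,
profile orientation, tier monotonicity, downstream/upstream contrast, 100%
PQS-positive peaks, monotone stratification), under idealised signal.  They
do not validate peak calling, read-level noise models, chromatin
accessibility confounds, or scanner specificity on real genomic sequence.

## Null model and problem sizes

The shuffle null pools ten seeded shuffle replicates of the motif set (all
relocated to PQS-free positions) and compares the pooled null profile level
against the planted profile peak; with 120 anchors a single draw's level
fluctuates by tens of percent because a handful of large bumps dominate,
and pooling is the standard permutation-test remedy.  The expected ratio at
the default fixture is ~3%.

Problem sizes used by the test suite, chosen as representative desk-scale
workloads: oracle equivalence on 1000 random 300-mers across all six
classes; regex fidelity on 10 000 random 200-mers; planted recovery,
shuffle null and the end-to-end run on the default 2 × 500 kb / 120-motif
fixture; 200 random gene sets for partition completeness; 100 random
track/anchor draws for exact profile agreement; 50 parameter draws (each
with 20 noisy replicates) for the binding fit.

## Known limitations

* The non-canonical predicates are permissive about guanines inside loops
  (a vacancy tract may be the prefix of a longer run, with the loop
  absorbing the rest).  This follows from defining candidates by parse
  existence; the 4G-overlap filter removes the cases that would relabel
  canonical motifs.
* Genome-scale headline numbers of the original study (hundreds of
  thousands of peaks, percent promoter coverage in hg19) require the
  deposited sequencing data, the human genome and an external peak caller,
  and are out of scope by design.
* bigWig/bigBed are not read or written; bedGraph and BED are the
  interchange formats.
* The EMSA fit reports no confidence intervals; the recovery suite
  characterises typical errors instead.
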