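# quadprobe

Genome-wide G-quadruplex (G4) motif scanning and G4 ChIP-seq signal
analysis, with a deterministic synthetic-data generator so every stage is
testable without external data.

G-quadruplexes are four-stranded structures formed by guanine-rich DNA.
Affinity probes (small G4-binding proteins, G4 antibodies) are used to pull
down G4-containing chromatin and sequence it; interpreting such experiments
requires (i) knowing where the genome *could* form G4s — the putative
G-quadruplex sequences (PQS) — and (ii) quantifying probe enrichment around
those sites.  quadprobe is for computational biologists running or
re-analysing that kind of experiment.

## What it computes

**PQS scanning.**  Canonical motifs follow the consensus
G<sub>≥3</sub>(N<sub>1–7</sub>G<sub>≥3</sub>)<sub>≥3</sub> ("4G"), matched
with exact regex-engine semantics of the pattern `G{3,}(.{1,7}?G{3,}){3,}`
(greedy tracts, lazy loops, leftmost non-overlapping matches).  Three
non-canonical classes — one long loop of 8–15 nt (**4GL15**), a G-vacancy
leaving a two-guanine tract (**GVBQ**), and a single-nucleotide bulge in
one tract (**Bulge**) — are found by candidate enumeration followed by
removal of candidates overlapping canonical motifs.  Two/three-tract
**hybrid** motifs (potential DNA:RNA hybrid G4s) complete the six classes.
Both strands are scanned; minus-strand calls are mirrored to plus-strand
coordinates.

**Signal analysis.**  Coverage-track algebra (subtract/ratio with
pseudocount, RPKM), strand-aware reference-point and scaled-region signal
matrices, 0–255 heatmap scaling, stable row sorting with transferable
order, and seeded interval shuffling to PQS-free positions for null
controls.

**Statistics.**  Promoter / intragenic / TES-flank / intergenic genome
partition (every base labelled exactly once), per-TSS PQS load, peak–PQS
overlap fractions, fold-change stratification tables, and a deterministic
summary report.

**Binding quantitation.**  The two-population EMSA isotherm
`Y = F1·X/(Kd1+X) + (1−F1)·X/(Kd2+X)` fit by multi-start nonlinear least
squares with a degenerate-collapse rule (identical Kds, or Kd2 > 1 M,
report one Kd), and double-delta-Ct qPCR / pull-down enrichment formulas.

All coordinates are 0-based half-open (BED convention).

## Worked example

```r
library(quadprobe)

find_4g("GGGAGGGTGGGAGGG")
#>   start end subtype n_tracts  tracts loops bulge_offset
#> 1     0  15      4G        4 3,3,3,3 1,1,1           NA

s <- "TTGGTGGGAGGGTGGGTTT"
find_noncanonical(s, "GVBQ", find_4g(s))
#>   start end subtype n_tracts  tracts loops bulge_offset
#> 1     2  16    GVBQ        4 2,3,3,3 1,1,1           NA
```

The motif at [2,16) has a two-guanine vacancy tract followed by three
intact tracts — a G-vacancy PQS that the canonical consensus would miss.

The synthetic fixture plants 120 motifs of known class on a 2 × 500 kb
genome and simulates input/G4P coverage whose enrichment scales with each
host gene's expression tier:

```r
cfg <- sim_config(seed = 1)
sim <- make_genome(cfg)              # self-verifies scan == truth
motifs <- scan_genome(sim$genome)
table(motifs$subtype)
#>      4G   4GL15   Bulge    GVBQ Hybrid2 Hybrid3
#>      30      20      20      20      15      15

trk <- simulate_tracks(cfg, sim)
peak_pqs_overlap(trk$peaks, motifs)$fraction
#> [1] 1

d <- compare_tracks(trk$g4p, trk$input, "subtract")
g <- sim$genes
sm <- reference_point_matrix(d, data.frame(chrom = g$chrom, pos = g$tss,
                                           strand = g$strand), 2000L, 50L)
for (t in c(1, 2, 4))
  cat(sprintf("tier %d peak height: %.2f\n",
              t, max(colMeans(sm$values[g$tier == t, , drop = FALSE]))))
#> tier 1 peak height: 2.06
#> tier 2 peak height: 4.82
#> tier 4 peak height: 7.62
```

Every emitted peak covers a detected PQS (fraction 1), and TSS-anchored
enrichment rises monotonically with the expression tier, as designed.  A
noiseless titration returns its generating constants:

```r
x <- 10^seq(-10.5, -5.5, length.out = 14)
fit_two_site(x, predict_bound(x, 2e-9, 1.5e-7, 0.55))
#> binding_fit: Kd1 = 2e-09 M (F1 = 0.55), Kd2 = 1.5e-07 M, RSS = 4.65e-18
```

A thin command-line wrapper with `scan`, `simulate`, `fit-emsa` and
`profile` subcommands lives in `inst/cli/quadprobe.R`.

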