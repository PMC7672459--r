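Package: quadprobe
Title: Genome-Wide G-Quadruplex Motif Scanning and G4 ChIP Signal Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies canonical and non-canonical putative G-quadruplex
    sequences (PQS) on both strands of a genome, including motifs with one
    long loop (4GL15), a G-vacancy (GVBQ), a single-nucleotide bulge, and
    two/three-tract hybrid-G4 motifs. Computes ChIP-style coverage-track
    algebra (subtract/ratio, RPKM), reference-point and scaled-region signal
    matrices around TSSs and motifs, shuffle null controls, peak-PQS overlap
    and fold-change stratification statistics, a two-population EMSA binding
    isotherm fit, and delta-delta-Ct qPCR enrichment. Ships a deterministic
    synthetic-data generator that plants motifs of known subtype near
    synthetic TSSs so every analysis stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
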