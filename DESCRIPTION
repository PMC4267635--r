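Package: cclampscan
Title: Degenerate Motif Occupancy and Co-Occurrence Analysis for
    Two-Domain Transcription Factors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for studying how a secondary DNA-binding
    domain reshapes genome-wide transcription-factor occupancy, modelled
    on LEF/TCF factors that pair an HMG box (recognizing the Wnt Response
    Element, WRE) with a C-clamp (recognizing GC-rich Helper sites).
    Provides IUPAC degenerate-motif and weight-matrix scanning of peak
    sequences, a per-peak binomial background model with exact
    Poisson-binomial tail probabilities for WRE/Helper co-occurrence,
    comparative occupancy statistics between wild-type and
    binding-mutant peak sets (matched-region strength, motif copy-number
    stratification, spacing and orientation), peak-to-feature annotation,
    integration of peak occupancy with nascent-transcription changes
    (gene linking, hypergeometric overlaps, rank enrichment), and a
    seeded synthetic-data generator with a ground-truth manifest for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
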