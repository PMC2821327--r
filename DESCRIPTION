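Package: backtralign
Title: Frameshift-Aware Alignment of Protein Back-Translation Graphs
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects distant protein homologies across frameshift mutations by
    aligning the complete sets of putative coding DNA sequences of two proteins.
    Each protein is represented as a back-translation graph, a layered DAG whose
    paths are exactly the DNA sequences encoding it, optionally condensed with
    IUPAC ambiguity codes. Graphs are aligned by a Smith-Waterman-style dynamic
    programming algorithm with a non-monotonic gap model (rare, penalized
    frameshift gaps of size 1-2 and cheaper whole-codon skips), under a
    translation-dependent log-odds scoring system built from codon substitution
    models (mechanistic Goldman-Yang-type or empirical). Includes a reduced-memory
    cut-point alignment variant, Gumbel (Karlin-Altschul) significance calibration
    by simulation with per-reading-frame-difference E-values, and a codon-level
    divergence simulator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    Matrix,
    Rcpp,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Alignment, Genetics, SequenceMatching, Software
RoxygenNote: 7.3.3
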