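Package: captor
Title: Control Library Adaptors for Benchmarking and Correcting Nanopore Sequencing
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design, simulation and analysis toolkit for control library
    adaptors (CAPTORs): synthetic 90-nt adaptors whose variable regions tile a
    k-mer-complete source sequence and double as internal sequencing controls.
    Provides a de Bruijn based panel designer with homology and hairpin
    screens, staggered two-fold dilution master-mix manifests, a FASTQ read
    simulator with a context-dependent systematic error model and per-channel
    metadata, semi-global read classification and per-nucleotide event
    profiling, per-6-mer error tables, per-pore and per-time summaries,
    quantitative reference ladders with a segmental-regression limit of
    quantification, TMM and control-anchored RUVg normalisation with
    fold-change evaluation, and per-nucleotide subtraction error-correction
    for gene-specific control adaptors.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    edgeR,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
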