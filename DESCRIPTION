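Package: motifenv
Title: Sequence and Shape Environment of Transcription Factor Binding Motifs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of the sequence and DNA-shape environment surrounding
    transcription-factor core binding motifs. Aligns bound and unbound
    sequence pools on their best motif hit (position frequency matrix
    scanning with exact p-values), compares per-position nucleotide content
    and propeller twist between pools with one-sided rank tests and FDR
    q-values, scores homotypic clusters and the homotypic environment,
    measures TF-pair co-occupancy, and discriminates bound from unbound
    sequences with L2-regularized regression over environment features and
    with a two-state block hidden Markov model log-likelihood-ratio scorer.
    Ships a synthetic-data generator that plants recoverable effects for
    calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
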