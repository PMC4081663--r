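Package: snmm
Title: Single-Nucleotide Mutation Matrix Scoring of NF-kB p50 Binding Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores 10-bp DNA sequences for NF-kB p50 binding affinity with a
    single-nucleotide mutation matrix (SNMM) built from dsDNA-microarray
    measurements of a wild-type site and its 30 single-base mutants, alongside
    position-weight-matrix comparators (log-odds PWMSA and the Match matrix
    similarity score). Includes Pearson-correlation evaluation of model scores
    against EMSA, protein-binding-microarray and SELEX-Seq affinity data,
    grid-search optimisation of the decision threshold from false-negative and
    false-positive rates, motif scanning of longer sequences on both strands,
    a microarray intensity simulator for parameter-recovery studies, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
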