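Package: corepan
Title: Completeness-Aware Bayesian Core/Accessory Pan-Genome Partitioning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Classifies gene clusters (or any discrete genome-encoded trait)
    of a genome set as core or accessory from presence/absence patterns and
    per-genome completeness priors, using an iterative Bayesian
    log-likelihood-ratio classifier that is robust to highly incomplete
    metagenome-assembled and single-cell genomes. Includes a bootstrap
    procedure estimating the false discovery rate and sensitivity of a
    partition, readers for Roary, mmseqs2-style cluster tables and CheckM
    quality tables, species-level genome clustering from pairwise average
    nucleotide identity, and a ground-truth synthetic pan-genome generator
    with benchmarking harnesses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
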