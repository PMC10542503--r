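Package: orthoDE
Title: Ortholog-Aware Comparative Transcriptomics for Hybrid Speciation Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative RNA-seq analysis across closely related
    species without a reference genome, motivated by homoploid hybrid
    speciation in Argyranthemum. Implements trimmed-mean-of-M-values (TMM)
    normalization, common-dispersion negative-binomial exact tests for
    pairwise differential expression at a false-discovery-rate cutoff, a
    reciprocal-best-blast-hit (RBBH) diagnostic for ortholog co-assembly
    failure (chi-squared and phi association of DE status, and the
    reciprocal-versus-same-direction partition with its 2q(1-q)
    expectation), orthogroup utilities including one-to-one ortholog
    extraction and removal of paralog-contaminated orthogroups by genus
    non-monophyly on neighbor-joining gene trees, and a six-comparison
    truth-table classifier of expression phenotypes (parental-divergent,
    parent-like, and novel/transgressive) for two parental and two hybrid
    taxa. A negative-binomial synthetic-data generator with known ground
    truth (including split-ortholog and DE-paralog artifacts) makes every
    stage testable without the original sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    edgeR,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
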