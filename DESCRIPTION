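Package: mthet
Title: Heteroplasmy Detection in Deep-Sequenced Mitochondrial Genomes
Version: 1.0.0
Authors@R:
    person("M.", "Verity", email = "m.verity@example.org",
           role = c("aut", "cre"))
Description: Detects low-frequency mitochondrial heteroplasmy from
    deep-sequencing pileups of small circular genomes, including the
    fragmented minichromosome genomes of human lice and the single-chromosome
    mitochondrial genomes of ticks. Candidate minor alleles above a frequency
    threshold are screened with a binomial sequencing-error false-positive
    probability and Storey-Tibshirani q-values, sequencing-error hotspots
    (homopolymer-adjacent and adjacent-variant sites) are excluded, passing
    sites are classified as synonymous or nonsynonymous under the
    invertebrate mitochondrial genetic code with amino-acid property changes,
    and cohort-level per-gene and per-group summaries with t-tests are
    produced. A seeded synthetic-data generator emits references,
    annotations, pileups and reads with planted heteroplasmy so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    Rsamtools,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
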