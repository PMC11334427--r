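Package: markerlens
Title: Fine-Grained Microbiome Diversity with Alternative Marker Genes
Version: 0.1.0
Authors@R:
    person("Markerlens", "Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for resolving fine-grained gut-microbiome diversity with
    fast-evolving single-copy marker genes (such as dnaK and gyrB) as
    alternatives to the 16S rRNA gene. Implements Kimura (1980) pairwise
    distances and cross-marker identity regression, in-silico PCR with
    degenerate (IUPAC) primers and taxonomic-coverage reporting, codon-aware
    back-translation primer design, taxon-subset Shannon diversity with a
    two-part (hurdle) GLM against a continuous host phenotype (BMI) with
    Benjamini-Hochberg FDR control, and a median-of-ratios negative-binomial
    differential-abundance test. A synthetic-data module simulates marker
    genomes under K80 and hurdle-structured cohorts so the whole pipeline is
    testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    MASS,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ape,
    vegan,
    DESeq2,
    withr
Config/testthat/edition: 3
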