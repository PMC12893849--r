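Package: alloscore
Title: Directional Allogenomic Mismatch Scoring and Candidate Minor
    Histocompatibility Antigen Peptides
Version: 1.0.0
Authors@R:
    person("Allo", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes the directional Allogenomics Mismatch Score (AMS)
    between a transplant donor and recipient from VEP-annotated exome
    VCFs, reconstructs candidate minor histocompatibility antigen
    peptides around each amino-acid mismatch, scores them against HLA
    class I alleles through a pluggable affinity/cleavage predictor
    interface, and derives the affinity-filtered af-AMS.  Ships a
    Mendelian family genotype simulator (recombination, genotyping
    error, missingness) with an independent brute-force scoring oracle
    for validating score accuracy, and a command-line entry point
    wiring the counting, affinity and simulation stages.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    optparse,
    Biostrings,
    VariantAnnotation,
    SummarizedExperiment,
    GenomeInfoDb,
    BiocGenerics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
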