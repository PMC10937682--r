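Package: neoforge
Title: Neoantigen Discovery from Somatic Variants with MHC-I and
    Expression Filtering
Version: 0.1.0
Authors@R:
    person("neoforge", "developers", email = "neoforge@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for identifying candidate MHC class I
    neoantigens in paired tumour cell lines. Somatic variants (VCF) are
    applied to coding transcript models (GTF + FASTA), mutant peptides of
    length 8-11 are enumerated (with read-through translation of
    frameshifts), strong MHC-I binders (percent rank <= 0.5) are retained,
    and candidates are validated against RNA-seq variant support and
    gene-level expression (TPM) before classification as shared or unique
    between two lines. Also provides the cohort statistics used to relate
    dendritic-cell and effector T-cell gene signatures to tumour
    mutational burden and overall survival (signature scoring, median and
    quartile stratification, Pearson correlation, Kaplan-Meier and
    Mantel-Cox log-rank), and a synthetic-data generator with recorded
    ground truth so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    GenomeInfoDb,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer,
    jsonlite,
    withr,
    stats,
    tools,
    utils
Suggests:
    optparse,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
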