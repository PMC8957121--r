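Package: gbmseesaw
Title: Gene Body Methylation, Transcription, and Class-Level Seesaw Shifts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies gene-body and promoter DNA methylation from per-CpG
    bisulfite counts (plus MBD-seq enrichment scores and mdRAD RPKM),
    quantifies expression from RNA-seq counts, computes per-gene differential
    methylation (binomial likelihood-ratio test) and differential expression
    (median-of-ratios normalization with a negative-binomial Wald test), and
    tests baseline methylation-expression relationships, the correlation of
    methylation changes with expression changes, and the three-component
    class-level "seesaw" hypothesis for the bimodal methylation classes of
    invertebrate genomes. Includes a fully parameterized synthetic-study
    generator so every stage is verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    optparse,
    jsonlite
biocViews: Epigenetics, DNAMethylation, DifferentialMethylation,
    DifferentialExpression, Sequencing, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
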