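Package: trendseq
Title: Quantifying Transcriptome 3' End Diversification from 3' End
    Sequencing Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying alternative polyadenylation (APA) from
    multiplexed 3' end sequencing screens: assembly of a poly(A)-site
    isoform annotation from poly(A)-site-supporting reads with
    internal-priming filtering, barcode demultiplexing and A/T-stretch
    trimming, intersection-strict per-isoform read counting, per-isoform
    Fisher exact tests of differential isoform usage with
    Benjamini-Hochberg correction, shortening/lengthening indices, an
    APA-regulator interaction network, and a downstream clinical
    isoform-ratio signature workflow (array-derived lengthening indices,
    ROC/AUC with DeLong and bootstrap comparison, Kaplan-Meier/log-rank,
    and bootstrapped Cox concordance). A synthetic-data generator
    produces genomes with planted poly(A) sites and A-rich decoys,
    barcoded reads, count matrices with planted usage shifts, probe-level
    expression and survival data for end-to-end validation.
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
    Biostrings,
    SummarizedExperiment,
    survival,
    limma,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    rtracklayer,
    Rsamtools,
    optparse
biocViews: Transcriptomics, AlternativePolyadenylation, Sequencing,
    DifferentialExpression, Survival
Config/testthat/edition: 3
RoxygenNote: 7.3.3
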