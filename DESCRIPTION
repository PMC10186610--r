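Package: lhasig
Title: Inference of Longevity and Healthy Aging Immune Gene Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A multi-stage pipeline for deriving a longevity-and-healthy-aging
    (LHA) immune gene signature from blood transcriptomes: per-cohort
    differential expression with covariate adjustment, cross-cohort consensus
    gene sets with a permutation overlap null, age-trajectory pattern
    clustering with a slope metric to isolate common aging genes, LHA set
    derivation by subtraction, cell-type enrichment (weighted
    Kolmogorov-Smirnov gene set enrichment and hypergeometric
    over-representation), non-negative least squares deconvolution of immune
    cell proportions against a signature matrix, weighted co-expression module
    detection with module eigengene-age correlation, two-group methylome
    delta-beta analysis with skewness and differentially methylated probe
    calling, and promoter-binding/transcription-factor overlap analyses. A
    synthetic-data module generates every input with planted ground truth so
    the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    BiocGenerics,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Matrix,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    DESeq2,
    e1071,
    mclust,
    limma,
    rtracklayer
Config/testthat/edition: 3
RoxygenNote: 7.3.3
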