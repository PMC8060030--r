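Package: wolbomics
Title: Tissue-Specific Multi-Omics Analysis of Insulin-Wolbachia
    Interactions in Drosophila
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Differential-expression and network tools for factorial
    (genotype x Wolbachia) multi-omics studies of reduced insulin/IGF
    signalling in Drosophila tissues. Implements per-tissue two-factor
    linear models with empirical-Bayes variance moderation for log2
    label-free proteomic intensities, negative-binomial GLM
    likelihood-ratio tests for gene and transposon counts with combined
    normalization, TOST equivalence classification of
    Wolbachia-dependent and -independent features, transcript-protein
    concordance quadrant analysis, bias-corrected network propagation
    with cross-model minimum consensus and Ward clustering, and Fisher
    GO enrichment with term-redundancy reduction. Includes a
    ground-truthed synthetic-data generator emulating the four-tissue
    2x2 factorial design for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    mclust
Config/testthat/edition: 3
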