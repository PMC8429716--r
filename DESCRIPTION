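Package: sigclone
Title: Joint Inference of Intra-Tumor Heterogeneity and Mutational Signature Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Jointly infers the subclonal composition of a bulk tumor sample
    (number of clones, cancer cell fractions, mutation-to-clone assignment) and
    the mutational signature activity of each clone from somatic SNV read
    counts, allele-specific clonal copy number and tumor purity. The model is a
    mixture over clones, signatures and mutation multiplicities with a
    beta-binomial read-count emission, fitted by expectation-maximization with
    an adaptive penalized-likelihood choice of the number of clones. Includes a
    likelihood-ratio test for signature activity changes between clones with
    simulation-calibrated degrees of freedom, a generative simulator, and an
    evaluation-metric suite for subclonal reconstruction and signature
    deconvolution benchmarks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    optparse,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    pROC,
    vcfR,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
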