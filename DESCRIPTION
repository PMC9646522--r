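Package: mutburden
Title: Kilobase-Scale Somatic Mutation Rate Maps and Negative Binomial
    Burden Tests for Cancer Driver Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models the neutral somatic mutation rate of a cancer cohort
    genome-wide at kilobase scale and tests arbitrary sets of genomic
    positions for a mutational burden in excess of that rate. A small
    convolutional network summarises epigenomic track profiles of 10-kb
    bins into a low-dimensional embedding and a Gaussian process head
    predicts the mean and variance of the regional mutation rate under
    leakage-free five-fold genome partitioning. A maximum-likelihood
    trinucleotide context model distributes mutations to individual
    positions, yielding a closed-form negative binomial null over any
    query set of possible substitutions. Includes exact convolution
    across regions, cohort scaling factors, enrichment with Monte Carlo
    confidence intervals, excess decomposition, a generative simulator
    and a Monte Carlo power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    data.table,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    vcfR,
    kernlab,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: SomaticMutation, StatisticalMethod, Software
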