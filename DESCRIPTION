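Package: imprintcall
Title: Allele-Specific Imprinting Analysis from Haplotype-Resolved Counts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Calls genomic imprinting from maternal/paternal read counts in
    mouse F1 and N1 crosses and tests for genotype-dependent loss of
    imprinting with two engines: a paired negative-binomial GLM
    likelihood-ratio test and a fixed-dispersion beta-binomial regression.
    Includes recursive-partitioning segmentation of binned allelic
    proportions to find informative (heterozygous) regions in backcross
    samples, allele-specific differentially-methylated-region testing and
    genome-wide methylation testing from bisulfite counts, single-embryo
    sexing and contamination QC, and a truth-tagged synthetic data
    generator so every stage can be verified without raw sequencing data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    edgeR,
    rpart,
    IRanges,
    methods,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
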