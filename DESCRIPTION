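Package: bgpwas
Title: Bayesian Genome-Phenome Wide Association for InDel Function Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reverse-regression Bayesian genome-phenome wide association
    (BGPWAS): each variant's allele dosage is regressed on a standardized
    multi-trait phenome plus leave-one-chromosome-out principal components
    under horseshoe, ridge or lasso shrinkage priors, and traits whose 95%
    posterior intervals exclude zero are called associated. Includes
    kinship-aware multi-trait mixed-model phenotype imputation (low-rank
    matrix-normal model with a Wishart residual prior), VanRaden genomic
    relationship matrices, LOCO principal components, automated InDel
    consequence calling on coding transcripts (frameshift detection, mutant
    protein translation, truncation and domain loss), and a synthetic-data
    module that simulates genotype-phenome datasets with known causal
    structure for power and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vcfR,
    Biostrings,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
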