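Package: mhc2epi
Title: HLA Class II Epitope Presentation and Immunogenicity Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-stage pipeline for HLA class II epitope prediction. The
    presentation (eluted-ligand) stage combines transformer sequence encoders
    with bilinear attention over peptide and allele pseudosequence, a
    probabilistic motif-deconvolution model (mixture of 9-mer position weight
    matrices with binding-core offset priors), a flanking-residue cleavage
    classifier and a gene-expression feature, fused with fixed contribution
    weights. A conditional domain-adversarial transfer stage adapts the
    presentation features to the immunogenicity domain. Includes
    proteome-decoy generation, PPVn evaluation, percentile-rank calibration
    and a synthetic-data generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
LinkingTo:
    Rcpp,
    RcppArmadillo
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    patchwork,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
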