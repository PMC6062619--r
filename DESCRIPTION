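Package: ancestryproj
Title: Supervised Ancestry Projection for Ancient DNA Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Supervised projection of individual genomes onto a fixed panel
    of ancestry-specific allele frequencies, tailored to ancient-DNA cohorts.
    Estimates per-individual admixture proportions by maximum likelihood
    (EM on the probability simplex, with diploid and pseudo-haploid
    likelihoods), attaches marker-resampling bootstrap standard errors,
    combines individuals into sample-level profiles by inverse-variance
    weighting with a DerSimonian-Laird between-individual variance component,
    sparsifies profiles by 95% confidence interval and renormalizes, and
    tabulates Y-chromosome and mitochondrial haplogroup composition with
    prefix-matching semantics. Includes a Balding-Nichols simulator for
    frequency panels and admixed cohorts with configurable missingness and
    pseudo-haploid coding, VCF/TSV input handling with allele harmonization,
    and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    readr,
    rlang,
    stringr,
    ggplot2,
    generics,
    stats,
    utils,
    vcfR,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
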