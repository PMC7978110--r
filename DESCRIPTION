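Package: hetrace
Title: Subsampling Trace Estimators for Haseman-Elston Heritability
Version: 0.1.0
Authors@R:
    person("hetrace", "maintainers", email = "hetrace@example.org",
           role = c("aut", "cre"))
Author: hetrace maintainers [aut, cre]
Maintainer: hetrace maintainers <hetrace@example.org>
Description: Method-of-moments (Haseman-Elston) SNP heritability estimation
    at biobank scale without materializing the genetic relationship matrix
    (GRM). Implements three matched-cost estimators of tr(K'K) - the
    Gaussian-probe randomized estimator with its corrected sampling
    variance, a block subsampling estimator, and a lower-triangle "shotgun"
    pair-sampling estimator with an analytic sampling variance - built on
    the effective number of markers Me = 1/var(K_o). Provides a synthesized
    heritability estimator from per-SNP marginal chi-square statistics and
    a subsampled Me, chromosome-wise heritability partitioning (single and
    joint), weighted-GRM variants, a polygenicity diagnostic, PLINK
    bed/bim/fam input/output, and a genotype/phenotype simulator with
    controlled minor allele frequency and adjacent-marker linkage
    disequilibrium (Lewontin's D').
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
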