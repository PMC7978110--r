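#' Published per-autosome effective-marker estimates (UK Biobank)
#'
#' Reference table of per-autosome marker counts and effective marker
#' numbers (standardized `me_c` and weighted `me_w_c` GRM) estimated on
#' 278,788 unrelated white-British UK Biobank individuals genotyped at
#' 525,460 autosomal SNPs with MAF > 0.01. Genome-wide, `Me ~ 87,351` on
#' that panel. Shipped as a worked example for the closed-form trace
#' identity and the polygenicity slope; the underlying genotypes are
#' restricted-access and are not part of this package.
#'
#' @return A data frame with columns `autosome`, `n_markers`, `me_c`,
#'   `me_w_c` (22 rows).
#' @export
ukb_autosome_me <- function() {
  path <- system.file("extdata", "ukb_autosome_me.tsv", package = "hetrace",
                      mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t")
}

#' Genome-wide reference constants for the UK Biobank worked example
#'
#' The unrelated white-British panel behind [ukb_autosome_me()]:
#' `N = 278,788` individuals, `M = 525,460` SNPs, genome-wide effective
#' marker count `Me = 87,351` (rounded).
#'
#' @return Named list with `N`, `M`, `Me`.
#' @export
ukb_reference <- function() {
  list(N = 278788L, M = 525460L, Me = 87351)
}
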