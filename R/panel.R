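#' Genotype panel container
#'
#' A `genotype_panel` holds an N x M matrix of reference-allele counts
#' (0/1/2, `NA` for missing) together with per-SNP metadata: identifiers,
#' chromosome labels, base-pair positions and the reference-allele
#' frequency estimated from the non-missing calls. It is the common input
#' of every estimator in the package.
#'
#' @param genotypes integer/numeric N x M matrix with values in
#'   \{0, 1, 2, NA\}; rows are individuals, columns are SNPs.
#' @param snp_ids character vector of length M (defaults to `snp1..snpM`).
#' @param chromosomes per-SNP chromosome labels, length M; must form
#'   contiguous runs so per-chromosome slicing is well defined.
#' @param positions per-SNP base-pair positions, length M.
#' @param sample_ids character vector of length N.
#'
#' @return An object of class `genotype_panel`: a list with elements
#'   `genotypes`, `snp_ids`, `chromosomes`, `positions`, `allele_freq`
#'   (reference-allele frequency from non-missing calls), `n_nonmissing`
#'   (per-SNP complete-case count) and `sample_ids`.
#' @export
genotype_panel <- function(genotypes, snp_ids = NULL, chromosomes = NULL,
                           positions = NULL, sample_ids = NULL) {
  genotypes <- as.matrix(genotypes)
  if (!all(genotypes %in% c(0, 1, 2) | is.na(genotypes)))
    stop_domain("genotypes must be allele counts in {0, 1, 2} or NA")
  n <- nrow(genotypes)
  m <- ncol(genotypes)
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(m))
  if (is.null(chromosomes)) chromosomes <- rep("1", m)
  chromosomes <- as.character(chromosomes)
  if (is.null(positions)) positions <- stats::ave(
    seq_len(m), chromosomes, FUN = seq_along)
  if (is.null(sample_ids)) sample_ids <- paste0("id", seq_len(n))
  if (length(snp_ids) != m || length(chromosomes) != m || length(positions) != m)
    stop_domain("per-SNP metadata must have length M = %d", m)
  if (length(sample_ids) != n)
    stop_domain("sample_ids must have length N = %d", n)
  # contiguity: each chromosome label occupies one run of columns
  r <- rle(chromosomes)
  if (anyDuplicated(r$values))
    stop_domain("chromosome labels must form contiguous blocks of SNPs")
  n_obs <- colSums(!is.na(genotypes))
  if (any(n_obs == 0L)) stop_domain("SNP with no non-missing calls")
  p <- colSums(genotypes, na.rm = TRUE) / (2 * n_obs)
  structure(
    list(genotypes = genotypes, snp_ids = as.character(snp_ids),
         chromosomes = chromosomes, positions = as.integer(positions),
         allele_freq = p, n_nonmissing = as.integer(n_obs),
         sample_ids = as.character(sample_ids)),
    class = "genotype_panel")
}

#' @export
dim.genotype_panel <- function(x) dim(x$genotypes)

#' @export
print.genotype_panel <- function(x, ...) {
  d <- dim(x$genotypes)
  chr <- unique(x$chromosomes)
  cat(sprintf("genotype_panel: %d individuals x %d SNPs on %d chromosome(s)\n",
              d[1], d[2], length(chr)))
  cat(sprintf("  allele freq: [%.3f, %.3f]; missing calls: %d\n",
              min(x$allele_freq), max(x$allele_freq),
              sum(is.na(x$genotypes))))
  invisible(x)
}

#' Subset a genotype panel by SNPs and/or individuals
#'
#' @param panel a [genotype_panel()].
#' @param snps SNP selector: logical/integer index on columns.
#' @param individuals row selector.
#' @return A new `genotype_panel` with allele frequencies recomputed from
#'   the retained individuals.
#' @export
subset_panel <- function(panel, snps = NULL, individuals = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (is.null(snps)) snps <- seq_len(ncol(panel$genotypes))
  if (is.null(individuals)) individuals <- seq_len(nrow(panel$genotypes))
  genotype_panel(panel$genotypes[individuals, snps, drop = FALSE],
                 snp_ids = panel$snp_ids[snps],
                 chromosomes = panel$chromosomes[snps],
                 positions = panel$positions[snps],
                 sample_ids = panel$sample_ids[individuals])
}

#' Concatenate two genotype panels over SNPs
#'
#' Joins the marker sets of two panels measured on the same individuals,
#' e.g. to assemble a genome from independently simulated chromosome
#' blocks with different LD regimes. Chromosome labels must not overlap.
#'
#' @param a,b [genotype_panel()] objects with identical `sample_ids`.
#' @return A combined `genotype_panel`.
#' @export
bind_panels <- function(a, b) {
  stopifnot(inherits(a, "genotype_panel"), inherits(b, "genotype_panel"))
  if (!identical(a$sample_ids, b$sample_ids))
    stop_domain("panels must be over the same individuals, in the same order")
  if (length(intersect(unique(a$chromosomes), unique(b$chromosomes))))
    stop_domain("chromosome labels overlap between the two panels")
  genotype_panel(cbind(a$genotypes, b$genotypes),
                 snp_ids = c(a$snp_ids, b$snp_ids),
                 chromosomes = c(a$chromosomes, b$chromosomes),
                 positions = c(a$positions, b$positions),
                 sample_ids = a$sample_ids)
}
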