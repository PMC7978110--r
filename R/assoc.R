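#' Per-SNP marginal chi-square statistics
#'
#' For each SNP, the score statistic of the marginal regression of the
#' phenotype on the 2pq-standardized genotype:
#' `chisq_l = (x~_l' y~)^2 / n_l`, with `y~` the phenotype residualized
#' on the intercept (and covariates, if any) and rescaled so that
#' `||y~||^2 = N`. Under the null each statistic is asymptotically
#' chi-square with 1 df; their mean carries the heritability signal
#' through `N * mean(chisq) = y~' K y~` (exact when no data are missing
#' and no covariates are used).
#'
#' With covariates both the phenotype and every genotype column are
#' residualized on `[1, C]` before the score is formed (Frisch-Waugh),
#' which reproduces the multivariate-regression statistic.
#'
#' @param panel a [genotype_panel()].
#' @param phenotype numeric vector of length N.
#' @param covariates optional N x q numeric matrix, full column rank;
#'   an intercept is always included and must not be supplied.
#' @return A `summary_stats` data frame with columns `snp_id`,
#'   `chromosome`, `n_used`, `chisq`, `weight_2pq`, and attribute `n_total`.
#' @export
marginal_chisq <- function(panel, phenotype, covariates = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  n <- nrow(panel$genotypes)
  if (length(phenotype) != n)
    stop_domain("phenotype length %d != N = %d", length(phenotype), n)
  if (anyNA(phenotype)) stop_domain("phenotype contains missing values")
  if (stats::sd(phenotype) == 0) stop_domain("constant phenotype")
  xs <- standardize(panel)
  y <- phenotype - mean(phenotype)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n) stop_domain("covariates must have N rows")
    qrc <- qr(cbind(1, covariates))
    if (qrc$rank < ncol(covariates) + 1L)
      stop_domain("covariate matrix is rank deficient")
    y <- qr.resid(qrc, y)
    xs <- qr.resid(qrc, xs)
  }
  y <- y / sqrt(mean(y^2))               # ||y~||^2 = N exactly
  n_used <- panel$n_nonmissing
  chisq <- drop(crossprod(xs, y))^2 / n_used
  p <- panel$allele_freq
  out <- data.frame(snp_id = panel$snp_ids, chromosome = panel$chromosomes,
                    n_used = n_used, chisq = chisq,
                    weight_2pq = 2 * p * (1 - p))
  attr(out, "n_total") <- n
  class(out) <- c("summary_stats", "data.frame")
  out
}

#' Write summary statistics as a tab-delimited table
#'
#' Columns `SNP`, `CHR`, `N`, `CHISQ`, `TWO_PQ` — the summary-statistics
#' entry point for the hybrid route (individual-level data not needed
#' downstream).
#'
#' @param stats a `summary_stats` object from [marginal_chisq()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(stats, path) {
  stopifnot(inherits(stats, "summary_stats"))
  utils::write.table(
    data.frame(SNP = stats$snp_id, CHR = stats$chromosome, N = stats$n_used,
               CHISQ = stats$chisq, TWO_PQ = stats$weight_2pq),
    path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}

#' Read summary statistics written by [write_sumstats()]
#'
#' @param path tab-delimited file with columns SNP, CHR, N, CHISQ, TWO_PQ.
#' @return A `summary_stats` data frame.
#' @export
read_sumstats <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = c(SNP = "character", CHR = "character"))
  need <- c("SNP", "CHR", "N", "CHISQ", "TWO_PQ")
  if (!all(need %in% names(tab)))
    stop_domain("%s: expected columns %s", path, paste(need, collapse = ", "))
  if (any(tab$CHISQ < 0)) stop_domain("%s: negative chi-square values", path)
  out <- data.frame(snp_id = tab$SNP, chromosome = tab$CHR, n_used = tab$N,
                    chisq = tab$CHISQ, weight_2pq = tab$TWO_PQ)
  attr(out, "n_total") <- max(tab$N)
  class(out) <- c("summary_stats", "data.frame")
  out
}
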