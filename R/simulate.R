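#' Simulation configuration
#'
#' Describes the synthetic world used throughout the test suite: unrelated
#' diploid individuals, per-locus target allele frequencies drawn uniformly
#' from `maf_range`, and adjacent-marker linkage disequilibrium controlled
#' through Lewontin's D' drawn uniformly from `dprime_range`. Defaults
#' follow the simulation design the estimators were validated under:
#' MAF ~ U(0.03, 0.5) and strong LD D' in (0.6, 0.8); weak LD corresponds
#' to `dprime_range = c(0, 0.2)`.
#'
#' @param n_individuals sample size N.
#' @param n_markers number of biallelic markers M.
#' @param maf_range length-2 numeric in (0, 0.5], lower bound > 0.
#' @param dprime_range length-2 numeric inside \[0, 1\].
#' @param h2 narrow-sense SNP heritability used by [simulate_phenotype()].
#' @param chromosome_sizes optional integer vector of per-chromosome marker
#'   counts summing to `n_markers`; chromosomes are independent blocks.
#' @param seed integer seed; required, all randomness flows from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_individuals, n_markers,
                       maf_range = c(0.03, 0.5),
                       dprime_range = c(0.6, 0.8),
                       h2 = 0.5,
                       chromosome_sizes = NULL,
                       seed) {
  if (!is_count(n_individuals) || !is_count(n_markers))
    stop_domain("n_individuals and n_markers must be positive integers")
  if (length(maf_range) != 2L || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop_domain("maf_range must be an interval in (0, 0.5]")
  if (length(dprime_range) != 2L || dprime_range[1] < 0 ||
      dprime_range[2] > 1 || dprime_range[1] > dprime_range[2])
    stop_domain("dprime_range must be an interval inside [0, 1]")
  if (length(h2) != 1L || h2 < 0 || h2 > 1)
    stop_domain("h2 must lie in [0, 1]")
  if (is.null(chromosome_sizes)) chromosome_sizes <- n_markers
  chromosome_sizes <- as.integer(chromosome_sizes)
  if (any(chromosome_sizes < 1L) || sum(chromosome_sizes) != n_markers)
    stop_domain("chromosome_sizes must be positive and sum to n_markers")
  if (missing(seed) || is.null(seed) || !is.numeric(seed) ||
      !is_count(abs(seed) + 1))
    stop_domain("an integer seed is required")
  structure(list(n_individuals = as.integer(n_individuals),
                 n_markers = as.integer(n_markers),
                 maf_range = as.numeric(maf_range),
                 dprime_range = as.numeric(dprime_range),
                 h2 = as.numeric(h2),
                 chromosome_sizes = chromosome_sizes,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# One haplotype matrix (n x m, 0/1) for a single chromosome: first-order
# Markov chain along the markers. For adjacent loci with frequencies
# p1, p2 and drawn D', the positive-D convention sets
#   D = D' * min(p1 (1 - p2), (1 - p1) p2),
# giving transition probabilities
#   P(a2 = 1 | a1 = 1) = p2 + D / p1
#   P(a2 = 1 | a1 = 0) = p2 - D / (1 - p1),
# which are in [0, 1] by construction (clipped defensively anyway).
sim_haplotypes_chrom <- function(n, p, dprime) {
  m <- length(p)
  h <- matrix(0L, n, m)
  h[, 1L] <- as.integer(stats::runif(n) < p[1L])
  if (m >= 2L) {
    for (l in 2:m) {
      d <- dprime[l - 1L] * min(p[l - 1L] * (1 - p[l]),
                                (1 - p[l - 1L]) * p[l])
      p11 <- min(1, max(0, p[l] + d / p[l - 1L]))
      p10 <- min(1, max(0, p[l] - d / (1 - p[l - 1L])))
      prev <- h[, l - 1L] == 1L
      pr <- ifelse(prev, p11, p10)
      h[, l] <- as.integer(stats::runif(n) < pr)
    }
  }
  h
}

#' Simulate a genotype panel with controlled MAF and adjacent-marker LD
#'
#' Genotypes are the sum of two independent haplotypes per individual
#' (Hardy-Weinberg sampling). Within a chromosome, each haplotype follows a
#' first-order Markov chain whose adjacent-locus transition probabilities
#' realize a drawn Lewontin's D'; LD therefore decays geometrically with
#' marker distance and is exactly zero across chromosomes.
#'
#' @param config a [sim_config()].
#' @param keep_haplotypes if `TRUE`, attach the two latent haplotype
#'   matrices as attribute `"haplotypes"` (used by LD oracles in tests).
#' @return A [genotype_panel()]. The drawn per-pair D' values are attached
#'   as attribute `"dprime_drawn"` (NA across chromosome boundaries).
#' @export
simulate_genotypes <- function(config, keep_haplotypes = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_individuals
  with_seed(config$seed, {
    p <- stats::runif(config$n_markers, config$maf_range[1], config$maf_range[2])
    blocks <- config$chromosome_sizes
    ends <- cumsum(blocks)
    starts <- ends - blocks + 1L
    dprime <- rep(NA_real_, config$n_markers - 1L)
    h1 <- vector("list", length(blocks))
    h2 <- vector("list", length(blocks))
    for (b in seq_along(blocks)) {
      idx <- starts[b]:ends[b]
      dp <- if (blocks[b] >= 2L)
        stats::runif(blocks[b] - 1L, config$dprime_range[1], config$dprime_range[2])
      else numeric(0)
      if (blocks[b] >= 2L) dprime[idx[-length(idx)]] <- dp
      h1[[b]] <- sim_haplotypes_chrom(n, p[idx], dp)
      h2[[b]] <- sim_haplotypes_chrom(n, p[idx], dp)
    }
    h1 <- do.call(cbind, h1)
    h2 <- do.call(cbind, h2)
    geno <- h1 + h2
    panel <- genotype_panel(
      geno,
      chromosomes = rep(seq_along(blocks), blocks),
      positions = unlist(lapply(blocks, seq_len), use.names = FALSE))
    attr(panel, "dprime_drawn") <- dprime
    attr(panel, "target_freq") <- p
    if (keep_haplotypes) attr(panel, "haplotypes") <- list(h1 = h1, h2 = h2)
    panel
  })
}

#' Simulate a polygenic phenotype
#'
#' Generates `y = X~ beta + e` on the standardized genotypes, with
#' `beta_l ~ N(0, h2 / M_causal)` for causal SNPs and
#' `e_i ~ N(0, 1 - h2)`, then standardizes y to zero mean and unit sample
#' variance. By default every SNP is causal (the infinitesimal model);
#' `causal` restricts the effects to a subset, e.g. to one chromosome,
#' which deliberately breaks the polygenicity assumption.
#'
#' @param panel a [genotype_panel()].
#' @param h2 heritability in \[0, 1\].
#' @param seed integer seed.
#' @param causal optional column selector for the causal SNPs.
#' @return Numeric phenotype vector of length N, standardized.
#' @export
simulate_phenotype <- function(panel, h2, seed, causal = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (length(h2) != 1L || !is.finite(h2) || h2 < 0 || h2 > 1)
    stop_domain("h2 must lie in [0, 1]")
  xs <- standardize(panel)
  if (!is.null(causal)) xs <- xs[, causal, drop = FALSE]
  m <- ncol(xs)
  n <- nrow(xs)
  with_seed(seed, {
    beta <- stats::rnorm(m, 0, sqrt(h2 / m))
    e <- stats::rnorm(n, 0, sqrt(1 - h2))
    y <- drop(xs %*% beta) + e
    y <- y - mean(y)
    s <- stats::sd(y)
    if (s == 0) stop_domain("degenerate phenotype: zero variance")
    y / s
  })
}
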