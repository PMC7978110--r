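me_value <- function(x) if (inherits(x, "me_estimate")) x$me else as.numeric(x)

new_h2_estimate <- function(h2, var_h2, method, n, sigma2_e = NA_real_,
                            trace_source = NULL) {
  structure(list(h2 = h2, var_h2 = var_h2, method = method,
                 n = as.integer(n), sigma2_e = sigma2_e,
                 trace_source = trace_source),
            class = "h2_estimate")
}

#' @export
print.h2_estimate <- function(x, ...) {
  cat(sprintf("h2 [%s]: %.4f (se %.3f), N = %d\n", x$method, x$h2,
              sqrt(max(x$var_h2, 0)), x$n))
  invisible(x)
}

#' Direct Haseman-Elston heritability from a dense GRM
#'
#' Solves the 2x2 method-of-moments normal equations
#' `[tr(K'K) tr(K); tr(K) N] (h2, sigma_e^2)' = (y'Ky, y'y)'`
#' exactly. This is the oracle / small-N path; estimates are not clamped
#' to \[0, 1\] — under the null the method-of-moments estimator is
#' centered at 0 and can be negative.
#'
#' @param phenotype numeric vector of length N; standardized internally
#'   to zero mean and `||y||^2 = N`.
#' @param grm a [build_grm()] result.
#' @return An `h2_estimate` with `h2`, `sigma2_e` and an Eq.-4-style
#'   `var_h2` computed from the full off-diagonal dispersion.
#' @export
h2_direct <- function(phenotype, grm) {
  stopifnot(inherits(grm, "grm"))
  k <- grm$values
  n <- nrow(k)
  if (length(phenotype) != n) stop_domain("phenotype length != N")
  y <- phenotype - mean(phenotype)
  if (all(y == 0)) stop_domain("constant phenotype")
  y <- y / sqrt(mean(y^2))
  tr <- exact_traces(grm)
  if (tr$tr_KtK - n <= .Machine$double.eps * n)
    stop_domain("degenerate GRM: tr(K'K) - N <= 0 (is K the identity?)")
  a <- matrix(c(tr$tr_KtK, tr$tr_K, tr$tr_K, n), 2, 2)
  det_a <- a[1, 1] * a[2, 2] - a[1, 2]^2
  if (abs(det_a) < 1e-10 * abs(a[1, 1] * a[2, 2]))
    stop_domain("degenerate GRM: singular moment system")
  b <- c(drop(crossprod(y, k %*% y)), sum(y^2))
  sol <- solve(a, b)
  os <- offdiag_stats(grm)
  me_hat <- 1 / os$var_Ko
  var_h2 <- 2 * me_hat / n^2 +
    me_hat^2 * os$var_Ko2 / (n * (n - 1) / 2) * sol[1]^2
  new_h2_estimate(sol[1], var_h2, "direct", n, sigma2_e = sol[2])
}

#' Synthesized heritability from summary statistics and Me
#'
#' The biobank-scale route: `h2_hat = Me_hat * (mean(chisq) - 1) / N`,
#' equivalently `(N mean(chisq) - N) / (N^2 / Me_hat)`, which replaces
#' `tr(K'K)` in the normal equations by its closed form `N^2/Me + N`.
#' Its sampling variance is
#' `var(h2_hat) = 2 Me_hat / N^2 + Me_hat^2 var(K_o^2) / n * h2_hat^2`,
#' whose first term is the null-variance floor shared with REML and whose
#' second term propagates the Me subsampling noise (`n` = number of
#' off-diagonal pairs behind the Me estimate).
#'
#' @param stats a `summary_stats` object from [marginal_chisq()].
#' @param me an `me_estimate` (any sampler; `var_Ko2` must be present).
#' @param N sample size the statistics were computed on.
#' @return An `h2_estimate`.
#' @export
h2_synthesized <- function(stats, me, N) {
  stopifnot(inherits(stats, "summary_stats"), inherits(me, "me_estimate"))
  if (!is_count(N)) stop_domain("N must be a positive integer")
  if (!is.finite(me$var_Ko2))
    stop_domain("me estimate lacks var_Ko2; use the full or shotgun sampler")
  ebar <- mean(stats$chisq)
  h2 <- me$me * (ebar - 1) / N
  var_h2 <- 2 * me$me / N^2 + me$me^2 * me$var_Ko2 / me$n_pairs_used * h2^2
  new_h2_estimate(h2, var_h2, "synthesized", N, trace_source = me)
}

#' Weighted-GRM heritability from summary statistics
#'
#' Uses the 2pq-weighted mean of the per-SNP chi-square statistics in the
#' numerator and the weighted effective marker count in the denominator:
#' `h2_w = (N * sum(w chisq)/sum(w) - N) / (N^2 / Me_w)`, `w = 2 p q`.
#' Reduces to [h2_synthesized()] when all weights are equal.
#'
#' @param stats a `summary_stats` object carrying `weight_2pq`.
#' @param me_w an `me_estimate` of kind `"weighted"`.
#' @param N sample size.
#' @return An `h2_estimate`.
#' @export
h2_weighted <- function(stats, me_w, N) {
  stopifnot(inherits(stats, "summary_stats"), inherits(me_w, "me_estimate"))
  if (!is_count(N)) stop_domain("N must be a positive integer")
  if (!is.finite(me_w$var_Ko2))
    stop_domain("me estimate lacks var_Ko2; use the full or shotgun sampler")
  if (!identical(me_w$kind, "weighted"))
    warning("me_w was not estimated with the weighted GRM recipe")
  w <- stats$weight_2pq
  if (any(w < 0) || sum(w) <= 0) stop_domain("invalid 2pq weights")
  ebar_w <- sum(w * stats$chisq) / sum(w)
  h2 <- me_value(me_w) * (ebar_w - 1) / N
  var_h2 <- 2 * me_value(me_w) / N^2 +
    me_value(me_w)^2 * me_w$var_Ko2 / me_w$n_pairs_used * h2^2
  new_h2_estimate(h2, var_h2, "weighted", N, trace_source = me_w)
}

#' Joint moment-system matrix for chromosome partitioning
#'
#' The (C+1) x (C+1) matrix of the joint method-of-moments system over C
#' chromosome GRMs plus the residual: diagonal entries
#' `N^2 / Me.c + N`, every off-diagonal entry `N` (cross-chromosome LD
#' taken as zero, so cross traces reduce to N), last row/column `N`.
#' Its inverse has the closed form: the first C diagonal entries are
#' `Me.c / N^2`, the off-diagonal block among chromosomes is 0, and the
#' last column is `-Me.c / N^2`.
#'
#' @param me_per_chrom numeric vector (or list of `me_estimate`) of Me.c.
#' @param N common sample size.
#' @return The (C+1) x (C+1) matrix.
#' @export
joint_moment_matrix <- function(me_per_chrom, N) {
  mec <- vapply(me_per_chrom, me_value, numeric(1))
  c_chr <- length(mec)
  a <- matrix(N, c_chr + 1L, c_chr + 1L)
  diag(a)[seq_len(c_chr)] <- N^2 / mec + N
  a
}

new_partition_estimate <- function(table, h2_chr_total, h2_genome, mode,
                                   ratio_expected) {
  structure(list(table = table, h2_chr_total = h2_chr_total,
                 h2_genome = h2_genome, mode = mode,
                 ratio_expected = ratio_expected),
            class = "partition_estimate")
}

#' @export
print.partition_estimate <- function(x, ...) {
  cat(sprintf("chromosome partition [%s]: sum h2_c = %.4f", x$mode,
              x$h2_chr_total))
  if (is.finite(x$h2_genome))
    cat(sprintf("; genome h2 = %.4f (expected ratio %.3f)",
                x$h2_genome, x$ratio_expected))
  cat("\n")
  print(x$table, digits = 4)
  invisible(x)
}

chromosome_means <- function(stats) {
  chrs <- unique(stats$chromosome)
  data.frame(
    chromosome = chrs,
    ebar = vapply(chrs, function(ch)
      mean(stats$chisq[stats$chromosome == ch]), numeric(1)),
    n_c = vapply(chrs, function(ch)
      round(stats::median(stats$n_used[stats$chromosome == ch])), numeric(1)))
}

resolve_me_per_chrom <- function(me_per_chrom, chrs) {
  if (!is.null(names(me_per_chrom))) {
    missing_chr <- setdiff(chrs, names(me_per_chrom))
    if (length(missing_chr))
      stop_domain("no Me estimate for chromosome(s): %s",
                  paste(missing_chr, collapse = ", "))
    me_per_chrom <- me_per_chrom[chrs]
  } else if (length(me_per_chrom) != length(chrs)) {
    stop_domain("me_per_chrom has %d entries for %d chromosomes",
                length(me_per_chrom), length(chrs))
  }
  vapply(me_per_chrom, me_value, numeric(1))
}

#' Chromosome-wise heritability, one chromosome at a time
#'
#' Per chromosome: `h2_c = (N_c mean_c(chisq) - N_c) / (N_c^2 / Me.c)`
#' using that chromosome's SNPs and its own sample size `N_c`. The sum
#' over chromosomes is the chromosome-wise partition heritability; its
#' ratio to the whole-genome estimate, compared against
#' `Me / sum(Me.c)`, is the polygenicity diagnostic.
#'
#' @param stats a `summary_stats` object spanning the genome.
#' @param me_per_chrom per-chromosome Me estimates (named list/vector, or
#'   in panel chromosome order).
#' @param N_per_chrom optional per-chromosome sample sizes; defaults to
#'   the median `n_used` within each chromosome.
#' @param me_genome optional genome-wide `me_estimate`; when supplied the
#'   whole-genome synthesized estimate and the expected ratio are filled.
#' @return A `partition_estimate`: per-chromosome table, `h2_chr_total`,
#'   `h2_genome`, `mode = "single"`, `ratio_expected = Me / sum(Me.c)`.
#' @export
partition_single <- function(stats, me_per_chrom, N_per_chrom = NULL,
                             me_genome = NULL) {
  stopifnot(inherits(stats, "summary_stats"))
  cm <- chromosome_means(stats)
  mec <- resolve_me_per_chrom(me_per_chrom, cm$chromosome)
  if (!is.null(N_per_chrom)) {
    if (length(N_per_chrom) != nrow(cm))
      stop_domain("N_per_chrom must have one entry per chromosome")
    cm$n_c <- as.numeric(N_per_chrom)
  }
  h2_c <- mec * (cm$ebar - 1) / cm$n_c
  tab <- data.frame(chromosome = cm$chromosome, n = cm$n_c, me_c = mec,
                    h2_c = h2_c)
  h2_genome <- NA_real_
  ratio <- NA_real_
  if (!is.null(me_genome)) {
    n_tot <- attr(stats, "n_total")
    if (is.null(n_tot)) n_tot <- max(stats$n_used)
    h2_genome <- h2_synthesized(stats, me_genome, n_tot)$h2
    ratio <- me_value(me_genome) / sum(mec)
  }
  new_partition_estimate(tab, sum(h2_c), h2_genome, "single", ratio)
}

#' Chromosome-wise heritability, jointly in one moment system
#'
#' Solves the (C+1)-dimensional system built by [joint_moment_matrix()]
#' with right-hand side `(N mean_c(chisq), ..., N)`. Requires a common
#' sample size across chromosomes; with unequal per-chromosome sample
#' sizes the closed-form structure no longer holds, so the function warns
#' and falls back to [partition_single()] with each chromosome's own N,
#' flagging the mode.
#'
#' @param stats a `summary_stats` object spanning the genome.
#' @param me_per_chrom per-chromosome Me estimates.
#' @param N common sample size.
#' @param me_genome optional genome-wide `me_estimate` (as in
#'   [partition_single()]).
#' @return A `partition_estimate` with `mode = "joint"` (or
#'   `"joint-fallback-single"` after the unequal-N fallback).
#' @export
partition_joint <- function(stats, me_per_chrom, N, me_genome = NULL) {
  stopifnot(inherits(stats, "summary_stats"))
  cm <- chromosome_means(stats)
  mec <- resolve_me_per_chrom(me_per_chrom, cm$chromosome)
  if (length(unique(cm$n_c)) > 1L) {
    warning("per-chromosome sample sizes differ; falling back to single-",
            "chromosome estimation with each chromosome's own N")
    out <- partition_single(stats, me_per_chrom, N_per_chrom = cm$n_c,
                            me_genome = me_genome)
    out$mode <- "joint-fallback-single"
    return(out)
  }
  if (!is_count(N)) stop_domain("N must be a positive integer")
  a <- joint_moment_matrix(mec, N)
  b <- c(N * cm$ebar, N)
  kap <- kappa(a, exact = FALSE)
  sol <- tryCatch(solve(a, b), error = function(e)
    stop_domain("singular joint system (condition number %.3g): %s",
                kap, conditionMessage(e)))
  h2_c <- sol[seq_len(nrow(cm))]
  tab <- data.frame(chromosome = cm$chromosome, n = N, me_c = mec,
                    h2_c = h2_c)
  h2_genome <- NA_real_
  ratio <- NA_real_
  if (!is.null(me_genome)) {
    h2_genome <- h2_synthesized(stats, me_genome, N)$h2
    ratio <- me_value(me_genome) / sum(mec)
  }
  out <- new_partition_estimate(tab, sum(h2_c), h2_genome, "joint", ratio)
  out$sigma2_e <- sol[nrow(cm) + 1L]
  out
}

#' Expected polygenicity slope Me / sum(Me.c)
#'
#' The expected ratio of whole-genome to summed chromosome-wise
#' heritability for a purely polygenic trait. Points above this slope
#' indicate effect sizes concentrated on particular chromosomes (e.g.
#' MHC-driven traits).
#'
#' @param me_genome genome-wide Me (number or `me_estimate`).
#' @param me_per_chrom per-chromosome Me values (vector or list).
#' @return `me_genome / sum(me_per_chrom)`.
#' @export
polygenicity_ratio <- function(me_genome, me_per_chrom) {
  mg <- me_value(me_genome)
  mec <- vapply(me_per_chrom, me_value, numeric(1))
  mg / sum(mec)
}
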