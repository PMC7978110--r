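#' Standardize genotypes to mean zero and 2pq scale
#'
#' Missing calls are imputed to the per-SNP mean `2 p_hat` so each column
#' is exactly mean-zero, then scaled by `sqrt(2 p_hat q_hat)` with
#' `p_hat` the sample reference-allele frequency. This is the
#' standardization underlying the GRM `K = X~ X~' / M`.
#'
#' @param panel a [genotype_panel()].
#' @return An N x M numeric matrix.
#' @export
standardize <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  p <- panel$allele_freq
  mono <- p <= 0 | p >= 1
  if (any(mono))
    stop_domain("monomorphic SNP(s): %s; filter before standardizing",
                paste(utils::head(panel$snp_ids[mono], 5), collapse = ", "))
  g <- panel$genotypes
  if (anyNA(g)) {
    miss <- which(is.na(g), arr.ind = TRUE)
    g[miss] <- 2 * p[miss[, 2]]
  }
  sweep(sweep(g, 2, 2 * p, "-"), 2, sqrt(2 * p * (1 - p)), "/")
}

#' Build a (weighted) genetic relationship matrix
#'
#' The standardized GRM is `K = X~ X~' / M`. The weighted GRM centers the
#' genotypes without per-SNP scaling and divides by the pooled variance:
#' `K_w[i,j] = sum_l (x_il - 2 p_l)(x_jl - 2 p_l) / sum_l 2 p_l q_l`,
#' which downweights rare variants relative to `K`.
#'
#' This is the dense oracle / small-N path: large-sample analyses should
#' use the subsampling estimators instead of materializing K.
#'
#' @param panel a [genotype_panel()].
#' @param kind `"standardized"` or `"weighted"`.
#' @param max_n refuse to materialize the N x N matrix above this cap.
#' @return An object of class `grm`: list with `values` (N x N symmetric),
#'   `kind` and `n_markers_used`.
#' @export
build_grm <- function(panel, kind = c("standardized", "weighted"),
                      max_n = 20000L) {
  stopifnot(inherits(panel, "genotype_panel"))
  kind <- match.arg(kind)
  n <- nrow(panel$genotypes); m <- ncol(panel$genotypes)
  if (n < 2L || m < 1L) stop_domain("need N >= 2 and M >= 1")
  if (n > max_n)
    stop_domain("N = %d exceeds the dense-GRM cap (%d); use the subsampling estimators",
                n, max_n)
  if (kind == "standardized") {
    k <- tcrossprod(standardize(panel)) / m
  } else {
    p <- panel$allele_freq
    g <- panel$genotypes
    if (anyNA(g)) {
      miss <- which(is.na(g), arr.ind = TRUE)
      g[miss] <- 2 * p[miss[, 2]]
    }
    xc <- sweep(g, 2, 2 * p, "-")
    k <- tcrossprod(xc) / sum(2 * p * (1 - p))
  }
  structure(list(values = k, kind = kind, n_markers_used = m), class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("grm (%s): %d x %d from %d markers; mean diag %.4f\n",
              x$kind, nrow(x$values), ncol(x$values), x$n_markers_used,
              mean(diag(x$values))))
  invisible(x)
}

#' Exact traces of a dense GRM
#'
#' Computes `tr(K)`, `tr(K'K) = sum_ij K_ij^2` (the squared Frobenius
#' norm) and `tr(K^4)` as the squared Frobenius norm of `K^2` (K is
#' symmetric). These are the oracles the subsampling estimators are
#' validated against; `tr(K^4)` enters the corrected sampling variance of
#' the randomized estimator, `2 tr(K^4) / B`.
#'
#' @param grm a [build_grm()] result.
#' @return List with `tr_K`, `tr_KtK`, `tr_K4`.
#' @export
exact_traces <- function(grm) {
  stopifnot(inherits(grm, "grm"))
  k <- grm$values
  k2 <- k %*% k
  list(tr_K = sum(diag(k)), tr_KtK = sum(k * k), tr_K4 = sum(k2 * k2))
}

#' Summary statistics of the GRM off-diagonal
#'
#' Statistics over the N(N-1)/2 lower-triangle elements `K_o`; their
#' dispersion defines the effective number of markers
#' `Me = 1 / var(K_o)`, and the dispersion of the squared elements drives
#' the sampling variance of the shotgun trace estimator. Variances use the
#' n-1 denominator.
#'
#' @param grm a [build_grm()] result with N >= 3.
#' @return List with `mean_Ko`, `var_Ko`, `mean_Ko2`, `var_Ko2`.
#' @export
offdiag_stats <- function(grm) {
  stopifnot(inherits(grm, "grm"))
  if (nrow(grm$values) < 3L) stop_domain("need N >= 3 for off-diagonal statistics")
  ko <- grm$values[lower.tri(grm$values)]
  list(mean_Ko = mean(ko), var_Ko = sample_var(ko),
       mean_Ko2 = mean(ko^2), var_Ko2 = sample_var(ko^2))
}

#' Export a GRM in GCTA binary format
#'
#' Writes `<prefix>.grm.bin` (lower triangle row-major including the
#' diagonal, 4-byte little-endian floats), `<prefix>.grm.N.bin` (pair-wise
#' marker counts, same layout) and `<prefix>.grm.id`.
#'
#' @param grm a [build_grm()] result.
#' @param panel the [genotype_panel()] the GRM was built from (ids).
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_gcta_grm <- function(grm, panel, prefix) {
  stopifnot(inherits(grm, "grm"), inherits(panel, "genotype_panel"))
  k <- grm$values
  n <- nrow(k)
  idx <- which(lower.tri(k, diag = TRUE), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  vals <- k[idx]
  con <- file(paste0(prefix, ".grm.bin"), "wb")
  writeBin(vals, con, size = 4L, endian = "little")
  close(con)
  con <- file(paste0(prefix, ".grm.N.bin"), "wb")
  writeBin(rep(as.numeric(grm$n_markers_used), length(vals)), con,
           size = 4L, endian = "little")
  close(con)
  utils::write.table(
    data.frame(panel$sample_ids, panel$sample_ids),
    paste0(prefix, ".grm.id"), quote = FALSE, row.names = FALSE,
    col.names = FALSE, sep = "\t")
  invisible(prefix)
}
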