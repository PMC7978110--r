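new_me_estimate <- function(me, n_pairs, var_Ko2, scope, kind, mean_Ko, N) {
  if (!is.finite(me) || me <= 0) stop_domain("Me estimate must be positive")
  structure(list(me = me, n_pairs_used = as.integer(n_pairs),
                 var_Ko2 = var_Ko2, scope = scope, kind = kind,
                 mean_Ko = mean_Ko, N = as.integer(N)),
            class = "me_estimate")
}

#' @export
print.me_estimate <- function(x, ...) {
  cat(sprintf("Me estimate [%s, %s]: %.2f from %d pairs\n",
              x$scope, x$kind, x$me, x$n_pairs_used))
  invisible(x)
}

# Off-diagonal GRM entries for given (i, j) pairs, streaming per-SNP:
# xs rows are standardized individuals, denom is M (standardized kind)
# or sum(2pq) (weighted kind, xs then centered-unscaled).
pair_offdiagonals <- function(xs, ij, denom, chunk = 4096L) {
  n <- nrow(ij)
  ko <- numeric(n)
  for (start in seq(1L, n, by = chunk)) {
    end <- min(start + chunk - 1L, n)
    sel <- start:end
    ko[sel] <- rowSums(xs[ij[sel, 1L], , drop = FALSE] *
                         xs[ij[sel, 2L], , drop = FALSE]) / denom
  }
  ko
}

#' Estimate the effective number of markers Me
#'
#' `Me = 1 / var(K_o)`: the number of independent markers that would
#' produce the observed dispersion of the GRM off-diagonal. It can be
#' estimated from all N(N-1)/2 pairs (`sampler = "full"`), from all pairs
#' within a random block of `size` individuals (`"block"`), or from
#' `size` random lower-triangle pairs (`"shotgun"`). Restricting `scope`
#' to one chromosome gives `Me.c`; `kind = "weighted"` uses the weighted
#' GRM recipe (centered genotypes, pooled 2pq denominator).
#'
#' @param panel a [genotype_panel()].
#' @param chromosome optional chromosome label restricting the SNP scope.
#' @param sampler `"full"`, `"block"` or `"shotgun"`.
#' @param size block size s (block) or pair count n (shotgun); ignored for
#'   the full sampler.
#' @param kind `"standardized"` or `"weighted"`.
#' @param seed integer seed for the subsamplers.
#' @return An object of class `me_estimate` with fields `me`,
#'   `n_pairs_used`, `var_Ko2` (dispersion of the squared off-diagonals,
#'   needed for the heritability variance), `scope`, `kind`, `mean_Ko`,
#'   `N`.
#' @export
estimate_me <- function(panel, chromosome = NULL,
                        sampler = c("full", "block", "shotgun"),
                        size = NULL,
                        kind = c("standardized", "weighted"),
                        seed = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  sampler <- match.arg(sampler)
  kind <- match.arg(kind)
  scope <- "genome"
  if (!is.null(chromosome)) {
    keep <- panel$chromosomes == as.character(chromosome)
    if (sum(keep) < 2L)
      stop_domain("chromosome '%s' selects fewer than 2 SNPs", chromosome)
    panel <- subset_panel(panel, snps = keep)
    scope <- paste0("chromosome ", chromosome)
  }
  n <- nrow(panel$genotypes)
  if (n < 3L) stop_domain("need N >= 3")
  if (kind == "standardized") {
    xs <- standardize(panel)
    denom <- ncol(xs)
  } else {
    p <- panel$allele_freq
    g <- panel$genotypes
    if (anyNA(g)) {
      miss <- which(is.na(g), arr.ind = TRUE)
      g[miss] <- 2 * p[miss[, 2]]
    }
    xs <- sweep(g, 2, 2 * p, "-")
    denom <- sum(2 * p * (1 - p))
    scope <- paste(scope, "(weighted)")
  }
  ko <- with_seed(seed, {
    if (sampler == "full") {
      kb <- tcrossprod(xs) / denom     # dense path; N capped upstream of use
      kb[lower.tri(kb)]
    } else if (sampler == "block") {
      if (!is_count(size) || size < 3 || size > n)
        stop_domain("block sampler needs 3 <= size <= N")
      idx <- sample.int(n, size)
      kb <- tcrossprod(xs[idx, , drop = FALSE]) / denom
      kb[lower.tri(kb)]
    } else {
      npairs <- n * (n - 1) / 2
      if (!is_count(size) || size < 3)
        stop_domain("shotgun sampler needs at least 3 pairs")
      if (size > npairs)
        stop_domain("size exceeds the N(N-1)/2 available pairs")
      pair_offdiagonals(xs, pair_from_index(sample.int(npairs, size)), denom)
    }
  })
  v <- sample_var(ko)
  if (v == 0)
    stop_domain("sampled off-diagonals have zero variance; increase the budget")
  new_me_estimate(1 / v, n_pairs = length(ko), var_Ko2 = sample_var(ko^2),
                  scope = scope, kind = kind, mean_Ko = mean(ko), N = n)
}

#' Per-chromosome Me estimates
#'
#' @param panel a [genotype_panel()].
#' @param ... passed to [estimate_me()] (sampler, size, kind, seed).
#' @return Named list of `me_estimate`, one per chromosome, in panel order.
#' @export
estimate_me_per_chromosome <- function(panel, ...) {
  chrs <- unique(panel$chromosomes)
  out <- lapply(chrs, function(ch) estimate_me(panel, chromosome = ch, ...))
  names(out) <- chrs
  out
}

#' Closed-form trace from Me
#'
#' For unrelated samples `tr(K'K) = N^2 / Me + N`; this converts an
#' effective-marker estimate into the trace that the Haseman-Elston
#' normal equations need.
#'
#' @param me effective number of markers (positive) or an `me_estimate`.
#' @param N sample size.
#' @return `N^2 / me + N`.
#' @export
me_to_trace <- function(me, N) {
  if (inherits(me, "me_estimate")) me <- me$me
  if (!is.numeric(me) || me <= 0) stop_domain("me must be positive")
  if (!is_count(N)) stop_domain("N must be a positive integer")
  N^2 / me + N
}
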