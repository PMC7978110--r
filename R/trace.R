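# Map 1-based linear indices of the strict lower triangle (row-major:
# (2,1), (3,1), (3,2), (4,1), ...) to (i, j) pairs with i > j.
# O(1) per index, no N(N-1)/2 enumeration.
pair_from_index <- function(k) {
  i <- ceiling((1 + sqrt(1 + 8 * k)) / 2)
  # guard floating-point edges
  lo <- (i - 1) * (i - 2) / 2
  i <- ifelse(k <= lo, i - 1, i)
  i <- ifelse(k > i * (i - 1) / 2, i + 1, i)
  j <- k - (i - 1) * (i - 2) / 2
  cbind(i = as.integer(i), j = as.integer(j))
}

#' Matched computational budgets for the three trace estimators
#'
#' The randomized estimator with `B` probe vectors costs O(NMB). To
#' compare estimators at equal cost, the block estimator uses
#' `s = floor(sqrt(2 B N))` individuals (s^2/2 pairs) and the shotgun
#' estimator `n = B * N` pairs, each pair costing O(M).
#'
#' @param N sample size.
#' @param B number of random probes.
#' @return List with `B`, `s`, `n`.
#' @export
matched_budgets <- function(N, B) {
  if (!is_count(N) || N < 2 || !is_count(B))
    stop_domain("need integer N >= 2 and B >= 1")
  list(B = as.integer(B), s = as.integer(floor(sqrt(2 * B * N))),
       n = as.integer(B * N))
}

new_trace_estimate <- function(value, method, budget, var_estimate = NA_real_,
                               seed = NULL, extra = list()) {
  if (!is.finite(value) || value <= 0)
    stop_domain("trace estimate must be positive; got %g", value)
  structure(c(list(value = value, method = method, budget = budget,
                   var_estimate = var_estimate, seed = seed), extra),
            class = "trace_estimate")
}

#' @export
print.trace_estimate <- function(x, ...) {
  cat(sprintf("tr(K'K) estimate [%s]: %.4f", x$method, x$value))
  if (is.finite(x$var_estimate))
    cat(sprintf("  (sampling var %.4g)", x$var_estimate))
  cat("\n  budget:", paste(names(x$budget), unlist(x$budget),
                           sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Randomized (Gaussian-probe) estimator of tr(K'K)
#'
#' Hutchinson-style estimator: with standard normal probes `z_b`,
#' `L_B = (1/B) sum_b ||X~ (X~' z_b)||^2 / M^2`, an unbiased estimate of
#' `tr(K'K)` computed without forming K. Its analytic sampling variance is
#' `2 tr(K^4) / B` (not `2 tr(K'K) / B`). `var_estimate` is the empirical
#' variance of the mean: sample variance of the B draws divided by B.
#'
#' @param panel a [genotype_panel()].
#' @param B number of probes, at least 2.
#' @param seed integer seed.
#' @return A `trace_estimate`; the per-probe draws are kept in `$draws`.
#' @export
trace_randomized <- function(panel, B, seed = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (!is_count(B) || B < 2) stop_domain("B must be an integer >= 2")
  xs <- standardize(panel)
  n <- nrow(xs); m <- ncol(xs)
  draws <- with_seed(seed, {
    z <- matrix(stats::rnorm(n * B), n, B)
    v <- xs %*% crossprod(xs, z)        # M * K z, column per probe
    colSums(v^2) / m^2
  })
  new_trace_estimate(mean(draws), "randomized", list(B = B),
                     var_estimate = sample_var(draws) / B, seed = seed,
                     extra = list(draws = draws))
}

#' Block-subsampling estimator of tr(K'K)
#'
#' Draws `s` individuals without replacement, computes the s(s-1)/2 GRM
#' off-diagonals among them, estimates `Me = 1 / var(K_o)` from that
#' block, and returns `L_S = N^2 / Me_hat + N` (the closed form of
#' `tr(K'K)` for unrelated samples). No analytic sampling variance is
#' available because block pairs share individuals; an optional bootstrap
#' (resampling individuals within the block) supplies one on request.
#'
#' @param panel a [genotype_panel()].
#' @param s block size, `3 <= s <= N`.
#' @param seed integer seed.
#' @param bootstrap compute a bootstrap variance of the estimate?
#' @param n_boot bootstrap resamples.
#' @return A `trace_estimate`; `$me` carries the block `me_estimate`.
#' @export
trace_block <- function(panel, s, seed = NULL, bootstrap = FALSE,
                        n_boot = 200L) {
  stopifnot(inherits(panel, "genotype_panel"))
  n <- nrow(panel$genotypes)
  if (!is_count(s) || s < 3 || s > n)
    stop_domain("block size s must satisfy 3 <= s <= N")
  xs <- standardize(panel)
  m <- ncol(xs)
  with_seed(seed, {
    idx <- sample.int(n, s)
    kb <- tcrossprod(xs[idx, , drop = FALSE]) / m
    ko <- kb[lower.tri(kb)]
    v <- sample_var(ko)
    if (v == 0)
      stop_domain("zero off-diagonal variance in the block; increase s")
    me <- 1 / v
    value <- n^2 / me + n
    var_est <- NA_real_
    if (bootstrap) {
      lt <- lower.tri(kb)
      bvals <- replicate(n_boot, {
        bi <- sample.int(s, s, replace = TRUE)
        # drop resampled pairs that are the same original individual:
        # their "off-diagonal" would actually be a diagonal element
        keep <- outer(bi, bi, "!=")[lt]
        kob <- kb[bi, bi][lt][keep]
        vb <- stats::var(kob)
        if (isTRUE(vb > 0)) n^2 * vb + n else NA_real_
      })
      var_est <- stats::var(bvals[is.finite(bvals)])
    }
    me_obj <- new_me_estimate(me, n_pairs = length(ko),
                              var_Ko2 = sample_var(ko^2),
                              scope = "genome", kind = "standardized",
                              mean_Ko = mean(ko), N = n)
    new_trace_estimate(value, "block", list(s = s),
                       var_estimate = var_est, seed = seed,
                       extra = list(me = me_obj))
  })
}

#' Lower-triangle shotgun estimator of tr(K'K)
#'
#' Samples `n` distinct lower-triangle GRM elements uniformly without
#' replacement and returns `L_T = N + (N^2 / n) sum_i K_o[A_i]^2`. Each
#' sampled element is an O(M) dot product of two individuals'
#' standardized genotype rows; K is never formed. The analytic sampling
#' variance `N^4 var(K_o^2) / n` is estimated by the sample variance
#' (n-1 denominator) of the n squared elements.
#'
#' @param panel a [genotype_panel()].
#' @param n number of sampled pairs, `2 <= n <= N(N-1)/2`.
#' @param seed integer seed.
#' @param chunk pairs per vectorized block (memory knob).
#' @return A `trace_estimate`; `$ko` carries the sampled off-diagonals.
#' @export
trace_shotgun <- function(panel, n, seed = NULL, chunk = 4096L) {
  stopifnot(inherits(panel, "genotype_panel"))
  nn <- nrow(panel$genotypes)
  npairs <- nn * (nn - 1) / 2
  if (!is_count(n) || n < 2) stop_domain("n must be an integer >= 2")
  if (n > npairs)
    stop_domain("n = %d exceeds the N(N-1)/2 = %g lower-triangle pairs", n, npairs)
  xs <- standardize(panel)
  m <- ncol(xs)
  with_seed(seed, {
    ks <- sample.int(npairs, n)
    ij <- pair_from_index(ks)
    ko <- numeric(n)
    for (start in seq(1L, n, by = chunk)) {
      end <- min(start + chunk - 1L, n)
      sel <- start:end
      ko[sel] <- rowSums(xs[ij[sel, 1L], , drop = FALSE] *
                           xs[ij[sel, 2L], , drop = FALSE]) / m
    }
    value <- nn + nn^2 * mean(ko^2)
    new_trace_estimate(value, "shotgun", list(n = n),
                       var_estimate = nn^4 * sample_var(ko^2) / n,
                       seed = seed, extra = list(ko = ko, pairs = ij))
  })
}
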