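---
title: "Subsampling trace estimators for Haseman-Elston heritability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subsampling trace estimators for Haseman-Elston heritability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hetrace)
```

## The problem

Method-of-moments (Haseman-Elston, HE) SNP heritability estimation solves
the 2x2 normal equations

$$
\begin{pmatrix} \mathrm{tr}(K'K) & \mathrm{tr}(K) \\ \mathrm{tr}(K) & N \end{pmatrix}
\begin{pmatrix} \hat h^2 \\ \hat\sigma_e^2 \end{pmatrix}
=
\begin{pmatrix} y'Ky \\ y'y \end{pmatrix},
$$

where $K = \tilde X \tilde X'/M$ is the genetic relationship matrix (GRM)
over $N$ individuals and $M$ SNPs, with genotypes standardized to
$\tilde x = (x - 2p)/\sqrt{2pq}$. Both sides are a computational problem at
biobank scale: $y'Ky$ costs $O(NM)$ once written as
$\frac{1}{M}\sum_l (\tilde x_l' y)^2$ — a sum of marginal association
statistics — but $\mathrm{tr}(K'K) = \sum_{ij} K_{ij}^2$ naively costs
$O(N^2 M)$.

The way out is the **effective number of markers**,
$M_e = 1/\mathrm{var}(K_o)$, the reciprocal dispersion of the GRM
off-diagonal. For unrelated samples

$$\mathrm{tr}(K'K) = N^2/M_e + N,$$

so the whole trace is one genome-wide LD summary, estimable from a small
subsample of individual pairs. The heritability estimator then *synthesizes*
GWAS summary statistics with a subsampled $M_e$:

$$\hat h^2 = \frac{N\,\overline{\chi^2} - N}{N^2/\hat M_e}
          = \hat M_e\,(\overline{\chi^2} - 1)/N .$$

## The three trace estimators at matched cost

All three cost $O(NMB)$ and never materialize $K$:

* **Randomized, `trace_randomized()`** ($L_B$): Gaussian probes $z_b$,
  $L_B = \frac{1}{B}\sum_b \|\tilde X(\tilde X' z_b)\|^2/M^2$. Its correct
  sampling variance is $2\,\mathrm{tr}(K^4)/B$ — proportional to the
  *fourth*-order trace, not $2\,\mathrm{tr}(K'K)/B$. The package's
  `var_estimate` is the empirical variance of the mean (sample variance of
  the $B$ draws divided by $B$): an earlier convention divided the sum of
  squared deviations by $B$ only, which estimates the single-draw variance
  instead.
* **Block, `trace_block()`** ($L_S$): draw $s = \lfloor\sqrt{2BN}\rfloor$
  individuals, compute all $s(s-1)/2$ off-diagonals, set
  $L_S = N^2/\hat M_e + N$. No analytic variance is available (block pairs
  share individuals); a within-block bootstrap is offered behind a flag.
  `floor` rather than `round` is used so the matched budget is never
  exceeded (both give $s = 7$ in the $N=14$, $B=2$ worked example).
* **Shotgun, `trace_shotgun()`** ($L_T$): sample $n = BN$ distinct
  lower-triangle elements uniformly without replacement (0-based row-major
  linear indexing of pairs $i > j$, mapped back in $O(1)$), each an $O(M)$
  dot product:
  $L_T = N + \frac{N^2}{n}\sum_i K^2_{o,A_i}$, with analytic sampling
  variance $N^4\,\mathrm{var}(K_o^2)/n$, estimated from the same draw with
  the $n-1$ denominator.

At matched cost the empirical ordering is
$\mathrm{var}(L_T) \le \mathrm{var}(L_S) < \mathrm{var}(L_B)$: shotgun
pairs share fewer individuals than block pairs, and the Gaussian-probe
variance carries the heavy $\mathrm{tr}(K^4)$ factor, which LD inflates by
an order of magnitude relative to $\mathrm{tr}(K'K)$.

## Heritability, its variance, and partitioning

`h2_synthesized()` implements the summary-statistic route with variance

$$\hat\sigma^2_{h} = \frac{2\hat M_e}{N^2}
  + \frac{\hat M_e^2\,\sigma^2_{K_o^2}}{n}\,(\hat h^2)^2 ,$$

whose first term is the null-variance floor (equal to the REML asymptotic
variance) and whose second term propagates the $M_e$-subsampling noise via
the delta method; the second term divides by $n$, the pair count behind
$\hat M_e$, which is what the delta method yields from
$\mathrm{var}(L_T) = N^4\mathrm{var}(K_o^2)/n$ (a $2n$ reading of the
typeset formula is not supported by that propagation). Estimates are *not*
clamped to $[0,1]$: a method-of-moments null is centered at zero and goes
negative about half the time, which the tests assert.

`partition_single()` applies the same estimator per chromosome with each
chromosome's own $N_c$ and $\hat M_{e.c}$; `partition_joint()` solves the
$(C+1)$-dimensional moment system whose matrix has diagonal
$N^2/M_{e.c} + N$ and all other entries $N$ (cross-chromosome LD treated
as zero, so cross traces reduce to the diagonal contribution $N$). Under a
common $N$ this matrix has a closed-form inverse — chromosome diagonal
$M_{e.c}/N^2$, zero off-diagonals among chromosomes, last column
$-M_{e.c}/N^2$ — which makes joint and single estimates *identical*; the
package solves numerically (a 23x23 solve is trivial) and verifies the
analytic inverse as a property, since the last diagonal entry of the
inverse is not part of the published closed form. With unequal $N_c$ the
closed form breaks down, so the joint routine warns and falls back to
single-mode estimation, flagging the output.

The **polygenicity diagnostic** compares whole-genome and summed
chromosome-wise heritability. The genome-wide $M_e$ is diluted by the
"blank LD" of cross-chromosome pairs, so
$M_e \le \sum_c M_{e.c}$, with a material gap only when chromosomes differ
in LD per marker (Cauchy-Schwarz: equality when $M_c \propto M_{e.c}$).
A purely polygenic trait sits on the line with slope
$M_e/\sum_c M_{e.c}$ (`polygenicity_ratio()`); architectures concentrated
in a strong-LD region (the MHC situation) push
$\hat h^2_{gen}/\hat h^2_{chr}$ above it.

## The synthetic world

`simulate_genotypes()` draws per-locus target frequencies
$p_l \sim U(0.03, 0.5)$ and builds two independent haplotypes per
individual by a first-order Markov chain along each chromosome. For
adjacent loci, Lewontin's $D' \sim U(d_{lo}, d_{hi})$ is realized through
the positive-$D$ convention $D = D'\min(p_1(1-p_2),(1-p_1)p_2)$ and the
transitions $P(1\mid 1) = p_2 + D/p_1$, $P(1\mid 0) = p_2 - D/(1-p_1)$,
which are within $[0,1]$ by construction, so no clipping is triggered in
practice (it exists defensively). LD therefore decays geometrically with
marker distance — "weak" ($D' \in [0, 0.2]$) and "strong"
($D' \in [0.6, 0.8]$, the default) LD are local properties — and is exactly
zero across chromosomes, which are independent blocks. The generation
mechanism itself is this package's choice; the validated quantities are
the MAF and $D'$ ranges and the phenotype model.

`simulate_phenotype()` draws $\beta_l \sim N(0, h^2/M)$,
$e \sim N(0, 1-h^2)$, returns standardized
$y = \tilde X\beta + e$; the optional `causal` argument confines effects
to a marker subset (used to break polygenicity deliberately). All
randomness flows from one integer seed per call; the local RNG state is
restored afterwards.

What the generator does **not** emulate: demographic structure,
relatedness, genotyping error and missingness patterns, dosage
uncertainty, allele-frequency/LD coupling, or long-range LD. A green test
therefore establishes correctness of the estimators under
Hardy-Weinberg-sampled unrelated genotypes with first-order local LD, not
robustness to cohort pathology.

## Numerical and interface choices

* Per-SNP association statistics use the score form
  $\chi^2_l = (\tilde x_l'\tilde y)^2/n_l$ with $\tilde y$ residualized
  (intercept and optional covariates, Frisch-Waugh on both sides) and
  rescaled to $\|\tilde y\|^2 = N$. This keeps the identity
  $N\overline{\chi^2} = y'Ky$ *exact*, which the synthesized estimator
  relies on; it differs from $n\,r^2$ (Pearson) by the ratio of the
  marker's realized variance to its Hardy-Weinberg value $2pq$, an
  $O(N^{-1/2})$ per-SNP wobble.
* $M_e$ uses the mean-subtracted $\mathrm{var}(K_o)$ per its definition,
  while $L_T$ uses the raw mean of squares; the difference is
  $E(K_o)^2 = 1/(N-1)^2$, negligible against $1/M_e$ for $N \ge 100$, and
  identity tests carry a 2% tolerance accordingly.
* Allele frequencies are always estimated from the analysis sample;
  missing genotypes are mean-imputed at standardization time, so columns
  stay exactly centered, and per-SNP complete-case counts are kept for the
  summary statistics.
* Dense-GRM code paths (`build_grm()`, `exact_traces()`) are oracles for
  testing and small-$N$ work; they refuse $N$ above a configurable cap
  (default 20,000) because the production paths never materialize $K$.
* MAF filtering is strictly greater-than (`maf > maf_min`), matching the
  "MAF > 0.01" convention; excluded regions are 1-based inclusive
  `chr:start-end`.

## Two calibration caveats the tests encode

**The heritability variance formula is a per-trait standard error.** Its
first term evaluates the variance of $\overline{\chi^2}$ at the null
(every $\chi^2$ central). Replicating complete traits — redrawing $\beta$
each time — adds the non-centrality inflation of $\mathrm{var}(\chi^2)$,
which is substantial when $h^2$ is large and $N/M_e$ is small: at
$N = M = 2000$ and $h^2 = 0.5$ the formula covers only ~1/3 (strong LD) to
~1/2 (weak LD) of that fully-marginal variance, while for a *fixed* trait
architecture with environmental noise and the $M_e$ subsample replicated —
the uncertainty a reported `h2_se` describes — it is within ~30%. The
acceptance suite calibrates the conditional reading; at biobank scale
($N/M_e \approx 3$, moderate $h^2$) the omitted term is a ~10% effect.

**The polygenicity slope is compared with per-trait error bars.** In an
LD-homogeneous genome the replicate-to-replicate noise of
$\hat h^2_{gen}/\hat h^2_{chr}$ largely cancels (both numerator and
denominator are built from the same per-chromosome quadratic forms), so
the Monte-Carlo mean of the ratio is orders of magnitude more precise than
any single trait, and a finite-sample offset of ~0.2% of the slope
survives. The tests therefore assert that traits sit on the line within
three per-trait standard deviations — the error-bar semantics of the
diagnostic plot — rather than within three SEs of the Monte-Carlo mean.

## Known limitations

* Only additive, single-trait heritability on unrelated samples: no
  dominance coding, no bi-trait genetic correlation, no REML, and no
  special handling of related individuals (relatedness shrinks $M_e$ and
  breaks the closed-form trace).
* The block estimator ships without an analytic variance (only the
  bootstrap), mirroring the state of the theory.
* `read_plink()` supports hard-call bed/bim/fam only — no VCF/BGEN or
  dosages.
* PCA for covariate construction is out of scope; principal components
  are accepted as a user-supplied covariate table.
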