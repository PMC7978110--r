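# Shared simulated panels, built once per test run and memoized.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures))
    assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# independent markers (D' = 0)
panel_indep <- function() fixture("indep", function()
  simulate_genotypes(sim_config(300, 500, dprime_range = c(0, 0),
                                seed = 101)))

# strong adjacent LD
panel_ld <- function() fixture("ld", function()
  simulate_genotypes(sim_config(300, 500, dprime_range = c(0.6, 0.8),
                                seed = 102)))

# weak LD, larger M, for chi-square calibration
panel_null <- function() fixture("null", function()
  simulate_genotypes(sim_config(500, 2000, dprime_range = c(0, 0.2),
                                seed = 103)))

# two chromosomes
panel_2chr <- function() fixture("2chr", function()
  simulate_genotypes(sim_config(300, 400, dprime_range = c(0.6, 0.8),
                                chromosome_sizes = c(250, 150), seed = 104)))

# two chromosomes with heterogeneous LD (weak vs strong): the regime where
# cross-chromosome "blank LD" dilution of the genome-wide Me is material
panel_het <- function() fixture("het", function() {
  weak <- simulate_genotypes(sim_config(300, 200, dprime_range = c(0, 0.2),
                                        seed = 105))
  strong <- simulate_genotypes(sim_config(300, 200,
                                          dprime_range = c(0.85, 0.98),
                                          seed = 106))
  strong$chromosomes <- rep("2", 200)
  bind_panels(weak, strong)
})

grm_of <- function(panel, key) fixture(paste0("grm_", key), function()
  build_grm(panel))

# Lewontin's D' between two 0/1 haplotype vectors (stacked over the two
# haplotypes per individual): brute-force from the 2x2 haplotype table.
dprime_oracle <- function(a1, a2) {
  p1 <- mean(a1); p2 <- mean(a2)
  d <- mean(a1 * a2) - p1 * p2
  dmax <- if (d >= 0) min(p1 * (1 - p2), (1 - p1) * p2)
  else min(p1 * p2, (1 - p1) * (1 - p2))
  if (dmax == 0) return(NA_real_)
  d / dmax
}

# mean realized adjacent-pair D' from a panel simulated with
# keep_haplotypes = TRUE; skips cross-chromosome boundaries
mean_adjacent_dprime <- function(panel) {
  h <- attr(panel, "haplotypes")
  stopifnot(!is.null(h))
  hap <- rbind(h$h1, h$h2)
  chr <- panel$chromosomes
  m <- ncol(hap)
  vals <- vapply(seq_len(m - 1L), function(l) {
    if (chr[l] != chr[l + 1L]) return(NA_real_)
    dprime_oracle(hap[, l], hap[, l + 1L])
  }, numeric(1))
  mean(vals, na.rm = TRUE)
}
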