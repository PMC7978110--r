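#' @keywords internal
"_PACKAGE"

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
# All stochastic operations in the package funnel through here so that a
# single integer seed makes a whole analysis reproducible.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a parent seed, kept inside the 32-bit integer
# range. Used to give independent sub-streams to independent steps.
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 7919 + offset) %% .Machine$integer.max)
}

stop_domain <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

# Sample variance with the n-1 denominator; errors out on length < 2.
sample_var <- function(x) {
  if (length(x) < 2L) stop_domain("need at least 2 values to estimate a variance")
  stats::var(x)
}
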