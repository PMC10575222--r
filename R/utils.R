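#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom stats rnorm runif setNames
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. All stochastic draws in the package
# flow through this so that results are bit-reproducible.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort("`seed` must be a single finite number.")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stream-specific child seed from a user seed; keeps independent
# randomisation for e.g. splitting vs. weight init without seed collisions.
# Result stays inside the 32-bit integer range.
child_seed <- function(seed, stream) {
  (as.double(seed) * 7919 + stream * 104729) %% 2147483647
}

# Split n into integer counts proportional to `fracs` (largest remainder,
# ties to the earlier index). sum(result) == round(sum(fracs) * n) when the
# fractions sum to 1; used for stratified partitioning.
largest_remainder <- function(n, fracs) {
  raw <- n * fracs
  base <- floor(raw)
  short <- round(sum(raw)) - sum(base)
  if (short > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
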