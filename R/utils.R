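#' @useDynLib apodetect, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif quantile sd median cor rpois setNames
#' @importFrom utils read.csv write.csv head tail
NULL

# Round half away from zero. R's round() uses banker's rounding, which would
# send 4.5 to 4; uniform index subsampling requires the conventional rule.
round_half_up <- function(x) floor(x + 0.5)

# n uniformly spaced values from a to b inclusive.
lin_space <- function(a, b, n) {
  if (n == 1L) return((a + b) / 2)
  a + (b - a) * (seq_len(n) - 1) / (n - 1)
}

# Uniform index subsampling used by the data loader and the detection window:
# pick k indices over 1..n, always including the first and last when n >= 2.
uniform_indices <- function(n, k) {
  if (n <= 0L) stop("empty input")
  if (n == 1L) return(rep(1L, k))
  as.integer(round_half_up(lin_space(1, n, k)))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Derive a child RNG seed from a parent seed and a stream index, staying
# within the 32-bit integer range.
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 7919 + stream * 104729) %% 2147483647)
}

# Evaluate expr with a temporary RNG state seeded by `seed`, restoring the
# caller's RNG state afterwards. All package randomness flows through this.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
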