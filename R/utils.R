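# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so package functions never perturb
# the session RNG stream.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Centered moving average with shrinking edge windows (width w, odd).
moving_average <- function(x, w) {
  n <- length(x)
  if (w <= 1L || n == 0L) return(x)
  k <- (w - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(0L, i - k - 1L)
  hi <- pmin(n, i + k)
  (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_cima <- function(...) stop(sprintf(...), call. = FALSE)

# Unordered channel pairs in fixed column-major order (i < j), shared by the
# feature extractor and the manifest so covariation columns always align.
channel_pairs <- function() {
  p <- combn(N_CHANNELS, 2L)
  data.frame(i = p[1L, ], j = p[2L, ])
}
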