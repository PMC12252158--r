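# Small internal helpers.

# Evaluate expr with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Cubic smoothstep on [0, 1].
smoothstep <- function(u) {
  u <- clamp(u, 0, 1)
  3 * u^2 - 2 * u^3
}

#' Dominant period of a series by autocorrelation
#'
#' Lag (in samples) of the first positive local peak of the
#' autocorrelation function -- the dominant period of a roughly periodic
#' series such as the walking aspect-ratio signal.  (The global ACF
#' argmax is biased toward lag 1 for short noisy sinusoids, so the first
#' local peak is used; if none exists the argmax is returned.)
#'
#' @param x Numeric series.
#' @param max_lag Largest lag considered (default `floor(length(x)/2)`).
#' @return Integer lag of the first autocorrelation peak.
#' @export
dominant_period <- function(x, max_lag = floor(length(x) / 2)) {
  stopifnot(length(x) >= 4)
  ac <- stats::acf(x, lag.max = max_lag, plot = FALSE, demean = TRUE)$acf[-1]
  for (k in seq(2, length(ac) - 1)) {
    if (ac[k] > 0 && ac[k] > ac[k - 1] && ac[k] >= ac[k + 1]) {
      return(k)
    }
  }
  which.max(ac)
}
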