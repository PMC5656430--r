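# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Wrap angles into [-pi, pi).
wrap_angle <- function(theta) {
  ((theta + pi) %% (2 * pi)) - pi
}

# Low-pass Gaussian series: white noise smoothed to approximately the given
# bandwidth (Hz) by zeroing Fourier components above it, rescaled to unit sd.
lowpass_series <- function(n, fs, bandwidth_hz) {
  if (n < 2L) return(numeric(n))
  x <- stats::rnorm(n)
  f <- (seq_len(n) - 1L) / n * fs
  f <- pmin(f, fs - f)                     # two-sided frequency axis
  keep <- f <= bandwidth_hz
  if (!any(keep[-1L])) keep[2L] <- keep[n] <- TRUE
  z <- stats::fft(x)
  z[!keep] <- 0
  y <- Re(stats::fft(z, inverse = TRUE)) / n
  s <- stats::sd(y)
  if (s > 0) y <- y / s
  y - mean(y)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(..., call. = FALSE)
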