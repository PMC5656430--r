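#' Multitaper coherence analysis
#'
#' A cell is scored against a behavioral reference (the stimulus train for
#' local bending, the optical signal of a reference motor neuron for
#' swimming, an intracellular electrode signal for crawling) by the magnitude
#' and phase of their multitaper coherence at the rhythm frequency, compared
#' with an analytic null threshold: under the null hypothesis of no coherence
#' the squared coherence magnitude estimated with K orthonormal tapers
#' satisfies \eqn{P(|C|^2 > x) = (1 - x)^{K-1}}, so the magnitude bound
#' exceeded with probability alpha is \eqn{\sqrt{1 - \alpha^{1/(K-1)}}}.
#'
#' @name spectral
NULL

.dpss_cache <- new.env(parent = emptyenv())

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computed as the top eigenvectors of the standard symmetric tridiagonal
#' commuting matrix, orthonormal by construction; results are cached per
#' (n, nw, k).
#'
#' @param n series length, samples.
#' @param nw time-bandwidth product (default 3).
#' @param k number of tapers (default 5); requires \code{k < 2 * nw}.
#' @return \code{n x k} matrix of tapers, most concentrated first, each with
#'   unit energy; symmetric tapers are sign-fixed to positive mean.
#' @export
dpss_tapers <- function(n, nw = 3, k = 5) {
  if (k < 1 || k >= 2 * nw) stop_input("need 1 <= k < 2 * nw tapers")
  if (n < 2 * k) stop_input("series too short for ", k, " tapers")
  key <- sprintf("%d_%g_%d", n, nw, k)
  if (!is.null(.dpss_cache[[key]])) return(.dpss_cache[[key]])
  w <- nw / n
  tt <- 0:(n - 1)
  dg <- ((n - 1 - 2 * tt) / 2)^2 * cos(2 * pi * w)
  od <- tt[-1] * (n - tt[-1]) / 2
  m <- diag(dg)
  m[cbind(2:n, 1:(n - 1))] <- od
  m[cbind(1:(n - 1), 2:n)] <- od
  v <- eigen(m, symmetric = TRUE)$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    s <- sum(v[, j])
    if (abs(s) > 1e-8) {                 # symmetric taper: positive mean
      if (s < 0) v[, j] <- -v[, j]
    } else if (v[2, j] - v[1, j] < 0) {  # antisymmetric: positive initial slope
      v[, j] <- -v[, j]
    }
  }
  .dpss_cache[[key]] <- v
  v
}

# K tapered DFT coefficients of x at frequency f (Hz); x is demeaned first.
tapered_dft <- function(x, fs, f, tapers) {
  x <- x - mean(x)
  n <- length(x)
  e <- exp(-2i * pi * f / fs * (0:(n - 1)))
  crossprod(tapers, x * e)[, 1]
}

#' Multitaper power spectrum
#'
#' @param x numeric series.
#' @param fs sampling rate, Hz.
#' @param nw,k multitaper parameters.
#' @return data frame \code{frequency_hz}, \code{power} on the FFT grid up to
#'   the Nyquist frequency.
#' @export
mt_spectrum <- function(x, fs, nw = 3, k = 5) {
  n <- length(x)
  v <- dpss_tapers(n, nw, k)
  x <- x - mean(x)
  pw <- rowMeans(vapply(seq_len(k), function(j) {
    Mod(stats::fft(v[, j] * x))^2
  }, numeric(n)))
  nf <- n %/% 2 + 1L
  data.frame(frequency_hz = (seq_len(nf) - 1L) / n * fs,
             power = pw[seq_len(nf)])
}

#' Pick the rhythm frequency of a reference signal
#'
#' Returns the frequency with the greatest multitaper spectral power within a
#' band.
#'
#' @param reference numeric series.
#' @param fs sampling rate, Hz.
#' @param band_hz c(lo, hi) search band; must lie within (0, Nyquist].
#' @param nw,k multitaper parameters.
#' @return frequency in Hz (on the FFT grid).
#' @export
pick_rhythm_frequency <- function(reference, fs, band_hz, nw = 3, k = 5) {
  if (length(band_hz) != 2 || band_hz[1] >= band_hz[2]) {
    stop_input("band_hz must be c(lo, hi) with lo < hi")
  }
  if (band_hz[2] > fs / 2 + 1e-9) stop_input("band exceeds the Nyquist frequency")
  sp <- mt_spectrum(reference, fs, nw, k)
  sel <- sp$frequency_hz >= band_hz[1] & sp$frequency_hz <= band_hz[2]
  if (!any(sel)) stop_input("no spectral bins inside the band")
  sp$frequency_hz[sel][which.max(sp$power[sel])]
}

#' Null-hypothesis coherence magnitude bound
#'
#' Magnitude that independent signals exceed with probability \code{alpha}
#' when coherence is estimated with \code{k} tapers:
#' \code{sqrt(1 - alpha^(1/(k - 1)))}.
#'
#' @param k_tapers number of tapers (>= 2).
#' @param alpha exceedance probability in (0, 1).
#' @return magnitude threshold in [0, 1].
#' @export
null_threshold <- function(k_tapers, alpha = 0.05) {
  if (any(k_tapers < 2)) stop_input("k_tapers must be >= 2")
  if (any(alpha <= 0 | alpha >= 1)) stop_input("alpha must be in (0, 1)")
  sqrt(1 - alpha^(1 / (k_tapers - 1)))
}

#' Multitaper coherence of a trace with a reference at one frequency
#'
#' Magnitude and phase from Slepian-tapered cross- and auto-spectra evaluated
#' at the requested frequency (direct DFT, so the frequency need not lie on
#' the FFT grid). Positive phase means the trace leads the reference. The
#' magnitude confidence interval is a leave-one-taper-out jackknife on the
#' arctanh scale.
#'
#' @param trace,reference equal-length numeric series.
#' @param fs sampling rate, Hz.
#' @param frequency evaluation frequency, Hz.
#' @param nw,k multitaper parameters (k >= 2).
#' @param alpha null-threshold level.
#' @return list with \code{magnitude}, \code{phase_rad}, \code{frequency_hz},
#'   \code{magnitude_ci} (95\% jackknife), \code{null_threshold},
#'   \code{involved}, \code{k}, \code{nw}.
#' @export
mt_coherence <- function(trace, reference, fs, frequency, nw = 3, k = 5,
                         alpha = 0.05) {
  if (length(trace) != length(reference)) {
    stop_input("trace and reference lengths differ")
  }
  if (k < 2) stop_input("k must be >= 2")
  v <- dpss_tapers(length(trace), nw, k)
  xx <- tapered_dft(trace, fs, frequency, v)
  yy <- tapered_dft(reference, fs, frequency, v)
  cross <- sum(xx * Conj(yy))
  denom <- sqrt(sum(Mod(xx)^2) * sum(Mod(yy)^2))
  mag <- if (denom > 0) Mod(cross) / denom else 0
  phase <- if (denom > 0) Arg(cross) else 0
  # jackknife over tapers on the arctanh scale
  mj <- vapply(seq_len(k), function(j) {
    cr <- sum(xx[-j] * Conj(yy[-j]))
    dn <- sqrt(sum(Mod(xx[-j])^2) * sum(Mod(yy[-j])^2))
    if (dn > 0) Mod(cr) / dn else 0
  }, numeric(1))
  zj <- atanh(pmin(mj, 1 - 1e-12))
  se <- sqrt((k - 1) / k * sum((zj - mean(zj))^2))
  tq <- stats::qt(0.975, df = k - 1)
  ci <- tanh(atanh(min(mag, 1 - 1e-12)) + c(-1, 1) * tq * se)
  thr <- null_threshold(k, alpha)
  list(magnitude = mag, phase_rad = wrap_angle(phase),
       frequency_hz = frequency,
       magnitude_ci = pmax(pmin(ci, 1), 0),
       null_threshold = thr, involved = mag > thr, k = k, nw = nw)
}

#' Coherence of every cell in a trace set against a reference
#'
#' @param ts a \code{trace_set} (typically dF/F).
#' @param reference reference series, same length and rate as the traces, or
#'   a cell id present in \code{ts} (that cell's own trace is used, phase 0
#'   by construction).
#' @param frequency evaluation frequency, Hz; if \code{NULL}, picked from the
#'   reference within \code{band_hz}.
#' @param band_hz search band for the rhythm frequency.
#' @param nw,k,alpha see \code{\link{mt_coherence}}.
#' @return A \code{coherence_result} data frame: \code{cell_id},
#'   \code{frequency_hz}, \code{magnitude}, \code{phase_rad},
#'   \code{ci_lo}, \code{ci_hi}, \code{null_threshold}, \code{involved}.
#' @export
coherence_map <- function(ts, reference, frequency = NULL,
                          band_hz = c(0.05, 5), nw = 3, k = 5, alpha = 0.05) {
  if (is.character(reference)) {
    if (!reference %in% ts$ids) stop_input("reference cell not in trace set")
    reference <- ts$values[, reference]
  }
  if (length(reference) != nrow(ts$values)) {
    stop_input("reference length does not match the traces")
  }
  if (is.null(frequency)) {
    frequency <- pick_rhythm_frequency(reference, ts$frame_rate_hz, band_hz,
                                       nw, k)
  }
  res <- lapply(seq_along(ts$ids), function(j) {
    co <- mt_coherence(ts$values[, j], reference, ts$frame_rate_hz,
                       frequency, nw, k, alpha)
    data.frame(cell_id = ts$ids[j], frequency_hz = co$frequency_hz,
               magnitude = co$magnitude, phase_rad = co$phase_rad,
               ci_lo = co$magnitude_ci[1], ci_hi = co$magnitude_ci[2],
               null_threshold = co$null_threshold, involved = co$involved,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  structure(out, class = c("coherence_result", "data.frame"))
}

#' Expected multitaper coherence of a sinusoid in white noise
#'
#' Analytic approximation used as generator ground truth: for a trace
#' \code{A sin(2 pi f t + phi) + noise} scored against a noiseless reference
#' at the same frequency, the expected coherence magnitude is
#' \code{sqrt(C / (C + K sigma^2))} with \code{C = A^2 / 4 * sum_k s_k^2},
#' where \code{s_k} is the sum of the k-th taper (only symmetric tapers
#' contribute).
#'
#' @param amplitude_mv sinusoid amplitude A.
#' @param noise_sd_mv white noise sd sigma.
#' @param n,fs series length and rate.
#' @param nw,k multitaper parameters.
#' @return expected coherence magnitude in [0, 1].
#' @export
expected_coherence <- function(amplitude_mv, noise_sd_mv, n, fs,
                               nw = 3, k = 5) {
  if (amplitude_mv <= 0) return(0)
  if (noise_sd_mv <= 0) return(1)
  v <- dpss_tapers(n, nw, k)
  cc <- amplitude_mv^2 / 4 * sum(colSums(v)^2)
  sqrt(cc / (cc + k * noise_sd_mv^2))
}

#' Monte-Carlo null coherence magnitudes
#'
#' Simulates pairs of independent Gaussian white-noise series and returns the
#' multitaper coherence magnitude of each pair at one frequency. Used to
#' calibrate \code{\link{null_threshold}}: the fraction of magnitudes below
#' \code{null_threshold(k, alpha)} should be \code{1 - alpha}.
#'
#' @param nrep number of replicate pairs.
#' @param n series length, samples.
#' @param fs sampling rate, Hz.
#' @param frequency evaluation frequency, Hz.
#' @param nw,k multitaper parameters.
#' @param seed RNG seed.
#' @return numeric vector of \code{nrep} coherence magnitudes.
#' @export
simulate_null_coherence <- function(nrep, n = 750, fs = 50, frequency = 1.5,
                                    nw = 3, k = 5, seed = NULL) {
  v <- dpss_tapers(n, nw, k)
  w <- v * exp(-2i * pi * frequency / fs * (0:(n - 1)))   # n x k weights
  with_seed(seed, {
    out <- numeric(nrep)
    block <- 2000L
    done <- 0L
    while (done < nrep) {
      b <- min(block, nrep - done)
      x <- matrix(stats::rnorm(n * b), n, b)
      y <- matrix(stats::rnorm(n * b), n, b)
      xx <- crossprod(w, x)              # k x b, tapered DFTs
      yy <- crossprod(w, y)
      num <- Mod(colSums(xx * Conj(yy)))
      den <- sqrt(colSums(Mod(xx)^2) * colSums(Mod(yy)^2))
      out[(done + 1L):(done + b)] <- num / den
      done <- done + b
    }
    out
  })
}

#' Write a coherence map as CSV
#' @param cm a \code{coherence_result}.
#' @param path file path.
#' @export
write_coherence <- function(cm, path) {
  utils::write.csv(as.data.frame(cm), path, row.names = FALSE)
  invisible(path)
}
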