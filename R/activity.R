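#' Per-neuron membrane-potential program
#'
#' Assigns each neuron of a canonical map the parameters of its simulated
#' membrane-potential trace: a resting baseline, behavior-locked terms
#' (sinusoidal oscillation for swimming and crawling, boxcar left/right
#' responses for local bending), a sparse spike train, unitary EPSPs of
#' 2-4 mV, and white membrane noise.
#'
#' A fraction \code{involved_fraction} of cells receives a nonzero
#' behavior-locked term; for local bending, half of the responsive cells are
#' differential (distinct L and R responses) and the rest respond equally to
#' both sides. Oscillation frequencies default to 1.5 Hz (swim) and 0.1 Hz
#' (crawl), typical fictive rhythm rates.
#'
#' @param map a \code{canonical_map}.
#' @param seed RNG seed.
#' @param involved_fraction fraction of cells with a behavior-locked term.
#' @param swim_freq_hz,crawl_freq_hz rhythm frequencies, Hz.
#' @param osc_amp_range oscillation amplitude range, mV.
#' @param bend_amp_range stimulus response amplitude range, mV.
#' @param noise_sd_mv membrane noise standard deviation, mV.
#' @param epsp_rate_hz,spike_rate_hz event rates, Hz.
#' @return An \code{activity_program} data frame, one row per neuron.
#' @export
activity_program <- function(map, seed = 1L, involved_fraction = 0.6,
                             swim_freq_hz = 1.5, crawl_freq_hz = 0.1,
                             osc_amp_range = c(4, 8),
                             bend_amp_range = c(2, 6),
                             noise_sd_mv = 1.0,
                             epsp_rate_hz = 0.5, spike_rate_hz = 0.2) {
  n <- nrow(map)
  with_seed(seed, {
    involved <- stats::runif(n) < involved_fraction
    amp <- ifelse(involved, stats::runif(n, osc_amp_range[1], osc_amp_range[2]), 0)
    bend_resp <- ifelse(involved, stats::runif(n, bend_amp_range[1], bend_amp_range[2]), 0)
    differential <- involved & (stats::runif(n) < 0.5)
    side <- stats::runif(n) < 0.5
    bl <- ifelse(differential, ifelse(side, bend_resp, 0.25 * bend_resp), bend_resp)
    br <- ifelse(differential, ifelse(side, 0.25 * bend_resp, bend_resp), bend_resp)
    out <- data.frame(
      id = map$id,
      baseline_mv = -50,
      swim_amp_mv = amp, swim_freq_hz = swim_freq_hz,
      swim_phase_rad = stats::runif(n, -pi, pi),
      crawl_amp_mv = amp, crawl_freq_hz = crawl_freq_hz,
      crawl_phase_rad = stats::runif(n, -pi, pi),
      bend_left_mv = bl, bend_right_mv = br,
      spike_rate_hz = spike_rate_hz,
      spike_amp_mv = stats::runif(n, 5, 10),
      spike_width_s = 0.01,
      epsp_rate_hz = epsp_rate_hz,
      epsp_amp_mv = stats::runif(n, 2, 4),
      epsp_decay_s = 0.1,
      noise_sd_mv = noise_sd_mv,
      stringsAsFactors = FALSE)
  })
  validate_activity_program(out)
  structure(out, class = c("activity_program", "data.frame"))
}

validate_activity_program <- function(p) {
  amps <- c("swim_amp_mv", "crawl_amp_mv", "bend_left_mv", "bend_right_mv",
            "spike_amp_mv", "epsp_amp_mv", "noise_sd_mv")
  for (a in amps) if (any(p[[a]] < 0)) stop_input(a, " must be >= 0")
  for (f in c("swim_freq_hz", "crawl_freq_hz")) {
    if (any(p[[f]] <= 0)) stop_input(f, " must be > 0")
  }
  for (ph in c("swim_phase_rad", "crawl_phase_rad")) {
    if (any(p[[ph]] < -pi | p[[ph]] >= pi)) stop_input(ph, " must lie in [-pi, pi)")
  }
  invisible(p)
}

#' Simulate per-cell membrane potential traces
#'
#' Builds each cell's voltage as baseline + behavior-locked term + spikes +
#' EPSPs + white noise, sampled directly at the frame rate. Spikes briefer
#' than one frame are represented by their frame-integrated area. Ground
#' truth for the downstream estimators (oscillation phase relative to the
#' reference cell, expected coherence magnitude, L-vs-R response difference)
#' is recorded in \code{$truth}.
#'
#' @param map a \code{canonical_map}.
#' @param program an \code{activity_program} (default one is generated from
#'   \code{seed}).
#' @param behavior one of "swim", "crawl", "bend".
#' @param protocol a \code{stim_protocol}; required iff \code{behavior ==
#'   "bend"}.
#' @param duration_s recording length, s (defaults: 15 s at 50 Hz for
#'   bend/swim, 50 s at 20 Hz for crawl; bend defaults to the protocol span).
#' @param rate_hz sampling rate, Hz; must suit the behavior (50 Hz for
#'   bend/swim, 20 Hz for crawl).
#' @param seed RNG seed.
#' @return A \code{voltage_sim}: list with \code{times} (s), \code{volt}
#'   (frames x cells matrix, mV), \code{map}, \code{program},
#'   \code{behavior}, \code{protocol}, \code{rate_hz} and \code{truth}.
#' @export
simulate_voltages <- function(map, program = NULL,
                              behavior = c("swim", "crawl", "bend"),
                              protocol = NULL, duration_s = NULL,
                              rate_hz = NULL, seed = 1L) {
  behavior <- match.arg(behavior)
  if (is.null(rate_hz)) rate_hz <- if (behavior == "crawl") 20 else 50
  expected_rate <- if (behavior == "crawl") 20 else 50
  if (rate_hz != expected_rate) {
    warning(sprintf("rate_hz = %g is unusual for %s (expected %g Hz)",
                    rate_hz, behavior, expected_rate))
  }
  if (behavior == "bend" && is.null(protocol)) {
    stop_input("`protocol` is required for behavior = \"bend\"")
  }
  if (is.null(program)) program <- activity_program(map, seed = seed)
  if (is.null(duration_s)) {
    duration_s <- if (behavior == "crawl") 50
    else if (behavior == "bend")
      max(protocol$onset_s + protocol$duration_s) + 1.5
    else 15
  }
  n <- round(duration_s * rate_hz)
  times <- (seq_len(n) - 1L) / rate_hz
  ncell <- nrow(map)

  with_seed(seed, {
    volt <- matrix(rep(program$baseline_mv, each = n), n, ncell)
    if (behavior %in% c("swim", "crawl")) {
      amp <- program[[paste0(behavior, "_amp_mv")]]
      frq <- program[[paste0(behavior, "_freq_hz")]]
      phs <- program[[paste0(behavior, "_phase_rad")]]
      for (j in seq_len(ncell)) {
        if (amp[j] > 0)
          volt[, j] <- volt[, j] + amp[j] * sin(2 * pi * frq[j] * times + phs[j])
      }
    } else {
      for (i in seq_len(nrow(protocol))) {
        idx <- times >= protocol$onset_s[i] &
               times < protocol$onset_s[i] + protocol$duration_s[i]
        resp <- if (protocol$label[i] == "L") program$bend_left_mv
                else program$bend_right_mv
        volt[idx, ] <- volt[idx, ] + rep(resp, each = sum(idx))
      }
    }
    dt <- 1 / rate_hz
    for (j in seq_len(ncell)) {
      volt[, j] <- volt[, j] +
        event_train(n, dt, program$spike_rate_hz[j],
                    program$spike_amp_mv[j] *
                      min(1, program$spike_width_s[j] / dt),
                    decay_s = NULL) +
        event_train(n, dt, program$epsp_rate_hz[j], program$epsp_amp_mv[j],
                    decay_s = program$epsp_decay_s[j])
      if (program$noise_sd_mv[j] > 0)
        volt[, j] <- volt[, j] + stats::rnorm(n, sd = program$noise_sd_mv[j])
    }
  })
  colnames(volt) <- map$id

  truth <- voltage_truth(map, program, behavior, n, rate_hz)
  structure(list(times = times, volt = volt, map = map, program = program,
                 behavior = behavior, protocol = protocol, rate_hz = rate_hz,
                 truth = truth),
            class = "voltage_sim")
}

# Poisson event train: impulses (decay_s = NULL) or exponentially decaying
# kernels of the given amplitude.
event_train <- function(n, dt, rate_hz, amp_mv, decay_s = NULL) {
  out <- numeric(n)
  if (rate_hz <= 0 || amp_mv <= 0) return(out)
  k <- stats::rpois(1, rate_hz * n * dt)
  if (k == 0) return(out)
  at <- sample.int(n, k, replace = TRUE)
  imp <- numeric(n)
  for (i in at) imp[i] <- imp[i] + amp_mv
  if (is.null(decay_s)) return(imp)
  a <- exp(-dt / decay_s)
  as.numeric(stats::filter(imp, a, method = "recursive"))
}

# Ground truth the downstream modules estimate.
voltage_truth <- function(map, program, behavior, n, rate_hz) {
  if (behavior %in% c("swim", "crawl")) {
    amp <- program[[paste0(behavior, "_amp_mv")]]
    phs <- program[[paste0(behavior, "_phase_rad")]]
    frq <- program[[paste0(behavior, "_freq_hz")]][1]
    involved <- amp > 0
    ref <- which(involved)[which.max(amp[involved])]
    coh <- vapply(seq_len(nrow(map)), function(j) {
      expected_coherence(amp[j], program$noise_sd_mv[j], n, rate_hz)
    }, numeric(1))
    list(behavior = behavior, involved = involved,
         rhythm_freq_hz = frq,
         reference_id = map$id[ref],
         phase_rel_ref = wrap_angle(phs - phs[ref]),
         osc_amp_mv = amp, noise_sd_mv = program$noise_sd_mv,
         coherence_magnitude = coh)
  } else {
    list(behavior = behavior,
         involved = (program$bend_left_mv + program$bend_right_mv) > 0,
         lr_difference_mv = program$bend_left_mv - program$bend_right_mv,
         noise_sd_mv = program$noise_sd_mv)
  }
}

#' @export
print.voltage_sim <- function(x, ...) {
  cat(sprintf("<voltage_sim> %s: %d cells x %d frames @ %g Hz (%.1f s)\n",
              x$behavior, ncol(x$volt), nrow(x$volt), x$rate_hz,
              nrow(x$volt) / x$rate_hz))
  invisible(x)
}
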