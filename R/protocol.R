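#' Left/right stimulus protocol for local bending trials
#'
#' Trials stimulate the left or right ventral pressure (P) cell with a train of
#' depolarizing pulses (20 Hz, 50\% duty cycle, 1 s). Labels follow the paired
#' order (LR)(RL)(LR)(RL)..., i.e. LRRLLRRL..., so every consecutive pair
#' contains one L and one R trial and class counts are balanced.
#'
#' @param n_trials even number of trials (default 20: 10 L + 10 R).
#' @param onset0_s onset of the first stimulus, s.
#' @param period_s spacing between consecutive onsets, s (default 2 s, a
#'   0.5 Hz train).
#' @param duration_s stimulus duration, s.
#' @param pulse_rate_hz,duty intra-stimulus pulse train parameters.
#' @return A \code{stim_protocol} data frame with columns \code{trial},
#'   \code{label}, \code{onset_s}, \code{duration_s}.
#' @examples
#' p <- stimulus_protocol(8)
#' paste(p$label, collapse = "")
#' @export
stimulus_protocol <- function(n_trials = 20L, onset0_s = 1.5, period_s = 2,
                              duration_s = 1, pulse_rate_hz = 20, duty = 0.5) {
  if (n_trials < 2 || n_trials %% 2 != 0) {
    stop_input("`n_trials` must be even and >= 2")
  }
  n_trials <- as.integer(n_trials)
  pair <- (seq_len(n_trials) + 1L) %/% 2L
  first <- seq_len(n_trials) %% 2L == 1L
  label <- ifelse(pair %% 2L == 1L,          # odd pairs are (L,R)
                  ifelse(first, "L", "R"),
                  ifelse(first, "R", "L"))
  out <- data.frame(trial = seq_len(n_trials), label = label,
                    onset_s = onset0_s + (seq_len(n_trials) - 1L) * period_s,
                    duration_s = duration_s, stringsAsFactors = FALSE)
  attr(out, "pulse_rate_hz") <- pulse_rate_hz
  attr(out, "duty") <- duty
  structure(out, class = c("stim_protocol", "data.frame"))
}

#' Stimulus train reference series
#'
#' Encodes a protocol as a binary on/off series at frame resolution, the
#' reference used for coherence analysis of local bending.
#'
#' @param protocol a \code{stim_protocol}.
#' @param times frame times, s.
#' @return numeric vector, 1 while any stimulus is on, else 0.
#' @export
protocol_reference <- function(protocol, times) {
  on <- numeric(length(times))
  for (i in seq_len(nrow(protocol))) {
    on[times >= protocol$onset_s[i] &
       times < protocol$onset_s[i] + protocol$duration_s[i]] <- 1
  }
  on
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat(sprintf("<stim_protocol> %d trials (%d L / %d R), onsets %.2f..%.2f s\n",
              nrow(x), sum(x$label == "L"), sum(x$label == "R"),
              min(x$onset_s), max(x$onset_s)))
  invisible(x)
}
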