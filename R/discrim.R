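#' Stimulus discriminability by partner-excluding leave-one-out decoding
#'
#' Each cell's ability to predict stimulus identity (left vs right P-cell) is
#' scored trial by trial: the held-out trial and its partner trial (the next
#' trial for odd trial numbers, the preceding one for even) are removed, the
#' mean response of each class is computed from the remaining trials, and the
#' held-out trial is predicted as the class whose mean is nearer. The success
#' fraction over trials is the prediction score; cells at or above 75\% are
#' encoders, 50\% being chance.
#'
#' @name discrim
NULL

#' Per-trial windowed responses
#'
#' For every cell and trial, the stimulus response is the mean dF/F over
#' [onset, onset + 0.5 s) and the control response the mean over
#' [onset - 1.0, onset - 0.5) s, both relative to the reference phase
#' [onset - 0.5, onset - 0.1) s.
#'
#' @param ts a \code{trace_set} (dF/F).
#' @param protocol a \code{stim_protocol}.
#' @param stim_window,control_window,reference_window offsets (s) relative to
#'   each onset.
#' @return data frame: \code{cell_id}, \code{trial}, \code{label},
#'   \code{stim_response}, \code{control_response}.
#' @export
window_responses <- function(ts, protocol,
                             stim_window = c(0, 0.5),
                             control_window = c(-1.0, -0.5),
                             reference_window = c(-0.5, -0.1)) {
  times <- (seq_len(nrow(ts$values)) - 1L) / ts$frame_rate_hz
  win_mean <- function(on, w) {
    sel <- times >= on + w[1] & times < on + w[2]
    if (!any(sel)) {
      stop_input("window [", on + w[1], ", ", on + w[2],
                 ") s contains no frames")
    }
    colMeans(ts$values[sel, , drop = FALSE])
  }
  res <- lapply(seq_len(nrow(protocol)), function(i) {
    on <- protocol$onset_s[i]
    ref <- win_mean(on, reference_window)
    data.frame(cell_id = ts$ids, trial = protocol$trial[i],
               label = protocol$label[i],
               stim_response = win_mean(on, stim_window) - ref,
               control_response = win_mean(on, control_window) - ref,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, res)
}

#' Partner trial index
#'
#' The partner of an odd-numbered trial is the next trial; of an
#' even-numbered trial, the preceding one. Partnership is an involution
#' pairing trials as (1,2), (3,4), ...
#'
#' @param trial_index 1-based trial number(s).
#' @param n_trials total number of trials (must be even).
#' @return partner index/indices.
#' @export
partner_index <- function(trial_index, n_trials) {
  if (n_trials %% 2 != 0) stop_input("n_trials must be even")
  if (any(trial_index < 1 | trial_index > n_trials)) {
    stop_input("trial_index out of range")
  }
  ifelse(trial_index %% 2 == 1, trial_index + 1L, trial_index - 1L)
}

#' Leave-one-out prediction success for one cell
#'
#' @param responses numeric responses in trial order.
#' @param labels "L"/"R" labels in trial order; classes must be balanced.
#' @param encoder_threshold success fraction defining an encoder (0.75).
#' @return list: \code{success_fraction}, \code{n_trials}, \code{n_correct},
#'   \code{encoder}. Held-out responses exactly equidistant from both class
#'   means are scored incorrect.
#' @export
loo_prediction_success <- function(responses, labels,
                                   encoder_threshold = 0.75) {
  n <- length(responses)
  if (length(labels) != n) stop_input("responses/labels length mismatch")
  if (sum(labels == "L") != sum(labels == "R")) {
    stop_input("unequal L/R class counts")
  }
  if (n %% 2 != 0 || n < 4) stop_input("need an even number (>= 4) of trials")
  correct <- 0L
  for (i in seq_len(n)) {
    keep <- setdiff(seq_len(n), c(i, partner_index(i, n)))
    m_l <- mean(responses[keep][labels[keep] == "L"])
    m_r <- mean(responses[keep][labels[keep] == "R"])
    d_l <- abs(responses[i] - m_l)
    d_r <- abs(responses[i] - m_r)
    pred <- if (d_l < d_r) "L" else if (d_r < d_l) "R" else "tie"
    if (identical(pred, labels[i])) correct <- correct + 1L
  }
  sf <- correct / n
  list(success_fraction = sf, n_trials = n, n_correct = correct,
       encoder = sf >= encoder_threshold)
}

#' Prediction scores for all cells and both phases
#'
#' Applies the partner-excluding LOO scorer to the stimulus-phase responses
#' and, with identical machinery, to the control-phase responses.
#'
#' @param responses output of \code{\link{window_responses}}.
#' @param encoder_threshold encoder criterion (default 0.75).
#' @return A \code{prediction_scores} data frame: \code{cell_id},
#'   \code{phase} ("stimulus"/"control"), \code{success_fraction},
#'   \code{n_trials}, \code{encoder}.
#' @export
prediction_scores <- function(responses, encoder_threshold = 0.75) {
  cells <- unique(responses$cell_id)
  out <- lapply(cells, function(cid) {
    sub <- responses[responses$cell_id == cid, , drop = FALSE]
    sub <- sub[order(sub$trial), , drop = FALSE]
    do.call(rbind, lapply(c("stimulus", "control"), function(ph) {
      r <- if (ph == "stimulus") sub$stim_response else sub$control_response
      sc <- loo_prediction_success(r, sub$label, encoder_threshold)
      data.frame(cell_id = cid, phase = ph,
                 success_fraction = sc$success_fraction,
                 n_trials = sc$n_trials, encoder = sc$encoder,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  structure(out, class = c("prediction_scores", "data.frame"))
}

#' Discriminability table over identified neurons
#'
#' Joins per-ROI prediction scores to neuron identities and tabulates encoder
#' counts (stimulus phase vs control phase) per surface.
#'
#' @param scores a \code{prediction_scores} data frame.
#' @param assignment an \code{assignment_map} (ROI id to neuron id), or
#'   \code{NULL} to keep ROI ids.
#' @param map optional \code{canonical_map} supplying surfaces.
#' @return list: \code{table} (neuron-keyed scores, both phases; unassigned
#'   ROIs retained with \code{neuron_id = NA}), \code{encoder_counts}
#'   (encoders per phase and surface), \code{unassigned} (ROI ids without an
#'   identity).
#' @export
discriminability_map <- function(scores, assignment = NULL, map = NULL) {
  tab <- as.data.frame(scores)
  if (!is.null(assignment)) {
    pairs <- assignment$pairs
    tab$neuron_id <- pairs$neuron_id[match(tab$cell_id, pairs$roi_id)]
  } else {
    tab$neuron_id <- tab$cell_id
  }
  if (!is.null(map)) {
    tab$surface <- map$surface[match(tab$neuron_id, map$id)]
  } else {
    tab$surface <- NA_character_
  }
  unassigned <- unique(tab$cell_id[is.na(tab$neuron_id)])
  assigned <- tab[!is.na(tab$neuron_id), , drop = FALSE]
  counts <- if (nrow(assigned) > 0) {
    assigned$surface[is.na(assigned$surface)] <- "unknown"
    stats::aggregate(encoder ~ phase + surface, data = assigned, FUN = sum)
  } else {
    data.frame(phase = character(0), surface = character(0),
               encoder = integer(0))
  }
  list(table = tab, encoder_counts = counts, unassigned = unassigned)
}
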