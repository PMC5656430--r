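# Shared fixtures, built lazily and cached for the whole test run.

.fix <- new.env(parent = emptyenv())

# A small well-resolved map: few cells, generous spacing, so rendered cells
# are >= 2 px radius in the standard small frame.
small_map <- function(n_per_surface = 12, seed = 11) {
  key <- sprintf("map_%d_%d", n_per_surface, seed)
  if (is.null(.fix[[key]])) {
    .fix[[key]] <- generate_canonical_map(n_per_surface, seed = seed,
                                          semi_axes = c(80, 28),
                                          radius_range = c(6, 10))
  }
  .fix[[key]]
}

small_frame <- c(64L, 192L)

small_params <- function(map, ...) {
  imaging_params(frame_shape = small_frame, um_per_px = 1,
                 motion_amp_px = 0, ...)
}

# A standard noisy swim recording with drift, used by several files.
swim_recording <- function() {
  if (is.null(.fix$swim_rec)) {
    map <- small_map()
    prog <- activity_program(map, seed = 12, noise_sd_mv = 1)
    vs <- simulate_voltages(map, prog, "swim", duration_s = 8, seed = 13)
    prm <- imaging_params(frame_shape = small_frame, um_per_px = 1,
                          motion_amp_px = 0.4)
    .fix$swim_rec <- list(map = map, prog = prog, vs = vs,
                          rec = render_recording(vs, prm, seed = 14))
  }
  .fix$swim_rec
}

# Brute-force LOO oracle: literal enumeration, written independently of the
# scorer. For each trial, drop it and its partner, average the rest per
# class, predict nearer class mean.
oracle_loo <- function(responses, labels) {
  n <- length(responses)
  correct <- 0
  for (i in 1:n) {
    partner <- if (i %% 2 == 1) i + 1 else i - 1
    idx <- seq_len(n)[-c(i, partner)]
    ml <- mean(responses[idx[labels[idx] == "L"]])
    mr <- mean(responses[idx[labels[idx] == "R"]])
    if (abs(responses[i] - ml) < abs(responses[i] - mr)) {
      pred <- "L"
    } else if (abs(responses[i] - mr) < abs(responses[i] - ml)) {
      pred <- "R"
    } else {
      pred <- NA_character_   # tie: never correct
    }
    if (!is.na(pred) && pred == labels[i]) correct <- correct + 1
  }
  correct / n
}

# Exhaustive assignment oracle for tiny instances: enumerate all injective
# neuron -> ROI mappings (each neuron may also stay unassigned) and pick the
# minimum total cost, with the same unassignment penalty rule as the
# implementation (assignment preferred whenever feasible).
oracle_assign <- function(cost_matrix) {
  n_neu <- nrow(cost_matrix); n_roi <- ncol(cost_matrix)
  penalty <- max(cost_matrix[is.finite(cost_matrix)]) * 2 + 1
  best <- NULL; best_cost <- Inf
  options <- lapply(seq_len(n_neu), function(i) c(0L, seq_len(n_roi)))
  grid <- expand.grid(options)
  for (g in seq_len(nrow(grid))) {
    pick <- as.integer(grid[g, ])
    used <- pick[pick > 0]
    if (anyDuplicated(used)) next
    cost <- sum(ifelse(pick > 0,
                       cost_matrix[cbind(seq_len(n_neu), pmax(pick, 1))],
                       penalty))
    if (any(pick > 0) && any(!is.finite(cost))) next
    if (cost < best_cost) { best_cost <- cost; best <- pick }
  }
  best
}

# Two planted activity groups (sin vs cos) for clustering recovery tests.
planted_traces <- function(n_per_group = 5, n = 500, sd = 0.3, seed = 2) {
  set.seed(seed)
  tt <- seq(0, 10, length.out = n)
  g1 <- sapply(seq_len(n_per_group), function(i) sin(tt) + rnorm(n, sd = sd))
  g2 <- sapply(seq_len(n_per_group), function(i) cos(tt) + rnorm(n, sd = sd))
  x <- cbind(g1, g2)
  colnames(x) <- paste0("c", seq_len(2 * n_per_group))
  x
}

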