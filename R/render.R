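#' Imaging parameters of the optical forward model
#'
#' Collects the parameters turning membrane voltage into dual-view pixel
#' counts: dye sensitivity (relative fluorescence change per 100 mV, default
#' 2.7\%), frame geometry and rate, photon shot noise per cell-sized area
#' (parts per million of the cell-mean signal, default 70 ppm), bleaching
#' decay, a shared global multiplicative fluctuation, and slow sub-pixel
#' rigid motion.
#'
#' @param frame_shape c(rows, cols) in pixels.
#' @param frame_rate_hz 20 or 50 Hz (50 for bend/swim, 20 for crawl).
#' @param sensitivity_pct_per_100mv dye sensitivity, percent dF/F per 100 mV.
#' @param baseline_counts peak fluorescence counts at a cell center.
#' @param background_counts dim background level, counts.
#' @param shot_noise_ppm relative frame-to-frame noise of a cell-area mean,
#'   ppm; 0 disables noise.
#' @param bleach_amp,bleach_tau_s single-exponential bleaching: the signal is
#'   multiplied by (1 - amp) + amp * exp(-t / tau). amp <= 0.1, tau >= 10 s.
#' @param global_sd,global_bandwidth_hz shared multiplicative fluctuation:
#'   1 + lowpass Gaussian series of this sd; 0 disables.
#' @param motion_amp_px,motion_bandwidth_hz per-view rigid drift: lowpass
#'   Gaussian trajectories scaled to this peak amplitude; 0 disables.
#' @param um_per_px spatial scale of the cameras.
#' @return An \code{imaging_params} list.
#' @export
imaging_params <- function(frame_shape = c(128L, 512L), frame_rate_hz = 50,
                           sensitivity_pct_per_100mv = 2.7,
                           baseline_counts = 4000, background_counts = 400,
                           shot_noise_ppm = 70,
                           bleach_amp = 0.05, bleach_tau_s = 30,
                           global_sd = 2e-4, global_bandwidth_hz = 1,
                           motion_amp_px = 0.3, motion_bandwidth_hz = 0.5,
                           um_per_px = 1.5) {
  p <- list(frame_shape = as.integer(frame_shape),
            frame_rate_hz = frame_rate_hz,
            sensitivity_pct_per_100mv = sensitivity_pct_per_100mv,
            baseline_counts = baseline_counts,
            background_counts = background_counts,
            shot_noise_ppm = shot_noise_ppm,
            bleach_amp = bleach_amp, bleach_tau_s = bleach_tau_s,
            global_sd = global_sd, global_bandwidth_hz = global_bandwidth_hz,
            motion_amp_px = motion_amp_px,
            motion_bandwidth_hz = motion_bandwidth_hz,
            um_per_px = um_per_px)
  nonneg <- c("sensitivity_pct_per_100mv", "baseline_counts",
              "background_counts", "shot_noise_ppm", "bleach_amp",
              "bleach_tau_s", "global_sd", "motion_amp_px")
  for (f in nonneg) if (p[[f]] < 0) stop_input(f, " must be >= 0")
  if (!frame_rate_hz %in% c(20, 50)) {
    warning("frame_rate_hz is typically 50 (bend/swim) or 20 (crawl)")
  }
  if (p$bleach_amp > 0.1) stop_input("bleach_amp must be <= 0.1")
  if (p$bleach_amp > 0 && p$bleach_tau_s < 10) {
    stop_input("bleach_tau_s must be >= 10 s")
  }
  structure(p, class = "imaging_params")
}

#' Camera scale that fits a canonical map into a frame
#'
#' Returns the micrometres-per-pixel scale at which every cell of the map
#' (plus a margin) fits inside the given frame shape in both views.
#'
#' @param map a \code{canonical_map}.
#' @param frame_shape c(rows, cols), px.
#' @param margin_px clear border, px.
#' @return scalar um-per-px.
#' @export
fit_um_per_px <- function(map, frame_shape, margin_px = 6) {
  ext_x <- max(abs(map$x) + 3 * map$radius)
  ext_y <- max(abs(map$y) + 3 * map$radius)
  max(2 * ext_x / (frame_shape[2] - 1 - 2 * margin_px),
      2 * ext_y / (frame_shape[1] - 1 - 2 * margin_px))
}

# Canonical (um) -> view pixel coordinates. The dorsal camera faces the
# opposite side, so its image is mirrored left-right (columns).
view_coords <- function(map, view, params) {
  rows <- params$frame_shape[1]; cols <- params$frame_shape[2]
  sel <- map[map$surface == view, , drop = FALSE]
  px <- sel$x / params$um_per_px
  px <- if (view == "dorsal") (cols - 1) / 2 - px else (cols - 1) / 2 + px
  py <- (rows - 1) / 2 + sel$y / params$um_per_px
  data.frame(id = sel$id, cx = px, cy = py,
             radius_px = sel$radius / params$um_per_px,
             stringsAsFactors = FALSE)
}

#' Render a synthetic dual-view recording
#'
#' Applies the linear optical forward model to simulated voltages: each cell
#' body is a 2-D Gaussian intensity profile (sigma = radius / 2) whose
#' brightness is modulated as \code{F0 * (1 + s/100 * (V - V_rest)/100)},
#' with \code{s} the dye sensitivity in percent per 100 mV, then multiplied
#' by a bleaching decay and a global fluctuation shared by both views, offset
#' by per-view sub-pixel rigid motion (applied analytically to the Gaussian
#' centers, so the imposed trajectory is exact), and finally degraded by shot
#' noise in the Gaussian limit of Poisson photon counting, calibrated so a
#' median-cell-area mean fluctuates by \code{shot_noise_ppm}.
#'
#' @param vsim a \code{voltage_sim}.
#' @param params an \code{imaging_params}; its frame rate must match the
#'   simulation.
#' @param seed RNG seed for noise, motion and global series.
#' @param motion optional imposed trajectories: list with elements
#'   \code{ventral}/\code{dorsal}, each a data frame \code{dx_px, dy_px} per
#'   frame (overrides the generated trajectory).
#' @return A \code{dual_recording}: list with \code{stacks} (named list of
#'   \code{[frame, row, col]} arrays), \code{frame_times}, \code{events}
#'   (the protocol, if any), \code{rois} (ground-truth ROI table: id, view,
#'   center_x, center_y, radius in px), \code{params} and \code{truth}
#'   (voltages, percent dF/F per cell, per-view motion, identities).
#' @export
render_recording <- function(vsim, params = imaging_params(), seed = 1L,
                             motion = NULL) {
  if (abs(params$frame_rate_hz - vsim$rate_hz) > 1e-9) {
    stop_input("params$frame_rate_hz must match the voltage sampling rate")
  }
  n <- nrow(vsim$volt)
  map <- vsim$map
  dff_truth <- sweep(vsim$volt, 2, vsim$program$baseline_mv, "-") *
    params$sensitivity_pct_per_100mv / 100
  rec <- with_seed(seed, {
    glob <- if (params$global_sd > 0) {
      1 + params$global_sd * lowpass_series(n, params$frame_rate_hz,
                                            params$global_bandwidth_hz)
    } else rep(1, n)
    bleach <- (1 - params$bleach_amp) +
      params$bleach_amp * exp(-vsim$times / params$bleach_tau_s)
    views <- c("ventral", "dorsal")
    traj <- lapply(views, function(v) {
      if (!is.null(motion) && !is.null(motion[[v]])) {
        tr <- as.data.frame(motion[[v]])
        if (nrow(tr) != n) stop_input("imposed motion length mismatch")
        tr
      } else if (params$motion_amp_px > 0) {
        mk <- function() {
          s <- lowpass_series(n, params$frame_rate_hz,
                              params$motion_bandwidth_hz)
          s <- s - s[(n + 1L) %/% 2L]     # zero at the reference (middle) frame
          m <- max(abs(s)); if (m > 0) s <- s / m
          s * params$motion_amp_px
        }
        data.frame(dx_px = mk(), dy_px = mk())
      } else data.frame(dx_px = numeric(n), dy_px = numeric(n))
    })
    names(traj) <- views
    stacks <- list(); rois <- list()
    for (v in views) {
      vc <- view_coords(map, v, params)
      idx <- match(vc$id, colnames(vsim$volt))
      mod <- 1 + dff_truth[, idx, drop = FALSE] / 100
      stacks[[v]] <- render_view(vc, mod, params, traj[[v]], glob * bleach)
      rois[[v]] <- data.frame(id = vc$id, view = v, center_x = vc$cx,
                              center_y = vc$cy, radius = vc$radius_px,
                              stringsAsFactors = FALSE)
    }
    list(stacks = stacks, traj = traj,
         rois = do.call(rbind, rois), glob = glob, bleach = bleach)
  })
  rownames(rec$rois) <- NULL
  structure(list(
    stacks = rec$stacks, frame_times = vsim$times, events = vsim$protocol,
    rois = rec$rois, params = params,
    truth = c(vsim$truth,
              list(voltages = vsim$volt, dff_pct = dff_truth,
                   motion = rec$traj, global_series = rec$glob,
                   bleach = rec$bleach, map = map))),
    class = "dual_recording")
}

# Render one view: background + Gaussian cell profiles with per-frame motion
# offsets, multiplied by the shared gain series, plus calibrated shot noise.
render_view <- function(vc, mod, params, traj, gain) {
  rows <- params$frame_shape[1]; cols <- params$frame_shape[2]
  n <- nrow(mod)
  stack <- array(params$background_counts, dim = c(n, rows, cols))
  # floor sigma at one pixel: sharper profiles are not band-limited, which
  # breaks both the shift linearization and Fourier resampling
  sig <- pmax(vc$radius_px / 2, 1.0)
  pad <- ceiling(4 * sig + max(abs(unlist(traj)), 0) + 1)
  # static baseline image for noise calibration
  base <- matrix(params$background_counts, rows, cols)
  for (j in seq_len(nrow(vc))) {
    # pixel at 0-based coordinate x is matrix index x + 1
    lo_x <- max(1, floor(vc$cx[j] - pad[j]) + 1)
    hi_x <- min(cols, ceiling(vc$cx[j] + pad[j]) + 1)
    lo_y <- max(1, floor(vc$cy[j] - pad[j]) + 1)
    hi_y <- min(rows, ceiling(vc$cy[j] + pad[j]) + 1)
    if (lo_x > hi_x || lo_y > hi_y) next
    xs <- lo_x:hi_x
    ys <- lo_y:hi_y
    ex0 <- exp(-((xs - 1) - vc$cx[j])^2 / (2 * sig[j]^2))
    ey0 <- exp(-((ys - 1) - vc$cy[j])^2 / (2 * sig[j]^2))
    base[ys, xs] <- base[ys, xs] + params$baseline_counts * outer(ey0, ex0)
    for (t in seq_len(n)) {
      ex <- exp(-((xs - 1) - vc$cx[j] - traj$dx_px[t])^2 / (2 * sig[j]^2))
      ey <- exp(-((ys - 1) - vc$cy[j] - traj$dy_px[t])^2 / (2 * sig[j]^2))
      stack[t, ys, xs] <- stack[t, ys, xs] +
        params$baseline_counts * mod[t, j] * outer(ey, ex)
    }
  }
  for (t in seq_len(n)) stack[t, , ] <- stack[t, , ] * gain[t]
  if (params$shot_noise_ppm > 0) {
    # photons per count chosen so the median cell-area summed photon count
    # equals (1e6 / ppm)^2, i.e. the cell-mean relative sd equals ppm * 1e-6
    s_cell <- vapply(seq_len(nrow(vc)), function(j) {
      m <- disc_mask(rows, cols, vc$cx[j], vc$cy[j], vc$radius_px[j])
      sum(base[m])
    }, numeric(1))
    kappa <- (1e6 / params$shot_noise_ppm)^2 / stats::median(s_cell)
    noise <- stats::rnorm(length(stack)) * sqrt(pmax(stack, 0) / kappa)
    stack <- stack + array(noise, dim = dim(stack))
  }
  stack
}

# logical matrix mask of pixels within `radius` of (cx, cy), 0-based coords
disc_mask <- function(rows, cols, cx, cy, radius) {
  xs <- matrix(rep(0:(cols - 1), each = rows), rows, cols)
  ys <- matrix(rep(0:(rows - 1), cols), rows, cols)
  (xs - cx)^2 + (ys - cy)^2 <= radius^2
}

#' @export
print.dual_recording <- function(x, ...) {
  d <- dim(x$stacks[[1]])
  cat(sprintf("<dual_recording> %d frames of %dx%d px per view @ %g Hz\n",
              d[1], d[2], d[3], x$params$frame_rate_hz))
  cat(sprintf("  %d ROIs (%d ventral, %d dorsal); truth: %s\n",
              nrow(x$rois), sum(x$rois$view == "ventral"),
              sum(x$rois$view == "dorsal"),
              if (is.null(x$truth)) "absent" else "present"))
  invisible(x)
}
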