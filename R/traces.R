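#' ROI sets
#'
#' ROIs outline individual cell bodies in one camera view. Each ROI is an
#' ellipse (center, radii, rotation angle in radians) or a polygon; the pixel
#' membership mask is derived from the outline. Coordinates are 0-based
#' pixels, x = column.
#'
#' @param table data frame with columns \code{id}, \code{view}
#'   ("ventral"/"dorsal"), \code{cx}, \code{cy}, \code{rx}, and optionally
#'   \code{ry} (default \code{rx}) and \code{angle} (default 0).
#' @param polygons optional named list (by ROI id) of two-column vertex
#'   matrices (x, y) overriding the ellipse outline for those ids.
#' @return A \code{roi_set}.
#' @export
roi_set <- function(table, polygons = list()) {
  need <- c("id", "view", "cx", "cy", "rx")
  if (!all(need %in% names(table))) {
    stop_input("ROI table needs columns: ", paste(need, collapse = ", "))
  }
  if (is.null(table$ry)) table$ry <- table$rx
  if (is.null(table$angle)) table$angle <- 0
  if (anyDuplicated(paste(table$view, table$id))) {
    stop_input("ROI ids must be unique within a view")
  }
  structure(list(table = table, polygons = polygons), class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set> %d ROIs (%s)\n", nrow(x$table),
              paste(sprintf("%s: %d", names(table(x$table$view)),
                            as.integer(table(x$table$view))), collapse = ", ")))
  invisible(x)
}

#' ROIs from a synthetic recording's ground truth
#'
#' @param rec a \code{dual_recording} with a \code{rois} table.
#' @return a \code{roi_set} of circles at the true cell positions.
#' @export
truth_rois <- function(rec) {
  r <- rec$rois
  roi_set(data.frame(id = r$id, view = r$view, cx = r$center_x,
                     cy = r$center_y, rx = r$radius, stringsAsFactors = FALSE))
}

# Pixel membership (1-based linear indices into a rows x cols matrix) of one
# ROI. Pixel centers are at integer 0-based coordinates.
roi_mask_indices <- function(roi, polygons, rows, cols) {
  if (!is.null(polygons[[roi$id]])) {
    poly <- polygons[[roi$id]]
    if (min(poly[, 1]) < 0 || max(poly[, 1]) > cols - 1 ||
        min(poly[, 2]) < 0 || max(poly[, 2]) > rows - 1) {
      stop_input("ROI '", roi$id, "' extends outside the frame")
    }
    xs <- matrix(rep(0:(cols - 1), each = rows), rows, cols)
    ys <- matrix(rep(0:(rows - 1), cols), rows, cols)
    inside <- point_in_polygon(as.vector(xs), as.vector(ys),
                               poly[, 1], poly[, 2])
    idx <- which(inside)
  } else {
    ca <- cos(roi$angle); sa <- sin(roi$angle)
    rmax <- max(roi$rx, roi$ry)
    if (roi$cx - rmax < -0.5 || roi$cx + rmax > cols - 0.5 ||
        roi$cy - rmax < -0.5 || roi$cy + rmax > rows - 0.5) {
      stop_input("ROI '", roi$id, "' extends outside the frame")
    }
    pad <- ceiling(rmax)
    xr <- max(0, floor(roi$cx - pad)):min(cols - 1, ceiling(roi$cx + pad))
    yr <- max(0, floor(roi$cy - pad)):min(rows - 1, ceiling(roi$cy + pad))
    g <- expand.grid(y = yr, x = xr)
    dx <- g$x - roi$cx; dy <- g$y - roi$cy
    u <- (dx * ca + dy * sa) / roi$rx
    v <- (-dx * sa + dy * ca) / roi$ry
    sel <- u^2 + v^2 <= 1
    idx <- (g$x[sel]) * rows + g$y[sel] + 1L
  }
  if (length(idx) == 0L) stop_input("ROI '", roi$id, "' covers no pixels")
  if (any(idx < 1L | idx > rows * cols)) {
    stop_input("ROI '", roi$id, "' extends outside the frame")
  }
  idx
}

# Even-odd rule point-in-polygon test, vectorized over points.
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    cross <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Extract raw fluorescence traces from a stack
#'
#' Averages pixel values within each ROI outline in every frame, yielding one
#' raw fluorescence trace per ROI.
#'
#' @param stack \code{[frame, row, col]} array (ideally motion-corrected).
#' @param rois a \code{roi_set}.
#' @param view which view's ROIs to extract.
#' @param frame_rate_hz sampling rate, Hz.
#' @return A \code{trace_set}: list with \code{values} (frames x cells
#'   matrix), \code{ids}, \code{view}, \code{frame_rate_hz},
#'   \code{stage = "raw"}, and \code{raw_mean} (per-cell average raw
#'   fluorescence, the dF/F normalizer).
#' @export
extract_traces <- function(stack, rois, view = "ventral", frame_rate_hz = 50) {
  d <- dim(stack)
  tab <- rois$table[rois$table$view == view, , drop = FALSE]
  if (nrow(tab) == 0L) stop_input("no ROIs for view '", view, "'")
  n <- d[1]
  flat <- matrix(stack, nrow = n)     # frames x (rows*cols)
  vals <- matrix(0, n, nrow(tab))
  for (j in seq_len(nrow(tab))) {
    idx <- roi_mask_indices(tab[j, ], rois$polygons, d[2], d[3])
    vals[, j] <- if (length(idx) == 1L) flat[, idx]
                 else rowMeans(flat[, idx, drop = FALSE])
  }
  colnames(vals) <- tab$id
  structure(list(values = vals, ids = tab$id, view = view,
                 frame_rate_hz = frame_rate_hz, stage = "raw",
                 raw_mean = colMeans(vals)),
            class = "trace_set")
}

#' @export
print.trace_set <- function(x, ...) {
  cat(sprintf("<trace_set> stage=%s: %d cells x %d frames @ %g Hz\n",
              x$stage, ncol(x$values), nrow(x$values), x$frame_rate_hz))
  invisible(x)
}

# window length (odd samples) for a SALPA time constant
salpa_window <- function(time_constant_s, rate_hz, n_frames) {
  w <- 2L * as.integer(round(time_constant_s * rate_hz)) + 1L
  if (w < 5L) stop_input("SALPA window too short (< 5 samples; increase the time constant)")
  if (w > n_frames) {
    stop_input("SALPA window (", w, " samples) exceeds the trace length (",
               n_frames, "); decrease the time constant")
  }
  w
}

#' Local cubic detrending (SALPA)
#'
#' Subtracts a locally fitted third-order polynomial from each trace:
#' a centered sliding-window cubic least-squares fit (window = 2 x time
#' constant), stepped per sample, realized as Savitzky-Golay smoothing; the
#' leading and trailing half-windows use the off-center evaluations of the
#' full edge window, so polynomials up to cubic are annihilated everywhere.
#' This removes bleaching trends while preserving rhythms faster than the
#' window scale.
#'
#' @param ts a \code{trace_set}.
#' @param time_constant_s half-window, seconds (1-15 s typical).
#' @return the \code{trace_set} with detrended values,
#'   \code{stage = "detrended"}.
#' @export
salpa_detrend <- function(ts, time_constant_s = 5) {
  if (time_constant_s < 1 || time_constant_s > 15) {
    warning("SALPA time constant outside the usual 1-15 s range")
  }
  w <- salpa_window(time_constant_s, ts$frame_rate_hz, nrow(ts$values))
  ts$values <- apply(ts$values, 2, function(x) {
    x - signal::sgolayfilt(x, p = 3, n = w)
  })
  ts$stage <- "detrended"
  ts$salpa_s <- time_constant_s
  ts
}

#' Subtract the global background series
#'
#' Averages the brightness of ganglion pixels outside every ROI in each
#' frame, detrends that background series with the same SALPA parameters as
#' the traces, and subtracts it from every trace of the view. This removes
#' fluctuations shared across the image, such as fluorescent crosstalk
#' between the two views.
#'
#' @param ts a detrended \code{trace_set}.
#' @param stack the (corrected) stack the traces came from.
#' @param rois the \code{roi_set} used for extraction.
#' @param ganglion_mask optional logical \code{rows x cols} matrix limiting
#'   the background region; default: the whole frame minus the ROIs.
#' @return the \code{trace_set} with \code{stage = "global_subtracted"}.
#' @export
subtract_global <- function(ts, stack, rois, ganglion_mask = NULL) {
  d <- dim(stack)
  tab <- rois$table[rois$table$view == ts$view, , drop = FALSE]
  inroi <- logical(d[2] * d[3])
  for (j in seq_len(nrow(tab))) {
    inroi[roi_mask_indices(tab[j, ], rois$polygons, d[2], d[3])] <- TRUE
  }
  bg <- !inroi
  if (!is.null(ganglion_mask)) bg <- bg & as.vector(ganglion_mask)
  if (!any(bg)) stop_input("no non-ROI pixels available for the global background")
  flat <- matrix(stack, nrow = d[1])
  series <- rowMeans(flat[, bg, drop = FALSE])
  if (!is.null(ts$salpa_s)) {
    w <- salpa_window(ts$salpa_s, ts$frame_rate_hz, d[1])
    series <- series - signal::sgolayfilt(series, p = 3, n = w)
  } else {
    series <- series - mean(series)
  }
  ts$values <- ts$values - series
  ts$stage <- "global_subtracted"
  ts
}

#' Express traces as percent dF/F
#'
#' Divides each conditioned trace by the cell's average raw fluorescence and
#' scales to percent, so units refer to absolute brightness.
#'
#' @param ts a conditioned \code{trace_set} (carrying \code{raw_mean}).
#' @return the \code{trace_set} in percent units, \code{stage = "dff"}.
#' @export
to_dff <- function(ts) {
  if (is.null(ts$raw_mean) || any(!is.finite(ts$raw_mean)) ||
      any(ts$raw_mean <= 0)) {
    stop_input("dF/F requires a positive average raw fluorescence per cell")
  }
  ts$values <- 100 * sweep(ts$values, 2, ts$raw_mean, "/")
  ts$stage <- "dff"
  ts
}

#' Full trace-conditioning chain for one view
#'
#' raw extraction -> SALPA detrend -> global background subtraction ->
#' percent dF/F.
#'
#' @inheritParams extract_traces
#' @param time_constant_s SALPA time constant, s; default
#'   \code{min(15, duration / 4)} so the window always fits the recording.
#' @param ganglion_mask see \code{\link{subtract_global}}.
#' @return a \code{trace_set} at \code{stage = "dff"}.
#' @export
condition_traces <- function(stack, rois, view = "ventral", frame_rate_hz = 50,
                             time_constant_s = NULL, ganglion_mask = NULL) {
  n <- dim(stack)[1]
  if (is.null(time_constant_s)) {
    time_constant_s <- min(15, n / frame_rate_hz / 4)
  }
  ts <- extract_traces(stack, rois, view, frame_rate_hz)
  ts <- salpa_detrend(ts, time_constant_s)
  ts <- subtract_global(ts, stack, rois, ganglion_mask)
  to_dff(ts)
}

#' Write a trace set as wide CSV
#'
#' First column \code{frame_time_s}, then one column per cell id.
#' @param ts a \code{trace_set}.
#' @param path file path.
#' @export
write_traces <- function(ts, path) {
  df <- data.frame(frame_time_s = (seq_len(nrow(ts$values)) - 1L) /
                     ts$frame_rate_hz)
  df <- cbind(df, as.data.frame(ts$values))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
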