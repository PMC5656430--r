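#' Read and write image stacks as multi-page TIFF
#'
#' Stacks are stored as 32-bit float multi-page TIFF. TIFF float samples are
#' kept in [0, 1], so values are divided by a scale factor on write; the
#' factor is returned (and stored by \code{write_recording} in a metadata
#' sidecar) and must be supplied on read to recover absolute counts.
#'
#' @param stack \code{[frame, row, col]} array.
#' @param path TIFF file path.
#' @param scale divisor applied before writing; default slightly above the
#'   stack maximum.
#' @return \code{write_stack} returns the scale invisibly;
#'   \code{read_stack} returns the \code{[frame, row, col]} array.
#' @export
write_stack <- function(stack, path, scale = NULL) {
  if (is.null(scale)) scale <- max(stack) * (1 + 1e-6)
  pages <- lapply(seq_len(dim(stack)[1]),
                  function(t) pmin(pmax(stack[t, , ] / scale, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(scale)
}

#' @rdname write_stack
#' @export
read_stack <- function(path, scale = 1) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  n <- length(pages)
  d <- dim(pages[[1]])
  stack <- array(0, dim = c(n, d[1], d[2]))
  for (t in seq_len(n)) stack[t, , ] <- pages[[t]] * scale
  stack
}

#' Write a dual recording to a directory
#'
#' Emits one multi-page TIFF per view (\code{ventral.tif}, \code{dorsal.tif}),
#' ground-truth ROIs as \code{rois.csv} (id, view, center_x, center_y,
#' radius), the stimulus protocol (if any) as \code{protocol.json}, the
#' ground truth as \code{truth.json}, and scales/rates in \code{meta.json}.
#'
#' @param rec a \code{dual_recording}.
#' @param dir output directory (created if missing).
#' @return the directory path, invisibly.
#' @export
write_recording <- function(rec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  scales <- list()
  for (v in names(rec$stacks)) {
    scales[[v]] <- write_stack(rec$stacks[[v]], file.path(dir, paste0(v, ".tif")))
  }
  utils::write.csv(rec$rois, file.path(dir, "rois.csv"), row.names = FALSE)
  if (!is.null(rec$events)) {
    jsonlite::write_json(as.data.frame(rec$events),
                         file.path(dir, "protocol.json"), digits = NA)
  }
  meta <- list(scales = scales, frame_rate_hz = rec$params$frame_rate_hz,
               frame_shape = rec$params$frame_shape,
               um_per_px = rec$params$um_per_px)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(rec$truth)) {
    tr <- rec$truth
    tr$map <- as.data.frame(tr$map)
    jsonlite::write_json(tr, file.path(dir, "truth.json"), digits = NA)
  }
  invisible(dir)
}

#' Read a dual recording written by \code{write_recording}
#'
#' @param dir directory produced by \code{\link{write_recording}}.
#' @return a \code{dual_recording} (without ground truth unless
#'   \code{truth.json} is present).
#' @export
read_recording <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  stacks <- list()
  for (v in names(meta$scales)) {
    stacks[[v]] <- read_stack(file.path(dir, paste0(v, ".tif")),
                              scale = meta$scales[[v]])
  }
  n <- dim(stacks[[1]])[1]
  rois <- utils::read.csv(file.path(dir, "rois.csv"), stringsAsFactors = FALSE)
  events <- NULL
  pj <- file.path(dir, "protocol.json")
  if (file.exists(pj)) {
    events <- jsonlite::read_json(pj, simplifyVector = TRUE)
    class(events) <- c("stim_protocol", "data.frame")
  }
  truth <- NULL
  tj <- file.path(dir, "truth.json")
  if (file.exists(tj)) truth <- jsonlite::read_json(tj, simplifyVector = TRUE)
  structure(list(stacks = stacks,
                 frame_times = (seq_len(n) - 1L) / meta$frame_rate_hz,
                 events = events, rois = rois,
                 params = list(frame_rate_hz = meta$frame_rate_hz,
                               frame_shape = meta$frame_shape,
                               um_per_px = meta$um_per_px),
                 truth = truth),
            class = "dual_recording")
}
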