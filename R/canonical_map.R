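#' Generate a synthetic canonical neuron map
#'
#' Builds a canonical map of identified neurons for a two-surface ganglion:
#' roughly \code{n_per_surface} cell bodies on each of the ventral and dorsal
#' aspects, laid out inside an elliptical outline, mostly as bilateral homolog
#' pairs mirrored about the anterior-posterior midline, and partitioned into
#' six glial packets. Positions are drawn by dart throwing with a minimum
#' center separation so cell discs do not overlap, which keeps ROI extraction
#' and registration well posed.
#'
#' Coordinates are in micrometres; \code{x} runs along the long
#' (anterior-posterior) axis and \code{y} across the midline, so a homolog
#' pair is \code{(x, +y)} / \code{(x, -y)}.
#'
#' @param n_per_surface target number of neurons per surface (>= 2).
#' @param seed integer RNG seed; the map is reproducible field-for-field.
#' @param semi_axes ellipse semi-axes (x, y) of the ganglion outline, um.
#' @param radius_range range of cell body radii, um.
#' @return A \code{canonical_map}: a data frame with columns \code{id},
#'   \code{surface} ("ventral"/"dorsal"), \code{packet} (1..6), \code{x},
#'   \code{y}, \code{radius} (um) and \code{homolog_id} (\code{NA} for
#'   unpaired cells).
#' @examples
#' m <- generate_canonical_map(20, seed = 1)
#' table(m$surface)
#' @export
generate_canonical_map <- function(n_per_surface, seed = 1L,
                                   semi_axes = c(300, 80),
                                   radius_range = c(4, 9)) {
  if (!is.numeric(n_per_surface) || length(n_per_surface) != 1L ||
      n_per_surface < 2) {
    stop_input("`n_per_surface` must be a single number >= 2")
  }
  n_per_surface <- as.integer(n_per_surface)
  with_seed(seed, {
    surfaces <- c("ventral", "dorsal")
    out <- do.call(rbind, lapply(surfaces, function(surf) {
      place_surface(n_per_surface, surf, semi_axes, radius_range)
    }))
  })
  rownames(out) <- NULL
  structure(out, class = c("canonical_map", "data.frame"))
}

# Lay one surface out: paired cells first (mirrored across y = 0), then any
# leftover unpaired cell near the midline.
place_surface <- function(n, surface, semi_axes, radius_range) {
  a <- semi_axes[1]; b <- semi_axes[2]
  n_pairs <- n %/% 2L
  n_single <- n - 2L * n_pairs
  pfx <- if (surface == "ventral") "V" else "D"
  placed <- matrix(numeric(0), ncol = 3)  # x, y, radius of accepted cells
  rows <- list()
  sep_pad <- 2                            # um clearance between cell rims
  k <- 0L
  for (j in seq_len(n_pairs)) {
    r <- stats::runif(1, radius_range[1], radius_range[2])
    pos <- NULL
    for (try in 1:400) {
      x <- stats::runif(1, -a + r, a - r)
      ymax <- b * sqrt(max(0, 1 - (x / a)^2)) - r
      if (ymax <= r + sep_pad) next
      y <- stats::runif(1, r + sep_pad, ymax)
      cand <- rbind(c(x, y), c(x, -y))
      if (min_sep_ok(cand, r, placed, sep_pad)) { pos <- cand; break }
    }
    if (is.null(pos)) {                   # dense map: relax the separation
      x <- stats::runif(1, -a + r, a - r)
      ymax <- max(b * sqrt(max(0, 1 - (x / a)^2)) - r, r + sep_pad + 0.1)
      y <- stats::runif(1, r + sep_pad, ymax)
      pos <- rbind(c(x, y), c(x, -y))
    }
    placed <- rbind(placed, cbind(pos, r))
    idl <- sprintf("%s%03dL", pfx, j)
    idr <- sprintf("%s%03dR", pfx, j)
    k <- k + 2L
    rows[[length(rows) + 1L]] <- data.frame(
      id = c(idl, idr), surface = surface,
      packet = packet_of(pos[, 1], pos[, 2], a),
      x = pos[, 1], y = pos[, 2], radius = r,
      homolog_id = c(idr, idl), stringsAsFactors = FALSE)
  }
  if (n_single > 0L) {
    r <- stats::runif(1, radius_range[1], radius_range[2])
    x <- stats::runif(1, -a / 2, a / 2)
    rows[[length(rows) + 1L]] <- data.frame(
      id = sprintf("%sM%03d", pfx, n_pairs + 1L), surface = surface,
      packet = packet_of(x, 0, a), x = x, y = 0, radius = r,
      homolog_id = NA_character_, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

min_sep_ok <- function(cand, r, placed, pad) {
  if (nrow(placed) == 0L) return(TRUE)
  for (i in seq_len(nrow(cand))) {
    d <- sqrt((placed[, 1] - cand[i, 1])^2 + (placed[, 2] - cand[i, 2])^2)
    if (any(d < placed[, 3] + r + pad)) return(FALSE)
  }
  TRUE
}

# Six glial packets: anterior / medial / posterior thirds along x, split
# left/right across the midline. Midline cells join the left-side packet.
packet_of <- function(x, y, a) {
  third <- findInterval(x, c(-a / 3, a / 3)) + 1L   # 1, 2, 3 along x
  side <- ifelse(y > 0, 0L, 1L)
  as.integer((third - 1L) * 2L + side + 1L)
}

#' @export
print.canonical_map <- function(x, ...) {
  cat(sprintf("<canonical_map> %d neurons (%d ventral, %d dorsal), %d packets\n",
              nrow(x), sum(x$surface == "ventral"),
              sum(x$surface == "dorsal"), length(unique(x$packet))))
  cat(sprintf("  paired: %d, unpaired: %d\n",
              sum(!is.na(x$homolog_id)), sum(is.na(x$homolog_id))))
  invisible(x)
}

#' Read or write a canonical map as CSV
#'
#' Columns: \code{id, surface, packet, x, y, radius, homolog_id}.
#' @param map a \code{canonical_map}.
#' @param path file path.
#' @return \code{read_canonical_map} returns a \code{canonical_map}.
#' @export
write_canonical_map <- function(map, path) {
  utils::write.csv(as.data.frame(map), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_canonical_map
#' @export
read_canonical_map <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "surface", "packet", "x", "y", "radius", "homolog_id")
  if (!all(need %in% names(df))) {
    stop_input("canonical map CSV must have columns: ",
               paste(need, collapse = ", "))
  }
  structure(df[need], class = c("canonical_map", "data.frame"))
}
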