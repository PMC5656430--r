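#' Registration of imaged ROIs onto the canonical neuron map
#'
#' Identification proceeds in three steps mirroring semi-automatic
#' neurocartography practice: (1) a coarse affine alignment per glial packet,
#' composed as \code{M = T2 o S2 o R o S1 o T1} (translations, isotropic
#' scale, rotation, anisotropic scale) and fitted sequentially from
#' user-confirmed ROI/neuron pairs; (2) a fine alignment positing a local
#' displacement field built from Gaussian kernels at the confirmed anchors,
#' \deqn{\delta X(X,Y) = \sum_k \Delta X_k \exp(-((X-X_k)^2+(Y-Y_k)^2)/(2\sigma_k^2)),}
#' with \eqn{\sigma_k} equal to \eqn{\sqrt 3} times the distance from anchor
#' k to its nearest anchor; (3) automatic assignment of the remaining
#' canonical neurons to nearest ROIs, resolving conflicts by a cost that
#' favors size-matched pairs and penalizes displacement of large cells.
#'
#' @name cartography
NULL

# ---- affine transform -------------------------------------------------------

# A packet transform: y = t2 + s2 * (R %*% (s1 * (x + t1)))
apply_transform <- function(tr, xy) {
  xy <- as.matrix(xy)
  ctr <- sweep(xy, 2, -tr$t1)               # x + t1
  u <- tr$s1 * ctr %*% t(tr$rot)
  u <- sweep(u, 2, tr$s2, "*")
  sweep(u, 2, tr$t2, "+")
}

identity_transform <- function() {
  list(t1 = c(0, 0), s1 = 1, rot = diag(2), s2 = c(1, 1), t2 = c(0, 0))
}

# Fit components sequentially from matched point sets (canonical -> roi).
fit_packet_transform <- function(c_xy, r_xy) {
  c_xy <- unname(as.matrix(c_xy)); r_xy <- unname(as.matrix(r_xy))
  t1 <- -colMeans(c_xy)
  t2 <- colMeans(r_xy)
  cc <- sweep(c_xy, 2, colMeans(c_xy))
  rc <- sweep(r_xy, 2, colMeans(r_xy))
  spread_c <- sqrt(sum(cc^2)); spread_r <- sqrt(sum(rc^2))
  if (spread_c == 0) stop_input("degenerate anchors: zero canonical spread")
  s1 <- if (spread_r > 0) spread_r / spread_c else 1
  u <- s1 * cc
  # orthogonal Procrustes restricted to det = +1
  m <- t(rc) %*% u
  sv <- svd(m)
  d <- sign(det(sv$u %*% t(sv$v)))
  rot <- sv$u %*% diag(c(1, d)) %*% t(sv$v)
  u <- u %*% t(rot)
  s2 <- vapply(1:2, function(a) {
    den <- sum(u[, a]^2)
    if (den > 0) sum(u[, a] * rc[, a]) / den else 1
  }, numeric(1))
  s2[s2 <= 0] <- 1
  list(t1 = t1, s1 = s1, rot = rot, s2 = s2, t2 = t2)
}

# Correspondence-free fallback: match centroids, overall spread and per-axis
# spread of the two clouds (rotation left at identity).
fit_moment_transform <- function(c_xy, r_xy) {
  c_xy <- unname(as.matrix(c_xy)); r_xy <- unname(as.matrix(r_xy))
  t1 <- -colMeans(c_xy); t2 <- colMeans(r_xy)
  cc <- sweep(c_xy, 2, colMeans(c_xy)); rc <- sweep(r_xy, 2, colMeans(r_xy))
  sc <- sqrt(sum(cc^2)); sr <- sqrt(sum(rc^2))
  s1 <- if (sc > 0 && sr > 0) sr / sc else 1
  sdr <- apply(rc, 2, stats::sd); sdc <- apply(s1 * cc, 2, stats::sd)
  s2 <- ifelse(sdc > 0 & sdr > 0, sdr / sdc, 1)
  list(t1 = t1, s1 = s1, rot = diag(2), s2 = s2, t2 = t2)
}

collinear <- function(xy) {
  if (nrow(xy) < 3) return(TRUE)
  ev <- eigen(stats::cov(xy), symmetric = TRUE, only.values = TRUE)$values
  ev[2] < 1e-9 * max(ev[1], 1e-12)
}

#' Coarse packet-wise affine alignment
#'
#' Fits \code{M = T2 o S2 o R o S1 o T1} per glial packet from the
#' user-confirmed pairs of that packet: T1/T2 center both point sets, S1
#' matches overall spreads, R is the det=+1 orthogonal Procrustes rotation of
#' the centered, scaled sets, and S2 compensates anisotropic stretch per
#' axis. Packets with fewer than \code{min_pairs} (or collinear) anchors
#' inherit a whole-aspect transform: the same sequential fit on all pairs
#' pooled, or a correspondence-free moment match when no pairs exist at all.
#'
#' @param canonical a \code{canonical_map} (one aspect's neurons).
#' @param rois data frame of ROI centers: \code{id}, \code{x}, \code{y},
#'   \code{radius}.
#' @param user_pairs data frame \code{roi_id}, \code{neuron_id} of confirmed
#'   identities (may be empty).
#' @param min_pairs minimum anchors for a packet-local fit (default 3).
#' @return named list of packet transforms (names = packet numbers), with the
#'   whole-aspect fallback stored as attribute \code{"fallback"}.
#' @export
coarse_align <- function(canonical, rois, user_pairs, min_pairs = 3L) {
  canonical <- as.data.frame(canonical)
  pairs <- merge_pairs(user_pairs, canonical, rois)
  fallback <- if (nrow(pairs) >= min_pairs &&
                  !collinear(pairs[, c("rx", "ry")]) &&
                  !collinear(pairs[, c("cx", "cy")])) {
    fit_packet_transform(pairs[, c("cx", "cy")], pairs[, c("rx", "ry")])
  } else {
    fit_moment_transform(canonical[, c("x", "y")],
                         rois[, c("x", "y")])
  }
  packets <- sort(unique(canonical$packet))
  out <- lapply(packets, function(p) {
    sub <- pairs[pairs$packet == p, , drop = FALSE]
    if (nrow(sub) >= min_pairs && !collinear(sub[, c("rx", "ry")]) &&
        !collinear(sub[, c("cx", "cy")])) {
      fit_packet_transform(sub[, c("cx", "cy")], sub[, c("rx", "ry")])
    } else fallback
  })
  names(out) <- as.character(packets)
  attr(out, "fallback") <- fallback
  out
}

merge_pairs <- function(user_pairs, canonical, rois) {
  if (is.null(user_pairs) || nrow(user_pairs) == 0) {
    return(data.frame(roi_id = character(0), neuron_id = character(0),
                      packet = integer(0), cx = numeric(0), cy = numeric(0),
                      rx = numeric(0), ry = numeric(0)))
  }
  if (anyDuplicated(user_pairs$roi_id) || anyDuplicated(user_pairs$neuron_id)) {
    stop_input("contradictory user pairs: an ROI or neuron appears twice")
  }
  ci <- match(user_pairs$neuron_id, canonical$id)
  ri <- match(user_pairs$roi_id, rois$id)
  if (anyNA(ci) || anyNA(ri)) stop_input("user pair references unknown id")
  data.frame(roi_id = user_pairs$roi_id, neuron_id = user_pairs$neuron_id,
             packet = canonical$packet[ci],
             cx = canonical$x[ci], cy = canonical$y[ci],
             rx = rois$x[ri], ry = rois$y[ri], stringsAsFactors = FALSE)
}

# Predicted ROI-space positions of canonical neurons under packet transforms.
predict_positions <- function(canonical, transforms) {
  canonical <- as.data.frame(canonical)
  out <- matrix(0, nrow(canonical), 2)
  for (p in names(transforms)) {
    sel <- canonical$packet == as.integer(p)
    if (any(sel)) {
      out[sel, ] <- apply_transform(transforms[[p]],
                                    canonical[sel, c("x", "y")])
    }
  }
  colnames(out) <- c("x", "y")
  out
}

# ---- fine alignment ---------------------------------------------------------

#' Fine alignment: Gaussian-kernel displacement field
#'
#' Builds the residual warp field from the confirmed anchors: anchor k sits
#' at the actual ROI center \code{(X_k, Y_k)}, carries the mismatch
#' \code{(dX_k, dY_k)} between that center and its coarse-transform
#' prediction, and spreads it with a Gaussian kernel of scale
#' \code{sigma_k = sqrt(3)} times the distance from that ROI to its nearest
#' neighboring ROI (among all ROIs of the view, so the kernel scale tracks
#' the local cell spacing; with a single ROI, \code{sqrt(3)} times
#' \code{fallback_scale}).
#'
#' @param pairs data frame \code{roi_id, neuron_id} of anchors.
#' @param canonical,rois as in \code{\link{coarse_align}}.
#' @param transforms output of \code{\link{coarse_align}}.
#' @param fallback_scale nearest-neighbor stand-in when only one ROI exists.
#' @return A \code{warp_field}: data frame of anchors \code{X, Y, dX, dY,
#'   sigma}. Evaluate it with \code{\link{warp_eval}}.
#' @export
fine_align <- function(pairs, canonical, rois, transforms,
                       fallback_scale = NULL) {
  mp <- merge_pairs(pairs, canonical, rois)
  if (nrow(mp) == 0) {
    return(structure(data.frame(X = numeric(0), Y = numeric(0),
                                dX = numeric(0), dY = numeric(0),
                                sigma = numeric(0)),
                     class = c("warp_field", "data.frame")))
  }
  pred <- predict_positions(canonical[match(mp$neuron_id, canonical$id), ,
                                      drop = FALSE], transforms)
  anchors <- data.frame(X = mp$rx, Y = mp$ry,
                        dX = mp$rx - pred[, 1], dY = mp$ry - pred[, 2])
  if (nrow(rois) >= 2) {
    dm <- as.matrix(stats::dist(rois[, c("x", "y")]))
    diag(dm) <- Inf
    nn_all <- apply(dm, 1, min)
    nn <- nn_all[match(mp$roi_id, rois$id)]
    if (any(nn == 0)) stop_input("coincident anchors: sigma undefined")
    anchors$sigma <- sqrt(3) * nn
  } else {
    anchors$sigma <- sqrt(3) * (fallback_scale %||% 1)
  }
  structure(anchors, class = c("warp_field", "data.frame"))
}

#' Evaluate a warp field
#'
#' @param field a \code{warp_field}.
#' @param xy n x 2 matrix of positions (ROI space).
#' @return n x 2 matrix of displacements \code{(dX, dY)}; zero far from all
#'   anchors.
#' @export
warp_eval <- function(field, xy) {
  xy <- matrix(as.numeric(as.matrix(xy)), ncol = 2)
  out <- matrix(0, nrow(xy), 2)
  for (k in seq_len(nrow(field))) {
    w <- exp(-0.5 * ((xy[, 1] - field$X[k])^2 + (xy[, 2] - field$Y[k])^2) /
               field$sigma[k]^2)
    out[, 1] <- out[, 1] + field$dX[k] * w
    out[, 2] <- out[, 2] + field$dY[k] * w
  }
  out
}

# ---- automatic assignment ---------------------------------------------------

# Conflict cost: displacement weighted by neuron size, plus size dissimilarity.
assign_cost <- function(disp2, radius_n, radius_r, median_radius, lambda) {
  disp2 * radius_n / median_radius + lambda * (log(radius_n) - log(radius_r))^2
}

#' Automatic assignment of canonical neurons to ROIs
#'
#' Neurons not confirmed by the user are proposed to their nearest ROI in
#' warped space; conflicts (several neurons claiming one ROI) are resolved by
#' minimizing \code{cost = ||displacement||^2 * radius_n / median_radius +
#' lambda * (log radius_n - log radius_r)^2} with \code{lambda} the squared
#' median nearest-neighbor ROI distance: size-matched pairs are most
#' meritorious and displacing large cells is least favorable. Resolution is
#' greedy lowest-cost-first, with exhaustive enumeration on conflict
#' components of at most 8 neurons. The result is one-to-one; user pairs are
#' preserved verbatim; unresolvable neurons and ROIs are listed unassigned.
#'
#' @param canonical,rois,user_pairs as in \code{\link{coarse_align}}.
#' @param transforms packet transforms from \code{\link{coarse_align}}.
#' @param warp a \code{warp_field} from \code{\link{fine_align}}.
#' @param max_displacement candidate cutoff (px); default 3 times the median
#'   nearest-neighbor ROI distance.
#' @return An \code{assignment_map}: list with \code{pairs} (roi_id,
#'   neuron_id, provenance, displacement_px, size_ratio, cost),
#'   \code{unassigned_rois}, \code{unassigned_neurons}, \code{transforms},
#'   \code{warp}.
#' @export
auto_assign <- function(canonical, rois, transforms, warp,
                        user_pairs = NULL, max_displacement = NULL) {
  canonical <- as.data.frame(canonical)
  pred <- predict_positions(canonical, transforms)
  if (nrow(warp) > 0) pred <- pred + warp_eval(warp, pred)
  nn_scale <- if (nrow(rois) >= 2) {
    dm <- as.matrix(stats::dist(rois[, c("x", "y")]))
    diag(dm) <- Inf
    stats::median(apply(dm, 1, min))
  } else 1
  if (is.null(max_displacement)) max_displacement <- 3 * nn_scale
  lambda <- nn_scale^2
  med_rad <- stats::median(canonical$radius)
  # ROI radii on the ROI/pixel scale; compare sizes after mapping canonical
  # radii through the mean isotropic scale of the packet transform
  scale_of <- function(p) {
    tr <- transforms[[as.character(p)]] %||% attr(transforms, "fallback")
    tr$s1 * sqrt(abs(prod(tr$s2)))
  }
  rad_n <- canonical$radius *
    vapply(canonical$packet, scale_of, numeric(1))

  fixed_roi <- character(0); fixed_neu <- character(0)
  pairs <- data.frame(roi_id = character(0), neuron_id = character(0),
                      provenance = character(0), displacement_px = numeric(0),
                      size_ratio = numeric(0), cost = numeric(0),
                      stringsAsFactors = FALSE)
  if (!is.null(user_pairs) && nrow(user_pairs) > 0) {
    mp <- merge_pairs(user_pairs, canonical, rois)
    ci <- match(mp$neuron_id, canonical$id)
    ri <- match(mp$roi_id, rois$id)
    pairs <- data.frame(
      roi_id = mp$roi_id, neuron_id = mp$neuron_id, provenance = "user",
      displacement_px = sqrt((pred[ci, 1] - rois$x[ri])^2 +
                               (pred[ci, 2] - rois$y[ri])^2),
      size_ratio = rad_n[ci] / rois$radius[ri], cost = 0,
      stringsAsFactors = FALSE)
    fixed_roi <- mp$roi_id; fixed_neu <- mp$neuron_id
  }
  free_n <- which(!(canonical$id %in% fixed_neu))
  free_r <- which(!(rois$id %in% fixed_roi))
  cand <- NULL
  if (length(free_n) && length(free_r)) {
    d2 <- outer(pred[free_n, 1], rois$x[free_r], "-")^2 +
      outer(pred[free_n, 2], rois$y[free_r], "-")^2
    cost <- assign_cost(d2, rad_n[free_n],
                        matrix(rois$radius[free_r], length(free_n),
                               length(free_r), byrow = TRUE),
                        med_rad, lambda)
    ok <- which(d2 <= max_displacement^2, arr.ind = TRUE)
    if (nrow(ok)) {
      cand <- data.frame(ni = free_n[ok[, 1]], ri = free_r[ok[, 2]],
                         cost = cost[ok], d2 = d2[ok])
    }
  }
  if (!is.null(cand) && nrow(cand)) {
    sel <- resolve_conflicts(cand)
    add <- data.frame(
      roi_id = rois$id[sel$ri], neuron_id = canonical$id[sel$ni],
      provenance = "automatic", displacement_px = sqrt(sel$d2),
      size_ratio = rad_n[sel$ni] / rois$radius[sel$ri], cost = sel$cost,
      stringsAsFactors = FALSE)
    pairs <- rbind(pairs, add)
  }
  structure(list(
    pairs = pairs,
    unassigned_rois = setdiff(rois$id, pairs$roi_id),
    unassigned_neurons = setdiff(canonical$id, pairs$neuron_id),
    transforms = transforms, warp = warp),
    class = "assignment_map")
}

# Resolve candidate (neuron, roi, cost) triples to a one-to-one matching:
# exhaustive minimum-total-cost search on small connected components, greedy
# lowest-cost-first on large ones.
resolve_conflicts <- function(cand, exhaustive_max = 8L) {
  comp <- component_labels(cand)
  out <- list()
  for (cmp in unique(comp)) {
    sub <- cand[comp == cmp, , drop = FALSE]
    n_neu <- length(unique(sub$ni))
    picked <- if (n_neu <= exhaustive_max && nrow(sub) <= 32L) {
      exhaustive_match(sub)
    } else {
      greedy_match(sub)
    }
    out[[length(out) + 1L]] <- picked
  }
  do.call(rbind, out)
}

component_labels <- function(cand) {
  # union-find over the bipartite candidate graph
  ids <- c(paste0("n", cand$ni), paste0("r", cand$ri))
  parent <- stats::setNames(unique(ids), unique(ids))
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  for (i in seq_len(nrow(cand))) {
    a <- find(paste0("n", cand$ni[i])); b <- find(paste0("r", cand$ri[i]))
    if (a != b) parent[[a]] <- b
  }
  vapply(seq_len(nrow(cand)), function(i) find(paste0("n", cand$ni[i])),
         character(1))
}

greedy_match <- function(sub) {
  sub <- sub[order(sub$cost), , drop = FALSE]
  used_n <- integer(0); used_r <- integer(0)
  keep <- logical(nrow(sub))
  for (i in seq_len(nrow(sub))) {
    if (!(sub$ni[i] %in% used_n) && !(sub$ri[i] %in% used_r)) {
      keep[i] <- TRUE
      used_n <- c(used_n, sub$ni[i]); used_r <- c(used_r, sub$ri[i])
    }
  }
  sub[keep, , drop = FALSE]
}

# Branch over neurons (each taking one of its candidate ROIs or none),
# minimizing total cost with a fixed penalty per unassigned neuron high
# enough that assignment is always preferred when feasible.
exhaustive_match <- function(sub) {
  neus <- unique(sub$ni)
  penalty <- max(sub$cost) * 2 + 1
  best <- list(cost = Inf, rows = integer(0))
  nr <- nrow(sub)
  rec <- function(i, used_r, rows, acc) {
    if (acc >= best$cost) return()
    if (i > length(neus)) {
      best <<- list(cost = acc, rows = rows)
      return()
    }
    opts <- which(sub$ni == neus[i])
    for (o in opts) {
      if (!(sub$ri[o] %in% used_r)) {
        rec(i + 1L, c(used_r, sub$ri[o]), c(rows, o), acc + sub$cost[o])
      }
    }
    rec(i + 1L, used_r, rows, acc + penalty)   # leave neuron unassigned
  }
  rec(1L, integer(0), integer(0), 0)
  sub[best$rows, , drop = FALSE]
}

#' @export
print.assignment_map <- function(x, ...) {
  cat(sprintf("<assignment_map> %d pairs (%d user, %d automatic); %d ROIs / %d neurons unassigned\n",
              nrow(x$pairs), sum(x$pairs$provenance == "user"),
              sum(x$pairs$provenance == "automatic"),
              length(x$unassigned_rois), length(x$unassigned_neurons)))
  invisible(x)
}

#' Batch-iterated registration
#'
#' Emulates rounds of confirm-align-assign: in each round the coarse and fine
#' alignments are refitted from the current anchors and the remaining neurons
#' are auto-assigned; then the most confident automatic pairs (warped
#' displacement below the round's median and size ratio within [2/3, 3/2])
#' are promoted to anchors for the next round, together with any externally
#' confirmed pairs supplied for that round. Stops when the assignment is
#' stable or after \code{rounds} rounds.
#'
#' @param canonical,rois,user_pairs as in \code{\link{coarse_align}}.
#' @param confirm optional list of data frames (roi_id, neuron_id), extra
#'   confirmed pairs per round.
#' @param rounds maximum rounds (default 5).
#' @return the final \code{assignment_map}, with attribute \code{"rounds"}.
#' @export
iterate_registration <- function(canonical, rois, user_pairs = NULL,
                                 confirm = NULL, rounds = 5L) {
  anchors <- if (is.null(user_pairs)) {
    data.frame(roi_id = character(0), neuron_id = character(0),
               stringsAsFactors = FALSE)
  } else user_pairs[c("roi_id", "neuron_id")]
  prev <- NULL
  am <- NULL
  for (r in seq_len(rounds)) {
    if (!is.null(confirm) && length(confirm) >= r && !is.null(confirm[[r]])) {
      extra <- confirm[[r]][c("roi_id", "neuron_id")]
      extra <- extra[!(extra$roi_id %in% anchors$roi_id) &
                       !(extra$neuron_id %in% anchors$neuron_id), ,
                     drop = FALSE]
      anchors <- rbind(anchors, extra)
    }
    tr <- coarse_align(canonical, rois, anchors)
    wf <- fine_align(anchors, canonical, rois, tr)
    am <- auto_assign(canonical, rois, tr, wf, user_pairs = anchors)
    key <- paste(sort(paste(am$pairs$roi_id, am$pairs$neuron_id)),
                 collapse = ";")
    if (identical(key, prev)) break
    prev <- key
    auto <- am$pairs[am$pairs$provenance == "automatic", , drop = FALSE]
    if (nrow(auto)) {
      conf <- auto[auto$displacement_px <= stats::median(auto$displacement_px) &
                     auto$size_ratio >= 2 / 3 & auto$size_ratio <= 3 / 2, ,
                   drop = FALSE]
      conf <- conf[!(conf$roi_id %in% anchors$roi_id) &
                     !(conf$neuron_id %in% anchors$neuron_id), , drop = FALSE]
      if (nrow(conf)) anchors <- rbind(anchors,
                                       conf[c("roi_id", "neuron_id")])
    }
    attr(am, "rounds") <- r
  }
  am
}

#' Overlay plot of an assignment
#'
#' Renders ROI centers, warped canonical positions and assignment links for
#' manual inspection.
#'
#' @param x an \code{assignment_map}.
#' @param canonical,rois the inputs it was built from.
#' @param ... passed to \code{plot}.
#' @export
plot_assignment <- function(x, canonical, rois, ...) {
  pred <- predict_positions(as.data.frame(canonical), x$transforms)
  if (nrow(x$warp) > 0) pred <- pred + warp_eval(x$warp, pred)
  graphics::plot(rois$x, rois$y, pch = 1, col = "grey40", asp = 1,
                 xlab = "x (px)", ylab = "y (px)", ...)
  graphics::points(pred[, 1], pred[, 2], pch = 3, col = "orange")
  ri <- match(x$pairs$roi_id, rois$id)
  ci <- match(x$pairs$neuron_id, canonical$id)
  graphics::segments(rois$x[ri], rois$y[ri], pred[ci, 1], pred[ci, 2],
                     col = ifelse(x$pairs$provenance == "user",
                                  "blue", "red3"))
  invisible(x)
}

#' Write an assignment map as CSV
#'
#' Columns: \code{roi_id, neuron_id, provenance, cost}.
#' @param am an \code{assignment_map}.
#' @param path file path.
#' @export
write_assignment <- function(am, path) {
  utils::write.csv(am$pairs, path, row.names = FALSE)
  invisible(path)
}
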