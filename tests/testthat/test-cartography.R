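rot2 <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
}

# rois table from transformed canonical coordinates
rois_from <- function(map, xy, radius_scale = 1) {
  data.frame(id = paste0("roi_", seq_len(nrow(xy))),
             x = xy[, 1], y = xy[, 2],
             radius = map$radius * radius_scale, stringsAsFactors = FALSE)
}

all_pairs <- function(map, rois) {
  data.frame(roi_id = rois$id, neuron_id = map$id, stringsAsFactors = FALSE)
}

ventral_map <- function(n = 40, seed = 5) {
  m <- generate_canonical_map(n, seed = seed)
  as.data.frame(m)[m$surface == "ventral", ]
}

test_that("identity data yields the identity transform", {
  mv <- ventral_map(20)
  rois <- rois_from(mv, as.matrix(mv[, c("x", "y")]))
  tr <- coarse_align(mv, rois, all_pairs(mv, rois))
  for (p in names(tr)) {
    tp <- tr[[p]]
    expect_equal(tp$s1, 1, tolerance = 1e-9)
    expect_equal(tp$s2, c(1, 1), tolerance = 1e-9)
    expect_equal(tp$rot, diag(2), tolerance = 1e-9)
    expect_equal(tp$t2, -tp$t1, tolerance = 1e-9)
  }
  pred <- dualvsd:::predict_positions(mv, tr)
  expect_equal(pred[, 1], mv$x, tolerance = 1e-9)
})

test_that("a planted rotation and isotropic scale are recovered", {
  mv <- ventral_map(30)
  xy <- sweep(as.matrix(mv[, c("x", "y")]), 2, colMeans(as.matrix(mv[, c("x", "y")])))
  planted <- 1.2 * xy %*% t(rot2(10))
  planted <- sweep(planted, 2, c(300, 100), "+")
  rois <- rois_from(mv, planted, radius_scale = 1.2)
  tr <- coarse_align(mv, rois, all_pairs(mv, rois))
  for (p in names(tr)) {
    tp <- tr[[p]]
    ang <- atan2(tp$rot[2, 1], tp$rot[1, 1]) * 180 / pi
    expect_equal(ang, 10, tolerance = 0.1)
    expect_equal(tp$s1 * sqrt(prod(tp$s2)), 1.2, tolerance = 0.01)
  }
})

test_that("anisotropic stretch is recovered in the total per-axis scale", {
  mv <- ventral_map(30)
  xy <- sweep(as.matrix(mv[, c("x", "y")]), 2,
              colMeans(as.matrix(mv[, c("x", "y")])))
  planted <- sweep(xy %*% t(rot2(6)), 2, c(1.3, 0.9), "*")
  rois <- rois_from(mv, sweep(planted, 2, c(150, 80), "+"))
  tr <- coarse_align(mv, rois, all_pairs(mv, rois))
  # S1/S2 split is not unique; the product per axis is identified
  tp <- attr(tr, "fallback")
  expect_equal(tp$s1 * tp$s2, c(1.3, 0.9), tolerance = 0.02)
  # fitted sequence reduces the discrepancy at every stage on this instance
  cc <- sweep(as.matrix(mv[, c("x", "y")]), 2, -tp$t1)
  rc <- sweep(as.matrix(rois[, c("x", "y")]), 2, tp$t2)
  err <- function(m) sum((rc - m)^2)
  e0 <- err(cc)
  e1 <- err(tp$s1 * cc)
  e2 <- err(tp$s1 * cc %*% t(tp$rot))
  e3 <- err(sweep(tp$s1 * cc %*% t(tp$rot), 2, tp$s2, "*"))
  expect_true(e1 <= e0 && e2 <= e1 && e3 <= e2)
})

test_that("translating all ROIs changes only T2 and no assignment", {
  mv <- ventral_map(24)
  set.seed(6)
  xy <- as.matrix(mv[, c("x", "y")]) + matrix(rnorm(2 * nrow(mv)), ncol = 2)
  rois <- rois_from(mv, xy)
  up <- all_pairs(mv, rois)[seq(1, nrow(mv), by = 3), ]
  tr1 <- coarse_align(mv, rois, up)
  wf1 <- fine_align(up, mv, rois, tr1)
  am1 <- auto_assign(mv, rois, tr1, wf1, up)
  rois2 <- rois
  rois2$x <- rois$x + 40; rois2$y <- rois$y - 25
  tr2 <- coarse_align(mv, rois2, up)
  wf2 <- fine_align(up, mv, rois2, tr2)
  am2 <- auto_assign(mv, rois2, tr2, wf2, up)
  for (p in names(tr1)) {
    expect_equal(tr2[[p]]$t2 - tr1[[p]]$t2, c(40, -25), tolerance = 1e-6)
    expect_equal(tr2[[p]]$s1, tr1[[p]]$s1, tolerance = 1e-9)
    expect_equal(tr2[[p]]$rot, tr1[[p]]$rot, tolerance = 1e-9)
  }
  o1 <- am1$pairs[order(am1$pairs$neuron_id), c("roi_id", "neuron_id")]
  o2 <- am2$pairs[order(am2$pairs$neuron_id), c("roi_id", "neuron_id")]
  expect_equal(o1, o2, ignore_attr = TRUE)
})

test_that("warp field reproduces anchors: single-kernel closed form", {
  mv <- ventral_map(10)
  rois <- rois_from(mv, as.matrix(mv[, c("x", "y")]))
  # zero residuals: identically zero field
  up <- all_pairs(mv, rois)
  tr <- coarse_align(mv, rois, up)
  wf0 <- fine_align(up, mv, rois, tr)
  expect_true(all(abs(wf0$dX) < 1e-9 & abs(wf0$dY) < 1e-9))

  # single anchor (single ROI) with a 5 px x-mismatch
  rois1 <- rois[1, , drop = FALSE]
  rois1$x[1] <- rois1$x[1] + 5
  up1 <- up[1, , drop = FALSE]
  tr1 <- list("0" = dualvsd:::identity_transform())
  names(tr1) <- as.character(mv$packet[1])
  attr(tr1, "fallback") <- dualvsd:::identity_transform()
  wf1 <- fine_align(up1, mv, rois1, tr1)
  expect_equal(nrow(wf1), 1)
  expect_equal(wf1$dX, 5)
  at_anchor <- warp_eval(wf1, cbind(wf1$X, wf1$Y))
  expect_equal(at_anchor[1, 1], 5)
  far <- warp_eval(wf1, cbind(wf1$X + 3 * wf1$sigma, wf1$Y))
  expect_equal(far[1, 1], 5 * exp(-9 / 2), tolerance = 1e-9)
  expect_lt(abs(far[1, 1]), 0.06)

  # two ROIs at nearest-neighbor distance d: sigma = sqrt(3) * d for both
  rois_two <- rois[1:2, ]
  up2 <- up[1:2, ]
  wf2 <- fine_align(up2, mv[1:2, ], rois_two, tr)
  d12 <- sqrt(diff(wf2$X)^2 + diff(wf2$Y)^2)
  expect_equal(wf2$sigma, rep(sqrt(3) * d12, 2))

  # coincident anchors are rejected
  rois_dup <- rois
  rois_dup$x[2] <- rois_dup$x[1]; rois_dup$y[2] <- rois_dup$y[1]
  expect_error(fine_align(up[1:2, ], mv, rois_dup, tr), "oincident")
})

test_that("warp reproduces residuals within 1% at isolated anchors", {
  set.seed(7)
  mv <- data.frame(id = paste0("n", 1:4), packet = 1,
                   x = c(0, 400, 0, 400), y = c(0, 0, 400, 400),
                   radius = 6)
  shift <- matrix(rnorm(8, sd = 2), ncol = 2)
  rois <- data.frame(id = paste0("r", 1:4), x = mv$x + shift[, 1],
                     y = mv$y + shift[, 2], radius = 6)
  # non-anchor ROIs 15 px from each anchor set the local kernel scale
  extra <- data.frame(id = paste0("e", 1:4), x = rois$x + 15, y = rois$y,
                      radius = 6)
  rois_all <- rbind(rois, extra)
  up <- data.frame(roi_id = rois$id, neuron_id = mv$id)
  tr <- list("1" = dualvsd:::identity_transform())
  attr(tr, "fallback") <- dualvsd:::identity_transform()
  wf <- fine_align(up, mv, rois_all, tr)
  # sigma = sqrt(3) * 15, anchors 400 apart: > 6 sigma, effectively isolated
  expect_true(all(wf$sigma == sqrt(3) * 15))
  expect_gt(400, 6 * max(wf$sigma))
  at <- warp_eval(wf, cbind(rois$x, rois$y))
  expect_equal(at[, 1], rois$x - mv$x, tolerance = 0.01)
  expect_equal(at[, 2], rois$y - mv$y, tolerance = 0.01)
})

test_that("conflicts resolve by size merit: enumeration oracle on a toy case", {
  # two neurons nearest to one ROI; the size-matched neuron must win
  mv <- data.frame(id = c("big", "small", "other"), packet = 1,
                   x = c(0, 2, 30), y = c(0, 2, 0),
                   radius = c(10, 4, 6))
  rois <- data.frame(id = c("r_small", "r_big", "r_other"),
                     x = c(1, 12, 30), y = c(1, 0, 0),
                     radius = c(4, 10, 6))
  tr <- list("1" = dualvsd:::identity_transform())
  attr(tr, "fallback") <- dualvsd:::identity_transform()
  wf <- fine_align(data.frame(roi_id = character(0),
                              neuron_id = character(0)), mv, rois, tr)
  am <- auto_assign(mv, rois, tr, wf)
  got <- stats::setNames(am$pairs$roi_id, am$pairs$neuron_id)
  expect_equal(unname(got["small"]), "r_small")
  expect_equal(unname(got["big"]), "r_big")
  expect_equal(unname(got["other"]), "r_other")

  # exhaustive oracle over the same cost matrix agrees
  lambda <- stats::median(c(12.08, 11, 30))^2   # not used: recompute below
  dm <- as.matrix(stats::dist(rois[, c("x", "y")])); diag(dm) <- Inf
  lam <- stats::median(apply(dm, 1, min))^2
  med_rad <- stats::median(mv$radius)
  cost <- outer(seq_len(3), seq_len(3), Vectorize(function(i, j) {
    d2 <- (mv$x[i] - rois$x[j])^2 + (mv$y[i] - rois$y[j])^2
    if (d2 > (3 * stats::median(apply(dm, 1, min)))^2) return(Inf)
    d2 * mv$radius[i] / med_rad +
      lam * (log(mv$radius[i]) - log(rois$radius[j]))^2
  }))
  pick <- oracle_assign(cost)
  expect_equal(rois$id[pick], unname(got[mv$id]))
})

test_that("assignment is a partial matching on random instances", {
  set.seed(8)
  for (rep in 1:5) {
    mv <- ventral_map(20, seed = rep)
    xy <- as.matrix(mv[, c("x", "y")]) +
      matrix(rnorm(2 * nrow(mv), sd = 3), ncol = 2)
    rois <- rois_from(mv, xy)
    rois <- rois[sort(sample(nrow(rois), round(0.8 * nrow(rois)))), ]
    up <- data.frame(roi_id = rois$id[1:5],
                     neuron_id = mv$id[as.integer(sub("roi_", "", rois$id[1:5]))])
    tr <- coarse_align(mv, rois, up)
    wf <- fine_align(up, mv, rois, tr)
    am <- auto_assign(mv, rois, tr, wf)
    expect_false(anyDuplicated(am$pairs$roi_id) > 0)
    expect_false(anyDuplicated(am$pairs$neuron_id) > 0)
    expect_setequal(c(am$pairs$roi_id, am$unassigned_rois), rois$id)
    expect_setequal(c(am$pairs$neuron_id, am$unassigned_neurons), mv$id)
  }
})

test_that("a distorted jittered ganglion is identified at >= 90% accuracy", {
  set.seed(9)
  mv <- ventral_map(60, seed = 12)
  xy <- sweep(as.matrix(mv[, c("x", "y")]), 2,
              colMeans(as.matrix(mv[, c("x", "y")])))
  planted <- sweep(1.1 * xy %*% t(rot2(7)), 2, c(1.05, 0.95), "*")
  planted <- sweep(planted, 2, c(250, 120), "+")
  warp <- cbind(4 * sin(xy[, 2] / 50), 4 * cos(xy[, 1] / 70))
  obs <- planted + warp + matrix(rnorm(length(xy), sd = 1), ncol = 2)
  rois <- rois_from(mv, obs, radius_scale = 1.1)
  keep <- sort(sample(nrow(rois), round(0.9 * nrow(rois))))
  rois_obs <- rois[keep, ]
  by_packet <- split(seq_len(nrow(mv)), mv$packet)
  sel <- unlist(lapply(by_packet, function(ii) utils::head(intersect(ii, keep), 4)))
  up <- data.frame(roi_id = rois$id[sel], neuron_id = mv$id[sel])
  am <- iterate_registration(mv, rois_obs, up)
  auto <- am$pairs[am$pairs$provenance == "automatic", ]
  truth <- paste0("roi_", match(auto$neuron_id, mv$id))
  expect_gte(mean(auto$roi_id == truth), 0.9)
  # deleted cells are reported unassigned, user pairs preserved verbatim
  expect_true(all(mv$id[-keep] %in% c(am$unassigned_neurons,
                                      am$pairs$neuron_id[am$pairs$provenance == "automatic"])) ||
                length(am$unassigned_neurons) > 0)
  expect_true(all(up$roi_id %in% am$pairs$roi_id[am$pairs$provenance == "user"]))
  # coarse+fine reduces mean canonical-to-ROI distance by >= 80% vs identity
  tr <- am$transforms
  pred <- dualvsd:::predict_positions(mv, tr)
  if (nrow(am$warp) > 0) pred <- pred + warp_eval(am$warp, pred)
  idx <- match(paste0("roi_", seq_len(nrow(mv))), rois_obs$id)
  ok <- !is.na(idx)
  d_fit <- sqrt(rowSums((pred[ok, ] - as.matrix(rois_obs[idx[ok], c("x", "y")]))^2))
  d_id <- sqrt(rowSums((as.matrix(mv[ok, c("x", "y")]) -
                          as.matrix(rois_obs[idx[ok], c("x", "y")]))^2))
  expect_lt(mean(d_fit), 0.2 * mean(d_id))
})

test_that("iterated registration converges and respects extra confirmations", {
  mv <- ventral_map(30, seed = 13)
  rois <- rois_from(mv, as.matrix(mv[, c("x", "y")]))
  up <- all_pairs(mv, rois)[1:4, ]
  am1 <- iterate_registration(mv, rois, up)
  # exact data: perfect assignment, fixed point
  truth <- paste0("roi_", match(am1$pairs$neuron_id, mv$id))
  expect_true(all(am1$pairs$roi_id == truth))
  # extra confirmed pairs never reduce accuracy
  set.seed(14)
  xy <- as.matrix(mv[, c("x", "y")]) +
    matrix(rnorm(2 * nrow(mv), sd = 4), ncol = 2)
  rois2 <- rois_from(mv, xy)
  up2 <- all_pairs(mv, rois2)[1:3, ]
  acc <- function(am) {
    auto <- am$pairs[am$pairs$provenance == "automatic", ]
    mean(auto$roi_id == paste0("roi_", match(auto$neuron_id, mv$id)))
  }
  a_base <- acc(iterate_registration(mv, rois2, up2, rounds = 1))
  extra <- all_pairs(mv, rois2)[10:14, ]
  a_more <- acc(iterate_registration(mv, rois2, up2,
                                     confirm = list(NULL, extra)))
  expect_gte(a_more, a_base - 1e-9)
  # contradictory pairs are rejected
  bad <- rbind(up2, up2[1, ])
  expect_error(coarse_align(mv, rois2, bad), "twice")
  # no user pairs at all: the moment fallback still runs end to end
  am0 <- iterate_registration(mv, rois, NULL)
  expect_s3_class(am0, "assignment_map")
})
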