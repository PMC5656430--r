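# a smooth synthetic cell image for basis/estimator tests
gauss_frame <- function(rows = 40, cols = 60, cx = 30, cy = 20, sigma = 3,
                        peak = 1000, bg = 50) {
  xs <- matrix(rep(0:(cols - 1), each = rows), rows, cols)
  ys <- matrix(rep(0:(rows - 1), cols), rows, cols)
  bg + peak * exp(-((xs - cx)^2 + (ys - cy)^2) / (2 * sigma^2))
}

as_stack <- function(frames) {
  out <- array(0, dim = c(length(frames), nrow(frames[[1]]), ncol(frames[[1]])))
  for (t in seq_along(frames)) out[t, , ] <- frames[[t]]
  out
}

test_that("a constant stack yields a degenerate-basis error", {
  st <- array(7, dim = c(3, 10, 12))
  expect_error(make_shift_basis(st, axis = "x"), "degenerate")
})

test_that("the x-basis of a one-hot image shifts the hot pixel one column", {
  fr <- matrix(0, 9, 11)
  fr[5, 6] <- 1
  st <- as_stack(list(fr))
  b <- make_shift_basis(st, reference_index = 1, axis = "x")
  ir <- matrix(b$ir, 9, 11)
  expect_equal(which(ir == max(ir), arr.ind = TRUE)[1, ],
               c(row = 5, col = 7))
})

test_that("the y-basis is the reference resampled one pixel along y", {
  fr <- gauss_frame()
  b <- make_shift_basis(as_stack(list(fr)), 1, "y")
  # integer shifts are exact: I_R equals the cell re-rendered at cy + 1
  interior <- 2:(nrow(fr) - 1)
  ir <- matrix(b$ir, nrow(fr), ncol(fr))
  il <- matrix(b$il, nrow(fr), ncol(fr))
  expect_equal(ir[interior, ], gauss_frame(cy = 21)[interior, ],
               tolerance = 1e-12)
  expect_equal(il[interior, ], gauss_frame(cy = 19)[interior, ],
               tolerance = 1e-12)
  # the difference is a y-derivative stencil: zero away from cell edges
  d <- ir - il
  ys <- matrix(rep(0:(nrow(fr) - 1), ncol(fr)), nrow(fr), ncol(fr))
  far <- abs(ys - 20) > 12
  expect_lt(max(abs(d[far])), 1e-3 * max(abs(d)))
  # and matches -2 d(image)/dy to stencil accuracy near the edges
  grad <- ((ys - 20) / 9) * (fr - 50)
  band <- abs(ys - 20) > 1 & abs(ys - 20) < 7
  expect_equal(mean(sign(d[band]) == sign(grad[band])), 1)
})

test_that("the estimator is exact on the linear shift family", {
  fr <- gauss_frame()
  b <- make_shift_basis(as_stack(list(fr)), 1, "x")
  mid <- (b$il + b$ir) / 2
  expect_equal(estimate_shift(mid, b), 0, tolerance = 1e-12)
  expect_equal(estimate_shift(b$ir, b), 1, tolerance = 1e-12)
  expect_equal(estimate_shift(b$il, b), -1, tolerance = 1e-12)
  for (dx in c(-0.7, -0.3, 0.25, 0.3, 0.9)) {
    ip <- ((1 - dx) * b$il + (1 + dx) * b$ir) / 2
    expect_equal(estimate_shift(ip, b), dx, tolerance = 1e-12)
  }
})

test_that("the estimator equals the brute-force least-squares fit", {
  fr <- gauss_frame()
  b <- make_shift_basis(as_stack(list(fr)), 1, "x")
  set.seed(1)
  ip <- as.vector(gauss_frame(cx = 30.4)) + rnorm(length(fr), sd = 2)
  fit <- stats::optimize(function(d) {
    sum((ip - ((1 - d) * b$il + (1 + d) * b$ir) / 2)^2)
  }, c(-1, 1), tol = 1e-12)
  expect_equal(estimate_shift(ip, b), fit$minimum, tolerance = 1e-6)
})

test_that("the estimate is antisymmetric in the shift direction", {
  for (d in c(0.2, 0.5, 0.8)) {
    plus <- gauss_frame(cx = 30 + d)
    minus <- gauss_frame(cx = 30 - d)
    b <- make_shift_basis(as_stack(list(gauss_frame())), 1, "x")
    expect_equal(estimate_shift(plus, b), -estimate_shift(minus, b),
                 tolerance = 1e-6)
  }
})

test_that("a motionless noiseless stack yields an all-zero trajectory", {
  fr <- gauss_frame()
  st <- as_stack(list(fr, fr, fr, fr, fr))
  tj <- estimate_trajectory(st, c("x", "y"))
  expect_equal(tj$dx_px, rep(0, 5), tolerance = 1e-9)
  expect_equal(tj$dy_px, rep(0, 5), tolerance = 1e-9)
  expect_equal(unlist(tj[attr(tj, "reference_index"), 2:4]),
               c(dx_px = 0, dy_px = 0, dtheta_0p1deg = 0))
})

test_that("imposed smooth drift is recovered within 0.05 px and axes separate", {
  sw <- swim_recording()
  st <- sw$rec$stacks$ventral
  tj <- estimate_trajectory(st, c("x", "y"))
  ref <- attr(tj, "reference_index")
  tr <- sw$rec$truth$motion$ventral
  expect_lt(max(abs(tj$dx_px - (tr$dx_px - tr$dx_px[ref]))), 0.05)
  expect_lt(max(abs(tj$dy_px - (tr$dy_px - tr$dy_px[ref]))), 0.05)

  # pure y-drift: x estimates stay near zero
  map <- small_map(4)
  prog <- activity_program(map, seed = 1, involved_fraction = 0,
                           noise_sd_mv = 0, epsp_rate_hz = 0, spike_rate_hz = 0)
  vs <- simulate_voltages(map, prog, "swim", duration_s = 1.2, seed = 2)
  n <- nrow(vs$volt)
  mo <- list(ventral = data.frame(dx_px = 0,
                                  dy_px = 0.6 * sin(2 * pi * (1:n) / n)))
  prm <- imaging_params(frame_shape = small_frame, um_per_px = 1,
                        motion_amp_px = 0, shot_noise_ppm = 0,
                        bleach_amp = 0, global_sd = 0)
  rec <- render_recording(vs, prm, seed = 3, motion = mo)
  tj2 <- estimate_trajectory(rec$stacks$ventral, c("x", "y"))
  expect_lt(abs(mean(tj2$dx_px)), 0.02)
})

test_that("correction round-trips: residual shift < 0.02 px", {
  map <- small_map(4)
  prog <- activity_program(map, seed = 1, involved_fraction = 0,
                           noise_sd_mv = 0, epsp_rate_hz = 0, spike_rate_hz = 0)
  vs <- simulate_voltages(map, prog, "swim", duration_s = 1, seed = 2)
  n <- nrow(vs$volt)
  mo <- list(ventral = data.frame(dx_px = rep(0.5, n), dy_px = rep(0, n)))
  mo$ventral$dx_px[(n + 1) %/% 2] <- 0.5    # constant, incl. reference
  prm <- imaging_params(frame_shape = small_frame, um_per_px = 1,
                        motion_amp_px = 0, shot_noise_ppm = 0,
                        bleach_amp = 0, global_sd = 0)
  rec <- render_recording(vs, prm, seed = 3, motion = mo)
  # shift reference frame content back so the stack has true 0.5 px offsets
  st <- rec$stacks$ventral
  base <- render_recording(vs, prm, seed = 3)$stacks$ventral
  st[(n + 1) %/% 2, , ] <- base[(n + 1) %/% 2, , ]
  tj <- estimate_trajectory(st, c("x", "y"))
  expect_equal(stats::median(tj$dx_px[-((n + 1) %/% 2)]), 0.5,
               tolerance = 0.02)
  cs <- correct_stack(st, tj)
  tj2 <- estimate_trajectory(cs, c("x", "y"))
  expect_lt(max(abs(tj2$dx_px)), 0.02)

  # zero trajectory leaves the stack untouched
  zero <- tj; zero$dx_px[] <- 0; zero$dy_px[] <- 0; zero$dtheta_0p1deg[] <- 0
  expect_identical(correct_stack(st, zero), st)
  expect_error(correct_stack(st, tj[-1, ]), "cover")
})

test_that("correction reduces motion-induced ROI variance on a noiseless drift", {
  map <- small_map(4)
  prog <- activity_program(map, seed = 1, involved_fraction = 0,
                           noise_sd_mv = 0, epsp_rate_hz = 0, spike_rate_hz = 0)
  vs <- simulate_voltages(map, prog, "swim", duration_s = 2, seed = 2)
  prm <- imaging_params(frame_shape = small_frame, um_per_px = 1,
                        motion_amp_px = 0.5, shot_noise_ppm = 0,
                        bleach_amp = 0, global_sd = 0)
  rec <- render_recording(vs, prm, seed = 4)
  rois <- truth_rois(rec)
  raw_unc <- extract_traces(rec$stacks$ventral, rois, "ventral", 50)
  tj <- estimate_trajectory(rec$stacks$ventral, c("x", "y"))
  raw_cor <- extract_traces(correct_stack(rec$stacks$ventral, tj), rois,
                            "ventral", 50)
  v_unc <- mean(apply(raw_unc$values, 2, stats::var))
  v_cor <- mean(apply(raw_cor$values, 2, stats::var))
  expect_lt(v_cor, v_unc / 10)
})

test_that("rotation is estimated in 0.1 degree units", {
  fr <- gauss_frame(cx = 20, cy = 14, sigma = 4)
  fr <- fr + gauss_frame(cx = 45, cy = 26, sigma = 3, peak = 800)
  rot <- dualvsd:::resample_frame(fr, theta_deg = 0.25)
  st <- as_stack(list(fr, rot, fr))
  tj <- estimate_trajectory(st, c("x", "y", "rotation"), reference_index = 1)
  expect_equal(tj$dtheta_0p1deg[2], 2.5, tolerance = 0.2)
})
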