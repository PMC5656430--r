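uniform_stack <- function(n = 20, rows = 16, cols = 24, value = 100) {
  array(value, dim = c(n, rows, cols))
}

simple_rois <- function() {
  roi_set(data.frame(id = c("a", "b"), view = "ventral",
                     cx = c(6, 16), cy = c(8, 8), rx = c(3, 2),
                     stringsAsFactors = FALSE))
}

test_that("extraction averages ROI pixels; uniform frames give constant traces", {
  st <- uniform_stack()
  ts <- extract_traces(st, simple_rois(), "ventral", 50)
  expect_true(all(ts$values == 100))
  expect_equal(ts$stage, "raw")
})

test_that("a one-pixel ROI reproduces that pixel's series", {
  st <- uniform_stack()
  series <- sin(seq_len(dim(st)[1]))
  st[, 9, 7] <- 100 + series          # pixel (x=6, y=8), 0-based
  rois <- roi_set(data.frame(id = "p", view = "ventral", cx = 6, cy = 8,
                             rx = 0.4, stringsAsFactors = FALSE))
  ts <- extract_traces(st, rois, "ventral", 50)
  expect_equal(unname(ts$values[, 1]), 100 + series)
})

test_that("ROIs outside the frame are rejected", {
  st <- uniform_stack()
  rois <- roi_set(data.frame(id = "out", view = "ventral", cx = 23, cy = 8,
                             rx = 3, stringsAsFactors = FALSE))
  expect_error(extract_traces(st, rois, "ventral", 50), "outside")
})

test_that("polygon ROIs select by the even-odd rule", {
  st <- uniform_stack()
  st[, 3, 3] <- 999                              # inside pixel (x=2, y=2)
  rois <- roi_set(
    data.frame(id = "sq", view = "ventral", cx = 0, cy = 0, rx = 1),
    polygons = list(sq = cbind(c(1.5, 3.5, 3.5, 1.5), c(1.5, 1.5, 3.5, 3.5))))
  ts <- extract_traces(st, rois, "ventral", 50)
  # square covers pixels (2,2),(2,3),(3,2),(3,3): one of four is 999
  expect_equal(unname(ts$values[1, 1]), (3 * 100 + 999) / 4)
})

test_that("raw traces track the forward model on a noiseless recording", {
  map <- small_map(4)
  prog <- activity_program(map, seed = 1, involved_fraction = 1,
                           noise_sd_mv = 0, epsp_rate_hz = 0, spike_rate_hz = 0)
  vs <- simulate_voltages(map, prog, "swim", duration_s = 4, seed = 2)
  prm <- imaging_params(frame_shape = small_frame, um_per_px = 1,
                        motion_amp_px = 0, shot_noise_ppm = 0,
                        bleach_amp = 0, global_sd = 0)
  rec <- render_recording(vs, prm, seed = 3)
  ts <- extract_traces(rec$stacks$ventral, truth_rois(rec), "ventral", 50)
  for (id in ts$ids) {
    expect_gt(stats::cor(ts$values[, id], rec$truth$dff_pct[, id]), 0.999)
  }
})

test_that("SALPA annihilates cubic trends and rejects over-long windows", {
  n <- 400
  tt <- seq_len(n) / 50
  cubic <- 5 + 0.8 * tt - 0.3 * tt^2 + 0.01 * tt^3
  ts <- structure(list(values = cbind(c1 = cubic), ids = "c1",
                       view = "ventral", frame_rate_hz = 50, stage = "raw",
                       raw_mean = mean(cubic)), class = "trace_set")
  out <- salpa_detrend(ts, time_constant_s = 2)
  expect_lt(stats::sd(out$values), 1e-6 * stats::sd(cubic))
  expect_error(salpa_detrend(ts, time_constant_s = 10), "window")
})

test_that("SALPA removes bleach while preserving a fast rhythm", {
  n <- 1500
  tt <- (seq_len(n) - 1) / 50
  bleach <- 5 * exp(-tt / 30)                       # percent units
  rhythm <- 0.2 * sin(2 * pi * 1.5 * tt)
  ts <- structure(list(values = cbind(c1 = bleach + rhythm), ids = "c1",
                       view = "ventral", frame_rate_hz = 50, stage = "raw",
                       raw_mean = 100), class = "trace_set")
  out <- salpa_detrend(ts, time_constant_s = 5)
  resid <- out$values[, 1]
  # rhythm amplitude preserved within 5% (compare at the rhythm frequency)
  amp_out <- Mod(sum(resid * exp(-2i * pi * 1.5 * tt)))
  amp_ref <- Mod(sum(rhythm * exp(-2i * pi * 1.5 * tt)))
  expect_equal(amp_out / amp_ref, 1, tolerance = 0.05)
  # trend removed > 95%
  trend_left <- stats::sd(resid - rhythm)
  expect_lt(trend_left, 0.05 * stats::sd(bleach))
})

test_that("SALPA shrinks white-noise variance on average and is near-idempotent", {
  set.seed(4)
  ratios <- numeric(8)
  for (rep in 1:8) {
    x <- rnorm(600)
    ts <- structure(list(values = cbind(c1 = x), ids = "c1",
                         view = "ventral", frame_rate_hz = 50, stage = "raw",
                         raw_mean = 1), class = "trace_set")
    out <- salpa_detrend(ts, time_constant_s = 2)
    ratios[rep] <- stats::var(out$values) / stats::var(x)
    # local least squares is a projection on interior windows; edge windows
    # use off-center evaluation, so allow a whisker above 1 per replicate
    expect_lt(ratios[rep], 1.02)
    again <- salpa_detrend(out, time_constant_s = 2)
    expect_lt(stats::sd(again$values - out$values), 1e-6 * stats::sd(x) +
                0.05 * stats::sd(out$values))
  }
  expect_lt(mean(ratios), 1)
})

test_that("global subtraction cancels a shared multiplicative series", {
  n <- 300; rows <- 16; cols <- 24
  set.seed(5)
  g <- 1 + 5e-3 * dualvsd:::lowpass_series(n, 50, 2)
  st <- array(rep(100 * g, rows * cols), dim = c(n, rows, cols))
  rois <- simple_rois()
  ts <- extract_traces(st, rois, "ventral", 50)
  ts <- salpa_detrend(ts, time_constant_s = 1)
  out <- subtract_global(ts, st, rois)
  expect_equal(out$stage, "global_subtracted")
  sd_before <- apply(ts$values, 2, stats::sd)
  sd_after <- apply(out$values, 2, stats::sd)
  expect_true(all(sd_after <= sd_before / 10))
  expect_error(subtract_global(ts, st, rois,
                               ganglion_mask = matrix(FALSE, rows, cols)),
               "non-ROI")
})

test_that("without a global series, subtraction changes little", {
  st <- uniform_stack(n = 300)
  set.seed(6)
  st[, 9, 7] <- 100 + rnorm(300, sd = 0.5)   # signal inside ROI 'a' only
  rois <- simple_rois()
  ts <- salpa_detrend(extract_traces(st, rois, "ventral", 50), 1)
  out <- subtract_global(ts, st, rois)
  expect_equal(out$values, ts$values, tolerance = 1e-9)
})

test_that("dF/F normalizes to the average raw fluorescence in percent", {
  st <- uniform_stack(n = 50, value = 200)
  rois <- simple_rois()
  ts <- extract_traces(st, rois, "ventral", 50)
  ts$values <- ts$values - 200               # conditioned: zero
  dff <- to_dff(ts)
  expect_true(all(dff$values == 0))
  ts$raw_mean[] <- 0
  expect_error(to_dff(ts), "positive")
})

test_that("conditioning is linear in the input signal", {
  n <- 400
  set.seed(7)
  s1 <- cbind(c1 = 2 * sin(2 * pi * 1.5 * (1:n) / 50))
  s2 <- cbind(c1 = rnorm(n))
  mk <- function(v) structure(list(values = v, ids = "c1", view = "ventral",
                                   frame_rate_hz = 50, stage = "raw",
                                   raw_mean = 100), class = "trace_set")
  f <- function(v) to_dff(salpa_detrend(mk(v), 2))$values
  expect_equal(f(s1 + s2), f(s1) + f(s2), tolerance = 1e-9)
})

test_that("end-to-end: recovered dF/F matches truth for strong oscillators", {
  sw <- swim_recording()
  rec <- sw$rec
  rois <- truth_rois(rec)
  for (v in c("ventral", "dorsal")) {
    tj <- estimate_trajectory(rec$stacks[[v]], c("x", "y"))
    cs <- correct_stack(rec$stacks[[v]], tj)
    dff <- condition_traces(cs, rois, v, 50)
    amp <- sw$vs$truth$osc_amp_mv[match(dff$ids, sw$map$id)]
    cc <- vapply(dff$ids, function(id) {
      stats::cor(dff$values[, id], rec$truth$dff_pct[, id])
    }, numeric(1))
    expect_true(all(cc[amp >= 5] > 0.9))
  }
})
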