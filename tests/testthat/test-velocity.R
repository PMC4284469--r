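test_that("uniform and stationary motion give constant/zero velocity", {
  tt <- 0:60
  trk <- track(tt, cbind(0.2 * tt, 0))
  vs <- compute_velocity(trk)
  expect_equal(vs$v, rep(0.2, length(tt)), tolerance = 1e-9)
  trk0 <- track(tt, cbind(rep(1, 61), rep(2, 61)))
  vs0 <- compute_velocity(trk0)
  expect_equal(vs0$v, rep(0, 61))
  expect_error(compute_velocity(trk, window = 2), "odd")
})

test_that("velocity from a noiseless decay-law track matches the law", {
  # single cycle, no reversal: positions are the antiderivative of v(t)
  p <- anchor_15()
  t <- 0:450
  x <- p$v_term * t + (p$v_max - p$v_term) * p$tau * (1 - exp(-t / p$tau))
  trk <- track(t, cbind(x, 0))
  vs <- compute_velocity(trk, window = 1)
  interior <- 5:446
  expect_equal(vs$v[interior], instantaneous_speed(p, t[interior]),
               tolerance = 1e-4)
})

test_that("velocity handles back-and-forth and curved paths with sign", {
  st <- generate_track(track_gen_config(duration = 2400, seed = 31,
                                        noise_sd = 0, curvature = 0.002))
  vs <- compute_velocity(st$track, window = 1)
  # speed magnitudes follow the law; sign flips exactly at true reversals
  revs <- detect_reversals(vs)
  expect_equal(length(revs), length(st$reversals))
  expect_lt(max(abs(revs - st$reversals)), 1.5)
})

test_that("reversal detection obeys hysteresis and interpolates crossings", {
  mk <- function(v) structure(list(times = seq_along(v), v = v, window = 1),
                              class = "velocity_series")
  # one clean sign change between samples 2 and 3
  r <- detect_reversals(mk(c(0.2, 0.2, -0.2, -0.2)), hysteresis = 0.02)
  expect_length(r, 1)
  expect_gt(r, 2); expect_lt(r, 3)
  # all-positive: none
  expect_length(detect_reversals(mk(rep(0.2, 10))), 0)
  # sub-hysteresis flutter is ignored
  flutter <- c(0.2, 0.2, 0.01, -0.01, 0.015, 0.2, 0.2)
  expect_length(detect_reversals(mk(flutter), hysteresis = 0.02), 0)
  # noisy synthetic track with scheduled reversals: exact count recovery
  st <- generate_track(track_gen_config(duration = 3600, seed = 8))
  a <- compute_velocity(st$track)
  revs <- detect_reversals(a)
  expect_equal(length(revs), length(st$reversals))
  expect_lt(max(abs(revs - st$reversals)), 1.5)
})

test_that("cycle segmentation is fencepost-correct and conserves time", {
  st <- generate_track(track_gen_config(duration = 3600, seed = 9))
  vs <- compute_velocity(st$track)
  revs <- detect_reversals(vs)
  cycles <- segment_cycles(vs, revs)
  expect_length(cycles, length(revs) - 1)
  durs <- vapply(cycles, function(cy) cy$duration, numeric(1))
  expect_equal(sum(durs), max(revs) - min(revs), tolerance = 1e-9)
  # two reversals -> one cycle
  expect_length(segment_cycles(vs, revs[1:2]), 1)
  # speeds non-negative, displacement bounded by max speed x duration
  for (cy in cycles) {
    expect_true(all(cy$speed >= 0))
    expect_lte(cy$displacement_um, max(vs$v^2)^0.5 * cy$duration * 1.01)
  }
})

test_that("constant-speed cycles sit on the displacement upper limit", {
  v <- c(rep(0.25, 100), rep(-0.25, 100), rep(0.25, 100))
  vs <- structure(list(times = seq_along(v), v = v, window = 1),
                  class = "velocity_series")
  revs <- detect_reversals(vs)
  cycles <- segment_cycles(vs, revs, guard_frames = 0)
  dd <- displacement_duration_table(cycles)
  expect_equal(dd$upper_limit_slope, 0.25, tolerance = 0.02)
  # decaying cycles fall strictly below v_max * duration
  p <- anchor_15()
  st <- generate_track(track_gen_config(params = p, duration = 7200,
                                        seed = 10, noise_sd = 0))
  a <- analyze_track(st$track)
  dd2 <- a$displacement
  expect_true(all(dd2$table$displacement_um <
                    p$v_max * dd2$table$duration_s))
})
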