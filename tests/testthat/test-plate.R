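straight_state <- function(length = 100, heading = 0, agar = 1.5,
                           kappa = 0, seed = 1) {
  sub <- agar_to_params(agar, kappa = kappa)
  fil <- new_filament(c(0, 0), heading, length, sub$kinetics, id = 1L)
  plate_state(list(fil), sub, encounters = FALSE, seed = seed)
}

test_that("a straight filament advances by speed*dt along its heading", {
  st <- straight_state(kappa = 0)
  fil <- st$filaments[[1]]
  fil$next_reversal <- Inf            # suppress reversals for this check
  p <- fil$params
  tip0 <- drop(glidekin:::fil_point_at(fil, fil$s_hi))
  dt <- 5
  n <- 40
  expected <- sum(instantaneous_speed(p, (0:(n - 1)) * dt)) * dt
  for (i in 1:n) plate_step(st, dt)
  tip1 <- drop(glidekin:::fil_point_at(fil, fil$s_hi))
  expect_equal(tip1 - tip0, c(expected, 0), tolerance = 1e-9)
  # body stays straight
  expect_equal(polyline_winding(filament_vertices(fil)), 0)
})

test_that("step preserves arc length; only growth changes it", {
  st <- straight_state(kappa = 0.002)
  fil <- st$filaments[[1]]
  for (i in 1:200) plate_step(st, 5)
  expect_equal(fil$length, 100, tolerance = 1e-9)
  v <- filament_vertices(fil)
  expect_equal(sum(sqrt(rowSums(diff(v)^2))), 100, tolerance = 1e-6)
  st$doubling_time <- 3600
  for (i in 1:10) plate_step(st, 5)
  expect_equal(fil$length, 100 * 2^(50 / 3600), tolerance = 1e-6)
})

test_that("the stability condition is enforced", {
  st <- straight_state()
  expect_error(plate_step(st, 60), "unstable")
})

test_that("reversal intervals are drawn from the configured range", {
  st <- straight_state(kappa = 0)
  fil <- st$filaments[[1]]
  revs <- c()
  last <- 0
  for (i in 1:2000) {
    nr <- fil$next_reversal
    plate_step(st, 5)
    if (fil$next_reversal != nr) revs <- c(revs, st$clock)
  }
  iv <- diff(revs)
  expect_true(all(iv >= 300 - 5 & iv <= 600 + 5))
  expect_gt(length(iv), 10)
})

test_that("backward motion retraces the forward sheath trail", {
  sc <- list(agar = 1.5, duration_s = 1800, dt_s = 5, doubling_time_s = NA,
             seed = 5, encounters = FALSE,
             inoculum = list(list(x_um = 0, y_um = 0, heading_rad = 0.3,
                                  length_um = 100)))
  st <- simulate_plate(sc, record_tips = TRUE)
  th <- st$tip_history
  fwd <- th$direction[, 1] == 1
  f <- cbind(th$head_x[fwd, 1], th$head_y[fwd, 1])
  b <- cbind(th$head_x[!fwd, 1], th$head_y[!fwd, 1])
  deposit_radius <- st$filaments[[1]]$width / 2
  mind <- vapply(seq_len(nrow(b)), function(i)
    min(sqrt((f[, 1] - b[i, 1])^2 + (f[, 2] - b[i, 2])^2)), numeric(1))
  expect_lt(max(mind), deposit_radius)
})

test_that("trail_query matches an exhaustive scan and honours the radius", {
  sub <- agar_to_params(1.5)
  f1 <- new_filament(c(0, 0), 0, 60, sub$kinetics, id = 1L)
  f2 <- new_filament(c(20, 10), pi / 3, 80, sub$kinetics, id = 2L)
  st <- plate_state(list(f1, f2), sub, seed = 2)
  set.seed(99)
  for (i in 1:25) {
    pt <- runif(2, -60, 60)
    r <- runif(1, 0, 30)
    q <- trail_query(st, pt, r)
    expect_equal(nrow(q), oracle_trail_scan(st, pt, r))
    if (nrow(q)) expect_true(all(q$distance <= r))
    q1 <- trail_query(st, pt, r, exclude_id = 1L)
    expect_equal(nrow(q1), oracle_trail_scan(st, pt, r, exclude_id = 1L))
    if (nrow(q1)) expect_true(all(q1$id != 1L))
  }
})

test_that("an encounter directs a counterclockwise (left) turn", {
  # advancing filament meets a perpendicular obstacle across its course
  sc <- generate_plate_scenario("two-filament-encounter", seed = 2,
                                duration_s = 2400, doubling_time_s = NA,
                                kappa = 0)
  st <- simulate_plate(sc)
  f1 <- st$filaments[[1]]
  expect_gt(f1$h_hi, 0)               # net counterclockwise rotation
  # encounter resolution keeps the two sheath trails a full deposit
  # radius apart at every deposited point
  t1 <- glidekin:::fil_trail_points(f1)
  t2 <- glidekin:::fil_trail_points(st$filaments[[2]])
  mind <- min(vapply(seq_len(nrow(t1)), function(i)
    min(sqrt((t2[, 1] - t1[i, 1])^2 + (t2[, 2] - t1[i, 2])^2)),
    numeric(1)))
  expect_gt(mind, st$filaments[[2]]$width / 2)
})

test_that("no obstruction leaves the heading unchanged; enclosure stalls", {
  sub <- agar_to_params(1.5)
  f1 <- new_filament(c(0, 0), 0, 50, sub$kinetics, id = 1L)
  st <- plate_state(list(f1), sub, seed = 3)
  res <- resolve_encounter(st, f1, heading = 0)
  expect_equal(res$turned, 0)
  expect_false(res$stalled)
  # box the filament in with obstacles in every trial direction
  ring <- lapply(1:12, function(i) {
    ang <- 2 * pi * i / 12
    new_filament(28 * c(cos(ang), sin(ang)), ang + pi / 2, 18,
                 sub$kinetics, width = 12, id = i + 1L)
  })
  st2 <- plate_state(c(list(f1), ring), sub, seed = 3)
  res2 <- resolve_encounter(st2, f1, heading = 0)
  expect_true(res2$stalled)
  # a stalled filament does not advance past its trail end
  arc0 <- glidekin:::fil_arc_max(f1)
  s0 <- f1$s_hi
  f1$next_reversal <- Inf
  f1$s_lo <- f1$s_lo + (arc0 - s0)    # put the tip at the trail end
  f1$s_hi <- arc0
  plate_step(st2, 5)
  expect_true(f1$stalled)
  expect_equal(f1$s_hi, arc0)
})

test_that("simulations are reproducible for a fixed seed", {
  sc <- generate_plate_scenario("plug", seed = 7, duration_s = 1800,
                                n_filaments = 4)
  v1 <- vertices_table(simulate_plate(sc))
  v2 <- vertices_table(simulate_plate(sc))
  expect_identical(v1, v2)
})
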