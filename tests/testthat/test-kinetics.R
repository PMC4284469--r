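test_that("instantaneous speed matches the closed-form decay law", {
  p <- kinetic_params(v_term = 0.169, v_max = 0.385, tau = 99)
  expect_equal(instantaneous_speed(p, 0), 0.385)              # exp(0) = 1
  expect_equal(instantaneous_speed(p, 1e6), 0.169,
               tolerance = 1e-12)                             # asymptote
  p01 <- kinetic_params(0, 1, 100)
  expect_equal(instantaneous_speed(p01, 100), exp(-1), tolerance = 1e-12)
  # vectorized, bounded, strictly decreasing
  t <- seq(0, 2000, by = 7)
  v <- instantaneous_speed(p, t)
  expect_true(all(v <= p$v_max & v >= p$v_term))
  expect_true(all(diff(v) < 0))
  expect_error(instantaneous_speed(p, -1), "non-negative")
})

test_that("kinetic parameter invariants are enforced", {
  expect_error(kinetic_params(-0.1, 0.3, 99), "v_term")
  expect_error(kinetic_params(0.2, 0.1, 99), "v_max")
  expect_error(kinetic_params(0.1, 0.3, 0), "tau")
  expect_error(kinetic_params(0.1, 0.3, 99, period_min = 600,
                              period_max = 300), "period")
})

test_that("cycle-average speed agrees with quadrature and is ordered", {
  p <- kinetic_params(0.169, 0.385, 99)
  for (dur in c(120, 450, 900)) {
    expect_equal(cycle_average_speed(p, dur), oracle_cycle_average(p, dur),
                 tolerance = 1e-8)
  }
  # constant integrand
  pc <- kinetic_params(0.2, 0.2, 50)
  expect_equal(cycle_average_speed(pc, 37), 0.2)
  # closed-form special case: v_term = 0, T = tau -> 1 - 1/e
  p01 <- kinetic_params(0, 1, 100)
  expect_equal(cycle_average_speed(p01, 100), 1 - exp(-1), tolerance = 1e-12)
  # strictly between v_term and v_max; decreasing in T, increasing in tau
  avg <- cycle_average_speed(p, c(100, 200, 400, 800))
  expect_true(all(avg > p$v_term & avg < p$v_max))
  expect_true(all(diff(avg) < 0))
  taus <- c(50, 99, 150, 300)
  avg_tau <- vapply(taus, function(tu)
    cycle_average_speed(kinetic_params(0.169, 0.385, tu), 450), numeric(1))
  expect_true(all(diff(avg_tau) > 0))
  expect_error(cycle_average_speed(p, 0), "positive")
})

test_that("v_max inversion reproduces the printed condition means", {
  # bisection oracle on the quadrature route vs the closed-form inverse
  vm1 <- solve_vmax_for_average(0.169, 99, 450, 0.216)
  expect_equal(vm1, oracle_solve_vmax(0.169, 99, 450, 0.216),
               tolerance = 1e-6)
  expect_equal(vm1, 0.385, tolerance = 2e-3)
  vm2 <- solve_vmax_for_average(0.148, 108, 450, 0.162)
  expect_equal(vm2, oracle_solve_vmax(0.148, 108, 450, 0.162),
               tolerance = 1e-6)
  expect_equal(vm2, 0.207, tolerance = 2e-3)
  # degenerate constant-speed solution and infeasibility
  expect_equal(solve_vmax_for_average(0.2, 99, 450, 0.2), 0.2)
  expect_error(solve_vmax_for_average(0.2, 99, 450, 0.1), "infeasible")
})

test_that("average/inversion round trip is the identity in v_max", {
  set.seed(421)
  for (i in 1:25) {
    v_term <- runif(1, 0, 0.3)
    v_max <- v_term + runif(1, 0.001, 0.5)
    tau <- runif(1, 10, 300)
    dur <- runif(1, 60, 1200)
    p <- kinetic_params(v_term, v_max, tau)
    target <- cycle_average_speed(p, dur)
    expect_equal(solve_vmax_for_average(v_term, tau, dur, target), v_max,
                 tolerance = 1e-6)
  }
})
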