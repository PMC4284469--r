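# Independent oracles used across the suite.  These deliberately use
# brute-force/quadrature routes distinct from the package implementation.

# Cycle-average speed by numerical quadrature of the instantaneous law on a
# fine grid (trapezoid rule).
oracle_cycle_average <- function(params, duration, n = 20001) {
  t <- seq(0, duration, length.out = n)
  v <- params$v_term + (params$v_max - params$v_term) * exp(-t / params$tau)
  sum((v[-1] + v[-n]) / 2 * diff(t)) / duration
}

# Invert the cycle average in v_max by bisection on the quadrature oracle.
oracle_solve_vmax <- function(v_term, tau, duration, target, tol = 1e-10) {
  f <- function(vm) {
    p <- kinetic_params(v_term, vm, tau)
    oracle_cycle_average(p, duration) - target
  }
  lo <- v_term; hi <- v_term + 10 * (target - v_term + 1)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

# Analytic CDF of the pooled speed distribution (noise-free): a cycle is
# chosen with probability proportional to its duration T ~ U(pmin, pmax),
# an observation time uniformly within it, and the decay law evaluated.
# P(V <= v) = E[(T - t_v)_+] / E[T] with t_v = -tau log((v - v_term)/dv).
oracle_pooled_speed_cdf <- function(params) {
  pmin <- params$period_min; pmax <- params$period_max
  dv <- params$v_max - params$v_term
  ET <- (pmin + pmax) / 2
  function(v) {
    vapply(v, function(vi) {
      if (vi <= params$v_term) return(0)
      if (vi >= params$v_max) return(1)
      tv <- -params$tau * log((vi - params$v_term) / dv)
      if (tv >= pmax) return(0)
      a <- max(pmin, tv)
      ((pmax - tv)^2 - (a - tv)^2) / 2 / (pmax - pmin) / ET
    }, numeric(1))
  }
}

# The same CDF by brute-force Monte-Carlo-free quadrature over the cycle
# duration distribution (used once to validate the closed form).
oracle_pooled_speed_cdf_quad <- function(params, v, n = 4001) {
  pmin <- params$period_min; pmax <- params$period_max
  Tg <- seq(pmin, pmax, length.out = n)
  w <- Tg / mean(Tg)                    # length-biased weight, f(T) uniform
  dv <- params$v_max - params$v_term
  vapply(v, function(vi) {
    if (vi <= params$v_term) return(0)
    if (vi >= params$v_max) return(1)
    tv <- -params$tau * log((vi - params$v_term) / dv)
    p_in <- pmax(0, Tg - tv) / Tg       # P(t_obs >= tv | T)
    mean(w * p_in)
  }, numeric(1))
}

# Exhaustive-scan oracle for trail queries.
oracle_trail_scan <- function(state, point, r, exclude_id = NULL) {
  hits <- 0L
  for (f in state$filaments) {
    if (!is.null(exclude_id) && f$id == exclude_id) next
    tp <- glidekin:::fil_trail_points(f)
    for (i in seq_len(nrow(tp))) {
      if (sqrt(sum((tp[i, ] - point)^2)) <= r) hits <- hits + 1L
    }
  }
  hits
}

# Noise-free single-cycle samples from the decay law.
law_cycle <- function(params, duration, dt = 1) {
  t <- seq(0, duration, by = dt)
  list(t_rel = t, speed = instantaneous_speed(params, t),
       duration = duration)
}

anchor_15 <- function() agar_to_params(1.5)$kinetics
anchor_20 <- function() agar_to_params(2.0)$kinetics
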