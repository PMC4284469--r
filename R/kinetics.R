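#' Kinetic parameters of the post-reversal speed law
#'
#' Gliding filaments of *Phormidium*-like cyanobacteria move back and forth,
#' and the tip speed is maximal immediately after each reversal of direction,
#' then declines exponentially towards a terminal value before the next
#' reversal.  The minimal law consistent with that observation is the offset
#' exponential
#' \deqn{v(t) = v_{term} + (v_{max} - v_{term})\, e^{-t/\tau},}
#' where \eqn{t} is the time since the last reversal.  This constructor
#' bundles the parameters of that law together with the range of
#' reversal-to-reversal intervals.
#'
#' @param v_term terminal (asymptotic) speed, µm/s; must be >= 0.
#' @param v_max speed immediately after a reversal, µm/s; must be >= `v_term`.
#' @param tau e-folding time constant of the decline, s; must be > 0.
#' @param period_min,period_max bounds of the reversal-to-reversal interval,
#'   s.  Defaults 300 and 600 s (the observed 5--10 min range).
#'
#' @return An object of class `"kinetic_params"`: a list with fields
#'   `v_term`, `v_max`, `tau`, `period_min`, `period_max`.
#' @seealso [instantaneous_speed()], [cycle_average_speed()],
#'   [solve_vmax_for_average()], [agar_to_params()]
#' @examples
#' p <- kinetic_params(v_term = 0.169, v_max = 0.385, tau = 99)
#' instantaneous_speed(p, c(0, 99, 450))
#' @export
kinetic_params <- function(v_term, v_max, tau, period_min = 300,
                           period_max = 600) {
  stopifnot(is.numeric(v_term), is.numeric(v_max), is.numeric(tau),
            length(v_term) == 1L, length(v_max) == 1L, length(tau) == 1L)
  if (!is.finite(v_term) || v_term < 0)
    stop("'v_term' must be a finite non-negative speed")
  if (!is.finite(v_max) || v_max < v_term)
    stop("'v_max' must be finite and >= v_term")
  if (!is.finite(tau) || tau <= 0)
    stop("'tau' must be a finite positive time constant")
  if (!is.finite(period_min) || !is.finite(period_max) ||
      period_min <= 0 || period_max < period_min)
    stop("reversal periods must satisfy 0 < period_min <= period_max")
  structure(list(v_term = v_term, v_max = v_max, tau = tau,
                 period_min = period_min, period_max = period_max),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Post-reversal speed law v(t) = v_term + (v_max - v_term) exp(-t/tau)\n")
  cat(sprintf("  v_max:  %.4g um/s\n", x$v_max))
  cat(sprintf("  v_term: %.4g um/s\n", x$v_term))
  cat(sprintf("  tau:    %.4g s\n", x$tau))
  cat(sprintf("  reversal interval: %g-%g s\n", x$period_min, x$period_max))
  invisible(x)
}

#' Instantaneous speed under the post-reversal decay law
#'
#' Evaluates \eqn{v(t) = v_{term} + (v_{max} - v_{term}) e^{-t/\tau}} at one
#' or more times since the last reversal.
#'
#' @param params a [kinetic_params()] object.
#' @param t time(s) since the last reversal, s; all values must be >= 0.
#' @return numeric vector of speeds (µm/s), each in `[v_term, v_max]`.
#' @export
instantaneous_speed <- function(params, t) {
  stopifnot(inherits(params, "kinetic_params"), is.numeric(t))
  if (any(!is.finite(t)) || any(t < 0))
    stop("'t' (time since reversal) must be finite and non-negative")
  params$v_term + (params$v_max - params$v_term) * exp(-t / params$tau)
}

#' Average speed over one reversal cycle
#'
#' Time average of the decay law over a cycle of duration `duration`:
#' \deqn{\bar v(T) = v_{term} + (v_{max} - v_{term})\frac{\tau}{T}
#'   \left(1 - e^{-T/\tau}\right).}
#' This links the per-instant speed law to pooled mean speeds measured over
#' whole recordings.
#'
#' @param params a [kinetic_params()] object.
#' @param duration cycle duration(s) T, s; must be > 0.
#' @return numeric vector of mean speeds, strictly between `v_term` and
#'   `v_max` whenever `v_max > v_term`.
#' @export
cycle_average_speed <- function(params, duration) {
  stopifnot(inherits(params, "kinetic_params"), is.numeric(duration))
  if (any(!is.finite(duration)) || any(duration <= 0))
    stop("cycle 'duration' must be finite and positive")
  dv <- params$v_max - params$v_term
  params$v_term + dv * (params$tau / duration) *
    (1 - exp(-duration / params$tau))
}

#' Solve for the post-reversal maximum speed given a target mean
#'
#' Inverts [cycle_average_speed()] in its `v_max` argument: returns the
#' `v_max` for which the cycle-average speed over a cycle of duration
#' `duration` equals `target_mean`.  Because the cycle average is affine in
#' `v_max`, the inverse is closed form:
#' \deqn{v_{max} = v_{term} + (\bar v - v_{term}) \big/
#'   \left[\tfrac{\tau}{T}(1 - e^{-T/\tau})\right].}
#' Used to pin down the (unreported) post-reversal maximum from a measured
#' condition mean speed.
#'
#' @param v_term terminal speed, µm/s.
#' @param tau time constant, s (> 0).
#' @param duration reference cycle duration T, s (> 0).
#' @param target_mean desired cycle-average speed, µm/s; must be >=
#'   `v_term`.
#' @return the solving `v_max` (µm/s).  `target_mean == v_term` returns
#'   `v_term` (constant-speed degenerate case).
#' @examples
#' # 1.5% agar: terminal 0.169 um/s, tau 99 s, condition mean 0.216 um/s
#' solve_vmax_for_average(0.169, 99, 450, 0.216)
#' @export
solve_vmax_for_average <- function(v_term, tau, duration, target_mean) {
  stopifnot(is.numeric(v_term), is.numeric(tau), is.numeric(duration),
            is.numeric(target_mean))
  if (v_term < 0) stop("'v_term' must be non-negative")
  if (tau <= 0 || duration <= 0) stop("'tau' and 'duration' must be positive")
  if (target_mean < v_term)
    stop("infeasible: 'target_mean' is below 'v_term' (no v_max can reach it)")
  g <- (tau / duration) * (1 - exp(-duration / tau))
  v_term + (target_mean - v_term) / g
}
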