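## Seeded synthetic-data generators.
##
## No trajectory recordings are distributed with the package; these
## generators stand in for the time-lapse data, producing tracks and pooled
## speed samples with the statistical structure the analysis pipeline
## assumes: back-and-forth motion with uniformly drawn reversal intervals,
## speed decaying exponentially from a post-reversal maximum to a terminal
## velocity, Gaussian tracking noise on positions, and log-normal-like
## pooled speed distributions.

#' Configuration for a synthetic track
#'
#' @param params a [kinetic_params()]; defaults to the 1.5%-agar condition
#'   from [agar_to_params()].
#' @param frame_dt frame interval, s (> 0); default 1 s.
#' @param duration recording duration, s; default 3600 s.
#' @param noise_sd i.i.d. Gaussian position noise SD per coordinate, µm
#'   (>= 0); default 0.05 µm, well below the per-frame displacement at 1 s
#'   intervals.
#' @param curvature path curvature, rad/µm (counterclockwise positive);
#'   default 0 (quasi-straight track).
#' @param origin,heading starting tip position (µm) and path heading (rad).
#' @param seed integer seed; identical seeds give identical tracks.
#' @return list of class `"track_gen_config"`.
#' @export
track_gen_config <- function(params = NULL, frame_dt = 1, duration = 3600,
                             noise_sd = 0.05, curvature = 0,
                             origin = c(0, 0), heading = 0, seed = NULL) {
  if (is.null(params)) params <- agar_to_params(1.5)$kinetics
  stopifnot(inherits(params, "kinetic_params"), frame_dt > 0, duration > 0,
            noise_sd >= 0, is.numeric(curvature), length(origin) == 2L)
  structure(list(params = params, frame_dt = frame_dt, duration = duration,
                 noise_sd = noise_sd, curvature = curvature,
                 origin = origin, heading = heading, seed = seed),
            class = "track_gen_config")
}

## Net distance travelled within a cycle after time dt since the reversal:
## the antiderivative of the decay law.
decay_displacement <- function(params, dt) {
  dv <- params$v_max - params$v_term
  params$v_term * dt + dv * params$tau * (1 - exp(-dt / params$tau))
}

#' Generate a synthetic tip track
#'
#' Integrates the post-reversal decay law along a path of constant
#' curvature, with scheduled reversals whose intervals are drawn uniformly
#' from the configured period range, and adds i.i.d. Gaussian noise to the
#' positions.  The ground-truth reversal times and parameters are returned
#' alongside the track, so analysis results can be checked against the
#' generator.
#'
#' @param cfg a [track_gen_config()].
#' @return list of class `"synthetic_track"` with components `track` (a
#'   [track()]), `reversals` (true reversal times, s), `params`, `config`.
#' @examples
#' st <- generate_track(track_gen_config(duration = 1800, seed = 42))
#' st$reversals
#' @export
generate_track <- function(cfg) {
  stopifnot(inherits(cfg, "track_gen_config"))
  p <- cfg$params
  with_seed(cfg$seed, {
    # reversal schedule covering the full duration
    intervals <- numeric(0)
    total <- 0
    while (total < cfg$duration) {
      it <- stats::runif(1, p$period_min, p$period_max)
      intervals <- c(intervals, it)
      total <- total + it
    }
    rev_times <- cumsum(intervals)
    reversals <- rev_times[rev_times < cfg$duration]
    cycle_starts <- c(0, reversals)
    n_cyc <- length(cycle_starts)
    dirs <- rep_len(c(1, -1), n_cyc)
    # arc coordinate at each cycle start
    cyc_len <- decay_displacement(p, diff(c(cycle_starts, cfg$duration)))
    full_len <- decay_displacement(p, intervals[seq_len(n_cyc)])
    s_start <- cumsum(c(0, (dirs * full_len)[-n_cyc]))
    times <- seq(0, cfg$duration, by = cfg$frame_dt)
    cyc <- findInterval(times, cycle_starts)
    phase <- times - cycle_starts[cyc]
    s <- s_start[cyc] + dirs[cyc] * decay_displacement(p, phase)
    # map arc coordinate onto a constant-curvature path
    u <- c(cos(cfg$heading), sin(cfg$heading))
    nl <- c(-sin(cfg$heading), cos(cfg$heading))   # left normal
    if (cfg$curvature == 0) {
      pos <- cbind(cfg$origin[1] + s * u[1], cfg$origin[2] + s * u[2])
    } else {
      k <- cfg$curvature
      pos <- cbind(
        cfg$origin[1] + (sin(k * s) / k) * u[1] + ((1 - cos(k * s)) / k) * nl[1],
        cfg$origin[2] + (sin(k * s) / k) * u[2] + ((1 - cos(k * s)) / k) * nl[2])
    }
    if (cfg$noise_sd > 0)
      pos <- pos + matrix(stats::rnorm(length(pos), 0, cfg$noise_sd),
                          ncol = 2L)
    structure(list(track = track(times, pos, reference = cfg$origin),
                   reversals = reversals, params = p, config = cfg),
              class = "synthetic_track")
  })
}

#' @export
print.synthetic_track <- function(x, ...) {
  cat(sprintf("Synthetic track: %d reversal(s) over %.0f s\n",
              length(x$reversals), x$config$duration))
  print(x$track)
  invisible(x)
}

#' Generate pooled speed samples
#'
#' Emulates pooling instantaneous speeds "over all time points" of a
#' fixed-rate recording: a cycle duration is drawn length-biased from the
#' uniform period range (longer cycles contribute proportionally more
#' frames), an observation time is drawn uniformly within the cycle, the
#' decay law is evaluated, and optional mean-preserving multiplicative
#' log-normal noise emulates measurement scatter.
#'
#' @param params a [kinetic_params()].
#' @param n number of samples (>= 1).
#' @param seed integer seed.
#' @param noise_cv coefficient of variation of the multiplicative noise;
#'   default 0.15; 0 disables noise.
#' @return numeric vector of `n` speeds, µm/s.
#' @examples
#' v <- generate_speed_samples(agar_to_params(1.5)$kinetics, 1e4, seed = 1)
#' mean(v)   # close to the 1.5%-agar condition mean 0.216 um/s
#' @export
generate_speed_samples <- function(params, n, seed = NULL, noise_cv = 0.15) {
  stopifnot(inherits(params, "kinetic_params"), is.numeric(n), n >= 1,
            noise_cv >= 0)
  n <- as.integer(n)
  with_seed(seed, {
    # length-biased cycle duration: density proportional to T on
    # [period_min, period_max]
    u <- stats::runif(n)
    T <- sqrt(params$period_min^2 +
                u * (params$period_max^2 - params$period_min^2))
    t_obs <- stats::runif(n) * T
    v <- instantaneous_speed(params, t_obs)
    if (noise_cv > 0) {
      sig <- sqrt(log(1 + noise_cv^2))
      v <- v * exp(stats::rnorm(n, -sig^2 / 2, sig))
    }
    v
  })
}
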