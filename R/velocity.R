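#' Signed tip velocity from a track
#'
#' Reduces the 2-D track to a signed 1-D coordinate — the arc-length
#' position along the track's own path, measured from the reference point —
#' and differentiates it: central finite differences at interior samples,
#' one-sided at the ends.  The path tangent is estimated at every sample by
#' local principal-component analysis of the positions in a sliding window
#' (a gliding filament retraces its sheath, so the local path is a stable,
#' nearly straight line even through reversals), its orientation is made
#' continuous in time, and each frame-to-frame displacement is projected
#' onto it; doubling back along the path flips the sign of the projection,
#' not of the tangent.  For a quasi-straight back-and-forth track the
#' coordinate coincides with the signed distance to the reference point,
#' but it generalizes to curved, sheath-guided paths.  An optional
#' moving-average smoother (default window 3 frames) suppresses tracking
#' noise before reversal detection.
#'
#' @param track a [track()].
#' @param window odd moving-average window length in frames (1 = no
#'   smoothing); default 3.
#' @param tangent_window odd window length (frames) for the local-PCA
#'   tangent estimate; default 9.  Should stay well below the number of
#'   frames over which the path bends appreciably.
#' @return an object of class `"velocity_series"`: list with `times` (s),
#'   `v` (signed velocity, µm/s, same length as the track) and `window`.
#' @export
compute_velocity <- function(track, window = 3, tangent_window = 9) {
  stopifnot(inherits(track, "track"), is.numeric(window), window >= 1,
            is.numeric(tangent_window), tangent_window >= 3)
  window <- as.integer(window)
  tangent_window <- as.integer(tangent_window)
  if (window %% 2L == 0L) stop("'window' must be odd")
  if (tangent_window %% 2L == 0L) stop("'tangent_window' must be odd")
  p <- track$positions
  tt <- track$times
  n <- nrow(p)
  theta <- local_tangent_angle(p, tangent_window)
  # orientation continuity: tangents are defined mod pi; flip whenever the
  # new direction opposes the previous one
  u <- cbind(cos(theta), sin(theta))
  dots <- rowSums(u[-n, , drop = FALSE] * u[-1L, , drop = FALSE])
  flip <- cumprod(c(1, ifelse(dots < 0, -1, 1)))
  u <- u * flip
  d <- diff(p)                        # displacement vectors
  um <- (u[-n, , drop = FALSE] + u[-1L, , drop = FALSE])
  um <- um / pmax(sqrt(rowSums(um^2)), 1e-12)
  proj <- rowSums(d * um)             # signed step along the path
  x0 <- sqrt(sum((p[1L, ] - track$reference)^2))
  x <- x0 + cumsum(c(0, proj))
  v <- numeric(n)
  v[1L] <- (x[2L] - x[1L]) / (tt[2L] - tt[1L])
  v[n] <- (x[n] - x[n - 1L]) / (tt[n] - tt[n - 1L])
  i <- 2:(n - 1L)
  v[i] <- (x[i + 1L] - x[i - 1L]) / (tt[i + 1L] - tt[i - 1L])
  if (window > 1L && n > window) {
    sm <- stats::filter(v, rep(1 / window, window), sides = 2)
    keep <- !is.na(sm)
    v[keep] <- sm[keep]
  }
  structure(list(times = tt, v = v, window = window),
            class = "velocity_series")
}

## Local path tangent angle (mod pi) at every sample, by principal-component
## analysis of the positions in a centred sliding window.  Rolling moments
## are computed with running sums, so the whole series is vectorized.
local_tangent_angle <- function(p, win) {
  n <- nrow(p)
  win <- min(win, if (n %% 2L == 1L) n else n - 1L)
  half <- (win - 1L) %/% 2L
  roll <- function(z) {
    cs <- cumsum(c(0, z))
    lo <- pmax(seq_len(n) - half, 1L)
    hi <- pmin(seq_len(n) + half, n)
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  mx <- roll(p[, 1]); my <- roll(p[, 2])
  sxx <- roll(p[, 1]^2) - mx^2
  syy <- roll(p[, 2]^2) - my^2
  sxy <- roll(p[, 1] * p[, 2]) - mx * my
  0.5 * atan2(2 * sxy, sxx - syy)
}

#' @export
print.velocity_series <- function(x, ...) {
  cat(sprintf("Velocity series: %d samples, |v| mean %.3f um/s (window %d)\n",
              length(x$v), mean(abs(x$v)), x$window))
  invisible(x)
}

#' Detect direction reversals in a velocity series
#'
#' A reversal is a sign change of the (smoothed) velocity that exceeds
#' `hysteresis` in magnitude on both sides, i.e. the series passes from
#' beyond `+h` to beyond `-h` (or vice versa).  The reversal time is
#' linearly interpolated at the zero crossing.  The hysteresis guards
#' against noise-induced flutter near zero.
#'
#' @param vs a [compute_velocity()] result.
#' @param hysteresis velocity threshold, µm/s (>= 0); default 0.02.
#' @return numeric vector of reversal times, s (possibly empty).
#' @export
detect_reversals <- function(vs, hysteresis = 0.02) {
  stopifnot(inherits(vs, "velocity_series"), is.numeric(hysteresis),
            hysteresis >= 0)
  v <- vs$v
  tt <- vs$times
  idx <- which(abs(v) > hysteresis)
  if (length(idx) < 2L) return(numeric(0))
  s <- sign(v[idx])
  ch <- which(diff(s) != 0)
  out <- numeric(0)
  for (j in ch) {
    i1 <- idx[j]; i2 <- idx[j + 1L]
    kk <- i1:(i2 - 1L)
    cross <- kk[v[kk] * v[kk + 1L] <= 0]
    k <- if (length(cross)) cross[1L] else i1
    v0 <- v[k]; v1 <- v[k + 1L]
    frac <- if (v0 == v1) 0.5 else v0 / (v0 - v1)
    out <- c(out, tt[k] + frac * (tt[k + 1L] - tt[k]))
  }
  out
}

#' Segment a velocity series into reversal cycles
#'
#' One cycle per interval between consecutive reversals; the partial
#' stretches before the first and after the last reversal are excluded
#' (they lack a reversal anchor, so their decay phase is unknown).  Within
#' a cycle, speeds are `|v|` against time since the reversal, and the net
#' displacement is the trapezoid integral of the signed velocity (taken as
#' zero at the reversal instants).  Speed samples within `guard_frames`
#' frame intervals of either reversal are excluded from `t_rel`/`speed`
#' (finite differencing and smoothing straddle the reversal there, mixing
#' opposite-direction motion, which would bias the decay fit); they still
#' contribute to the displacement integral.
#'
#' @param vs a [compute_velocity()] result.
#' @param reversals sorted reversal times from [detect_reversals()].
#' @param guard_frames width of the excluded boundary band, in frame
#'   intervals; default 2 (a central difference plus a 3-frame smoother
#'   reach 2 frames across a reversal).
#' @return list of `"cycle_segment"` objects, each with `start`, `end`,
#'   `duration` (s), `t_rel` (s since reversal), `speed` (µm/s),
#'   `displacement_um`.
#' @export
segment_cycles <- function(vs, reversals, guard_frames = 2) {
  stopifnot(inherits(vs, "velocity_series"), guard_frames >= 0)
  if (length(reversals) < 2L) return(list())
  if (is.unsorted(reversals)) stop("'reversals' must be sorted")
  guard <- guard_frames * stats::median(diff(vs$times))
  out <- vector("list", length(reversals) - 1L)
  for (i in seq_len(length(reversals) - 1L)) {
    r0 <- reversals[i]; r1 <- reversals[i + 1L]
    inside <- vs$times > r0 & vs$times < r1
    t_in <- vs$times[inside]
    v_in <- vs$v[inside]
    t_all <- c(r0, t_in, r1)
    v_all <- c(0, v_in, 0)
    disp <- abs(sum(diff(t_all) * (utils::head(v_all, -1) +
                                     utils::tail(v_all, -1)) / 2))
    clean <- t_in >= r0 + guard & t_in <= r1 - guard
    out[[i]] <- structure(list(start = r0, end = r1, duration = r1 - r0,
                               t_rel = t_in[clean] - r0,
                               speed = abs(v_in[clean]),
                               displacement_um = disp),
                          class = "cycle_segment")
  }
  out
}
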