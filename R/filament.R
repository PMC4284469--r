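## Filament agents.
##
## A filament's centreline always lies along the sheath trail it has laid
## down, so each agent stores a single arc-length-parameterised polyline
## (the trail/path) made of straight segments of fixed length `seg`, and the
## body occupies a sliding interval [s_lo, s_hi] on it.  Gliding translates
## the interval; reversals flip the direction of travel; only when an end of
## the interval runs past the end of the stored path is new path laid down
## ("virgin substrate"), curving counterclockwise at rate kappa and subject
## to encounter resolution.  This makes back-and-forth retracing of the
## sheath exact, and arc length is conserved by construction.

#' Create a filament agent
#'
#' Builds a straight filament of the given length centred at `origin`,
#' pointing along `heading`.  The filament's sheath trail initially
#' coincides with its body.
#'
#' @param origin numeric length-2, centre position (µm, plate plane).
#' @param heading initial heading, rad (counterclockwise from +x).
#' @param length body arc length, µm (> 0).
#' @param params a [kinetic_params()] object governing its speed law.
#' @param width filament width, µm; the sheath-trail deposit radius is
#'   `width / 2`.
#' @param seg trail segment length, µm; must be below the deposit radius
#'   for trail-following stability.
#' @param id integer filament identifier.
#' @return an object of class `"filament"` (an environment; mutable).
#' @export
new_filament <- function(origin, heading, length, params, width = 5,
                         seg = 2, id = 1L) {
  stopifnot(is.numeric(origin), length(origin) == 2L, is.finite(heading),
            is.numeric(length), length > 0,
            inherits(params, "kinetic_params"), width > 0, seg > 0)
  npts <- as.integer(ceiling(length / seg)) + 1L
  slack <- 256L
  cap <- npts + 2L * slack
  pts <- matrix(NA_real_, nrow = cap, ncol = 2L)
  u <- c(cos(heading), sin(heading))
  span <- (npts - 1L) * seg
  start <- origin - (span / 2) * u
  r_lo <- slack + 1L
  idx <- seq_len(npts)
  pts[r_lo + idx - 1L, 1L] <- start[1] + (idx - 1L) * seg * u[1]
  pts[r_lo + idx - 1L, 2L] <- start[2] + (idx - 1L) * seg * u[2]
  fil <- new.env(parent = emptyenv())
  fil$pts <- pts
  fil$r_lo <- r_lo
  fil$r_hi <- r_lo + npts - 1L
  fil$arc1 <- -(r_lo - 1L) * seg   # arc coordinate of matrix row 1
  fil$seg <- seg
  fil$h_hi <- heading
  fil$h_lo <- heading + pi
  fil$s_lo <- (span - length) / 2
  fil$s_hi <- fil$s_lo + length
  fil$length <- length
  fil$direction <- 1L
  fil$phase <- 0
  fil$next_reversal <- NA_real_
  fil$params <- params
  fil$width <- width
  fil$id <- as.integer(id)
  fil$stalled <- FALSE
  class(fil) <- "filament"
  fil
}

fil_arc_min <- function(fil) fil$arc1 + (fil$r_lo - 1L) * fil$seg
fil_arc_max <- function(fil) fil$arc1 + (fil$r_hi - 1L) * fil$seg

## Interpolated point(s) on the path at arc coordinate(s) s.
fil_point_at <- function(fil, s) {
  r <- (s - fil$arc1) / fil$seg + 1
  r <- pmin(pmax(r, fil$r_lo), fil$r_hi)
  i0 <- pmin(floor(r), fil$r_hi - 1L)
  fr <- r - i0
  p0 <- fil$pts[i0, , drop = FALSE]
  p1 <- fil$pts[i0 + 1L, , drop = FALSE]
  p0 + fr * (p1 - p0)
}

## Deposited sheath-trail points (the stored path) as a matrix.
fil_trail_points <- function(fil) {
  fil$pts[fil$r_lo:fil$r_hi, , drop = FALSE]
}

## Grow the backing matrix so that `n_lo`/`n_hi` extra rows fit below/above.
fil_ensure_capacity <- function(fil, n_lo = 0L, n_hi = 0L) {
  cap <- nrow(fil$pts)
  need_lo <- n_lo - (fil$r_lo - 1L)
  need_hi <- n_hi - (cap - fil$r_hi)
  if (need_lo <= 0L && need_hi <= 0L) return(invisible(fil))
  n_used <- fil$r_hi - fil$r_lo + 1L
  slack <- max(256L, n_lo, n_hi, n_used)
  new_cap <- n_used + 2L * slack
  new_pts <- matrix(NA_real_, nrow = new_cap, ncol = 2L)
  new_lo <- slack + 1L
  new_pts[new_lo:(new_lo + n_used - 1L), ] <-
    fil$pts[fil$r_lo:fil$r_hi, , drop = FALSE]
  fil$arc1 <- fil_arc_min(fil) - (new_lo - 1L) * fil$seg
  fil$r_lo <- new_lo
  fil$r_hi <- new_lo + n_used - 1L
  fil$pts <- new_pts
  invisible(fil)
}

## Lay down new path beyond one end.
##
## end = +1 appends beyond the high-arc end, end = -1 prepends below the
## low-arc end.  `ds` is the arc length requested; extension happens in
## whole segments (possibly overshooting by < seg, which simply deposits
## trail slightly ahead of the tip).  On virgin substrate the path turns
## counterclockwise AS A SPATIAL CURVE at rate kappa: its low-to-high
## tangent angle increases by kappa*seg per segment.  The turning sense is
## fixed in the filament's body frame (the anatomical chirality of the
## helical mucilage flow), not relative to the travel direction, so
## extension at the low end rotates the outward motion heading by
## -kappa*seg — this is what makes whole filaments curl with one handedness
## and wind into counterclockwise spirals instead of S-shapes.
## `blocked(p0, p1)`, if given, reports whether a candidate segment hits an
## obstacle; the heading is then rotated counterclockwise (a left turn for
## the advancing tip) in `turn_inc` increments up to `max_turn`, after
## which the filament stalls.  Returns the arc length actually added.
fil_extend <- function(fil, end, ds, kappa = 0, blocked = NULL,
                       turn_inc = 5 * pi / 180, max_turn = 170 * pi / 180) {
  seg <- fil$seg
  n_add <- as.integer(ceiling(ds / seg - 1e-9))
  if (n_add <= 0L) return(0)
  if (end > 0) fil_ensure_capacity(fil, n_hi = n_add)
  else fil_ensure_capacity(fil, n_lo = n_add)
  added <- 0
  max_k <- as.integer(floor(max_turn / turn_inc + 1e-9))
  for (j in seq_len(n_add)) {
    h <- if (end > 0) fil$h_hi + kappa * seg else fil$h_lo - kappa * seg
    r_end <- if (end > 0) fil$r_hi else fil$r_lo
    p0 <- fil$pts[r_end, ]
    ok <- FALSE
    h_try <- h
    for (k in 0:max_k) {
      h_try <- h + k * turn_inc
      p1 <- p0 + seg * c(cos(h_try), sin(h_try))
      if (is.null(blocked) || !blocked(p0, p1)) { ok <- TRUE; break }
    }
    if (!ok) { fil$stalled <- TRUE; break }
    if (end > 0) {
      fil$r_hi <- fil$r_hi + 1L
      fil$pts[fil$r_hi, ] <- p1
      fil$h_hi <- h_try
    } else {
      fil$r_lo <- fil$r_lo - 1L
      fil$pts[fil$r_lo, ] <- p1
      fil$h_lo <- h_try
    }
    added <- added + seg
  }
  added
}

#' Grow a filament by cell division
#'
#' Multiplies the body arc length by `2^(dt / doubling_time)`, appending the
#' new length equally at both ends.  Where an end runs past the stored
#' sheath trail, new trail is laid down (curving counterclockwise at rate
#' `kappa`, subject to the same encounter resolution as gliding); an
#' obstructed end stalls and that half of the growth is deferred.
#'
#' @param filament a [new_filament()] object (modified in place and
#'   returned).
#' @param dt elapsed time, s (>= 0).
#' @param doubling_time doubling time of the exponential elongation, s
#'   (> 0).
#' @param kappa curvature rate on virgin substrate, rad/µm.
#' @param blocked optional obstacle predicate `function(p0, p1)`; used by
#'   the plate simulator.
#' @return the filament, invisibly.
#' @export
grow <- function(filament, dt, doubling_time, kappa = 0, blocked = NULL) {
  stopifnot(inherits(filament, "filament"), is.numeric(dt), dt >= 0,
            is.numeric(doubling_time), doubling_time > 0)
  if (dt == 0) return(invisible(filament))
  d_l <- filament$length * (2^(dt / doubling_time) - 1)
  half <- d_l / 2
  # low end
  target_lo <- filament$s_lo - half
  if (target_lo < fil_arc_min(filament)) {
    fil_extend(filament, -1L, fil_arc_min(filament) - target_lo,
               kappa = kappa, blocked = blocked)
  }
  filament$s_lo <- max(target_lo, fil_arc_min(filament))
  # high end
  target_hi <- filament$s_hi + half
  if (target_hi > fil_arc_max(filament)) {
    fil_extend(filament, 1L, target_hi - fil_arc_max(filament),
               kappa = kappa, blocked = blocked)
  }
  filament$s_hi <- min(target_hi, fil_arc_max(filament))
  filament$length <- filament$s_hi - filament$s_lo
  invisible(filament)
}

#' Body vertices of a filament
#'
#' Samples the occupied interval of the filament's path, returning an
#' ordered polyline from tail-end to head-end of the arc-length interval.
#' Path nodes interior to the body are always included, so the polyline arc
#' length equals the body length exactly; additional vertices are inserted
#' if a finer `spacing` is requested.
#'
#' @param filament a filament.
#' @param spacing maximum vertex spacing, µm; default the trail segment
#'   length.
#' @return numeric matrix with columns `x`, `y` (µm), at least 2 rows.
#' @export
filament_vertices <- function(filament, spacing = NULL) {
  stopifnot(inherits(filament, "filament"))
  seg <- filament$seg
  if (is.null(spacing)) spacing <- seg
  arcs <- filament$arc1 + (seq(filament$r_lo, filament$r_hi) - 1L) * seg
  inner <- arcs[arcs > filament$s_lo + 1e-12 & arcs < filament$s_hi - 1e-12]
  s_vals <- c(filament$s_lo, inner, filament$s_hi)
  if (spacing < seg) {
    refined <- unlist(lapply(seq_len(length(s_vals) - 1L), function(i) {
      n <- ceiling((s_vals[i + 1L] - s_vals[i]) / spacing)
      seq(s_vals[i], s_vals[i + 1L], length.out = max(2L, n + 1L))[-1L]
    }))
    s_vals <- c(s_vals[1L], refined)
  }
  v <- fil_point_at(filament, s_vals)
  colnames(v) <- c("x", "y")
  v
}

#' @export
print.filament <- function(x, ...) {
  cat(sprintf(
    "Filament %d: length %.1f um, width %.1f um, %s end leading, phase %.0f s\n",
    x$id, x$length, x$width,
    if (x$direction > 0) "high-arc" else "low-arc", x$phase))
  cat(sprintf("  trail: %d points, %.1f um laid down\n",
              x$r_hi - x$r_lo + 1L, fil_arc_max(x) - fil_arc_min(x)))
  invisible(x)
}
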