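## Plate-level simulation.
##
## Rule set (the helical-flow rotation model, reduced to the plane):
##  * each filament glides back and forth, its tip speed following the
##    post-reversal decay law, with reversal intervals drawn uniformly from
##    the configured range;
##  * within its own sheath trail the filament is guided and simply retraces
##    the stored path;
##  * on virgin substrate the motion heading rotates counterclockwise at a
##    fixed rate kappa (the planar net effect of the clockwise axial
##    rotation driven by helical mucilage flow), and trail is deposited;
##  * a foreign trail or body blocks the way; the filament turns further
##    counterclockwise in fixed increments ("left turn on encounter") until
##    the path is clear, or stalls;
##  * filaments elongate exponentially by cell division, pushing both ends
##    into new territory.

#' Create a plate simulation state
#'
#' @param filaments list of [new_filament()] agents.
#' @param substrate a [agar_to_params()] object (or an agar concentration,
#'   which is converted).
#' @param encounters logical; resolve collisions with foreign trails and
#'   bodies (default `TRUE`).  Disabling is useful for single-filament
#'   kinematics checks.
#' @param doubling_time filament doubling time, s, or `NULL` for no growth.
#' @param turn_increment encounter turning increment, rad (default 5
#'   degrees).
#' @param max_turn maximum total encounter turn before stalling, rad
#'   (default 170 degrees).
#' @param seed integer seed for reversal scheduling; `NULL` uses the
#'   current RNG stream.
#' @return an object of class `"plate_state"` (an environment; mutable).
#' @seealso [plate_step()], [simulate_plate()], [detect_spirals()]
#' @export
plate_state <- function(filaments, substrate, encounters = TRUE,
                        doubling_time = NULL,
                        turn_increment = 5 * pi / 180,
                        max_turn = 170 * pi / 180, seed = NULL) {
  if (is.numeric(substrate)) substrate <- agar_to_params(substrate)
  stopifnot(inherits(substrate, "substrate_params"), is.list(filaments),
            length(filaments) >= 1L,
            all(vapply(filaments, inherits, logical(1), "filament")))
  state <- new.env(parent = emptyenv())
  state$filaments <- filaments
  state$substrate <- substrate
  state$clock <- 0
  state$encounters <- isTRUE(encounters)
  state$doubling_time <- doubling_time
  state$turn_increment <- turn_increment
  state$max_turn <- max_turn
  k <- substrate$kinetics
  with_seed(seed, {
    for (fil in state$filaments) {
      if (is.na(fil$next_reversal))
        fil$next_reversal <- stats::runif(1, k$period_min, k$period_max)
    }
  })
  class(state) <- "plate_state"
  state
}

## Obstacle predicate: does segment p0-p1 come within a foreign filament's
## trail deposit radius?  Bodies lie on their own trails, so trail points
## cover both trail and body obstacles.
plate_blocked <- function(state, self_id, p0, p1) {
  xmin <- min(p0[1], p1[1]); xmax <- max(p0[1], p1[1])
  ymin <- min(p0[2], p1[2]); ymax <- max(p0[2], p1[2])
  for (f in state$filaments) {
    if (f$id == self_id) next
    r <- f$width / 2
    tp <- f$pts
    sel <- which(tp[, 1] >= xmin - r & tp[, 1] <= xmax + r &
                 tp[, 2] >= ymin - r & tp[, 2] <= ymax + r)
    sel <- sel[sel >= f$r_lo & sel <= f$r_hi]
    if (length(sel) &&
        any(dist_point_segment(tp[sel, , drop = FALSE], p0, p1) <= r))
      return(TRUE)
  }
  FALSE
}

#' Query deposited sheath-trail points near a location
#'
#' Returns every trail point within radius `r` of `point`, with its owning
#' filament id and deposit radius.
#'
#' @param state a [plate_state()].
#' @param point numeric length-2 location, µm.
#' @param r query radius, µm.
#' @param exclude_id optional filament id whose trail is skipped.
#' @return data.frame with columns `id`, `x`, `y`, `deposit_radius`,
#'   `distance`.
#' @export
trail_query <- function(state, point, r, exclude_id = NULL) {
  stopifnot(inherits(state, "plate_state"), length(point) == 2L, r >= 0)
  out <- list()
  for (f in state$filaments) {
    if (!is.null(exclude_id) && f$id == exclude_id) next
    tp <- f$pts
    sel <- which(tp[, 1] >= point[1] - r & tp[, 1] <= point[1] + r &
                 tp[, 2] >= point[2] - r & tp[, 2] <= point[2] + r)
    sel <- sel[sel >= f$r_lo & sel <= f$r_hi]
    if (!length(sel)) next
    d <- sqrt((tp[sel, 1] - point[1])^2 + (tp[sel, 2] - point[2])^2)
    keep <- d <= r
    if (!any(keep)) next
    out[[length(out) + 1L]] <- data.frame(
      id = f$id, x = tp[sel[keep], 1], y = tp[sel[keep], 2],
      deposit_radius = f$width / 2, distance = d[keep])
  }
  if (!length(out))
    return(data.frame(id = integer(), x = numeric(), y = numeric(),
                      deposit_radius = numeric(), distance = numeric()))
  do.call(rbind, out)
}

#' Resolve an encounter by counterclockwise turning
#'
#' Given a filament's proposed motion heading, rotates it counterclockwise
#' in fixed increments until a trial step of one trail segment is clear of
#' foreign trails and bodies, or the maximum total turn is exhausted (the
#' filament then stalls).  With no obstruction the heading is returned
#' unchanged.
#'
#' @param state a [plate_state()].
#' @param filament the advancing filament (one of `state$filaments`).
#' @param heading proposed motion heading, rad; defaults to the filament's
#'   current leading-end extension heading.
#' @return list with `heading` (adjusted), `turned` (total counterclockwise
#'   rotation applied, rad) and `stalled` (logical).
#' @export
resolve_encounter <- function(state, filament, heading = NULL) {
  stopifnot(inherits(state, "plate_state"), inherits(filament, "filament"))
  if (is.null(heading))
    heading <- if (filament$direction > 0) filament$h_hi else filament$h_lo
  tip_s <- if (filament$direction > 0) filament$s_hi else filament$s_lo
  p0 <- drop(fil_point_at(filament, tip_s))
  seg <- filament$seg
  max_k <- as.integer(floor(state$max_turn / state$turn_increment + 1e-9))
  for (k in 0:max_k) {
    h_try <- heading + k * state$turn_increment
    p1 <- p0 + seg * c(cos(h_try), sin(h_try))
    if (!plate_blocked(state, filament$id, p0, p1))
      return(list(heading = h_try, turned = k * state$turn_increment,
                  stalled = FALSE))
  }
  list(heading = heading, turned = 0, stalled = TRUE)
}

#' Advance a plate simulation by one time step
#'
#' For each filament: the tip speed follows the post-reversal decay law and
#' the body translates along its sheath trail by `speed * dt`; when the
#' leading end runs past the stored trail, new trail is laid down, curving
#' counterclockwise on virgin substrate and turning left at encounters;
#' scheduled reversals flip the direction of travel, reset the speed phase
#' and draw the next interval uniformly from the configured range; if a
#' doubling time is set, the filament grows.  Arc length is conserved by
#' the move (growth is the only length change).
#'
#' @param state a [plate_state()]; modified in place.
#' @param dt time step, s; must satisfy the stability condition
#'   `v_max * dt < deposit radius` for every filament.
#' @return the state, invisibly.
#' @export
plate_step <- function(state, dt) {
  stopifnot(inherits(state, "plate_state"), is.numeric(dt), dt > 0)
  fils <- state$filaments
  many <- state$encounters && length(fils) > 1L
  for (fil in fils) {
    if (fil$params$v_max * dt >= fil$width / 2)
      stop("unstable configuration: v_max * dt must be below the trail ",
           "deposit radius (width / 2); reduce 'dt'")
  }
  kappa <- state$substrate$kappa
  t_new <- state$clock + dt
  for (fil in fils) {
    fil$stalled <- FALSE
    k <- fil$params
    v <- k$v_term + (k$v_max - k$v_term) * exp(-fil$phase / k$tau)
    ds <- v * dt
    blocked_fn <- if (many) {
      sid <- fil$id
      function(p0, p1) plate_blocked(state, sid, p0, p1)
    } else NULL
    if (fil$direction > 0L) {
      over <- fil$s_hi + ds - fil_arc_max(fil)
      if (over > 0)
        fil_extend(fil, 1L, over, kappa = kappa, blocked = blocked_fn,
                   turn_inc = state$turn_increment, max_turn = state$max_turn)
      ds_act <- min(ds, fil_arc_max(fil) - fil$s_hi)
      fil$s_lo <- fil$s_lo + ds_act
      fil$s_hi <- fil$s_hi + ds_act
    } else {
      over <- fil_arc_min(fil) - (fil$s_lo - ds)
      if (over > 0)
        fil_extend(fil, -1L, over, kappa = kappa, blocked = blocked_fn,
                   turn_inc = state$turn_increment, max_turn = state$max_turn)
      ds_act <- min(ds, fil$s_lo - fil_arc_min(fil))
      fil$s_lo <- fil$s_lo - ds_act
      fil$s_hi <- fil$s_hi - ds_act
    }
    fil$phase <- fil$phase + dt
    if (t_new >= fil$next_reversal) {
      fil$direction <- -fil$direction
      fil$phase <- 0
      fil$next_reversal <- t_new + stats::runif(1, k$period_min, k$period_max)
    }
    if (!is.null(state$doubling_time))
      grow(fil, dt, state$doubling_time, kappa = kappa, blocked = blocked_fn)
  }
  state$clock <- t_new
  invisible(state)
}

#' Run a plate scenario
#'
#' Builds a [plate_state()] from a scenario configuration (see
#' [generate_plate_scenario()] and [read_scenario_config()]) and steps it
#' for the configured duration.  All randomness (reversal scheduling) flows
#' from the scenario seed, so identical configurations reproduce identical
#' plates.
#'
#' @param scenario a scenario configuration list with fields `agar`,
#'   `kappa`, `width_um`, `seg_um`, `dt_s`, `duration_s`, `seed`,
#'   `doubling_time_s` (`NULL`/`NA` disables growth), `encounters`, and
#'   `inoculum` (list of `list(x_um, y_um, heading_rad, length_um)`).
#' @param record_tips logical; record the leading-tip position of every
#'   filament at every step (in `state$tip_history`).
#' @return the final [plate_state()]; `state$tip_history`, when recorded,
#'   is a list with `time_s` and per-filament `x`/`y` matrices.
#' @examples
#' sc <- generate_plate_scenario("sparse", seed = 1)
#' sc$duration_s <- 600
#' st <- simulate_plate(sc)
#' detect_spirals(st)
#' @export
simulate_plate <- function(scenario, record_tips = FALSE) {
  sc <- validate_scenario(scenario)
  substrate <- agar_to_params(sc$agar, kappa = sc$kappa)
  k <- substrate$kinetics
  fils <- lapply(seq_along(sc$inoculum), function(i) {
    ino <- sc$inoculum[[i]]
    new_filament(origin = c(ino$x_um, ino$y_um), heading = ino$heading_rad,
                 length = ino$length_um, params = k, width = sc$width_um,
                 seg = sc$seg_um, id = i)
  })
  dbl <- sc$doubling_time_s
  if (!is.null(dbl) && (!is.finite(dbl) || dbl <= 0)) dbl <- NULL
  n_steps <- as.integer(ceiling(sc$duration_s / sc$dt_s))
  tips <- NULL
  with_seed(sc$seed, {
    state <- plate_state(fils, substrate, encounters = sc$encounters,
                         doubling_time = dbl)
    if (record_tips) {
      m <- function() matrix(NA_real_, n_steps, length(fils))
      tips <- list(time_s = seq_len(n_steps) * sc$dt_s,
                   x = m(), y = m(),                  # leading tip
                   head_x = m(), head_y = m(),        # high-arc end
                   tail_x = m(), tail_y = m(),        # low-arc end
                   direction = matrix(NA_integer_, n_steps, length(fils)))
    }
    for (i in seq_len(n_steps)) {
      plate_step(state, sc$dt_s)
      if (record_tips) {
        for (j in seq_along(state$filaments)) {
          fil <- state$filaments[[j]]
          ph <- fil_point_at(fil, fil$s_hi)
          pt <- fil_point_at(fil, fil$s_lo)
          tips$head_x[i, j] <- ph[1]; tips$head_y[i, j] <- ph[2]
          tips$tail_x[i, j] <- pt[1]; tips$tail_y[i, j] <- pt[2]
          lead <- if (fil$direction > 0) ph else pt
          tips$x[i, j] <- lead[1]; tips$y[i, j] <- lead[2]
          tips$direction[i, j] <- fil$direction
        }
      }
    }
  })
  state$scenario <- sc
  if (record_tips) state$tip_history <- tips
  state
}

#' Classify spirals on a plate
#'
#' Computes, for every filament, the winding (the sum of signed turning
#' angles along its body polyline; counterclockwise positive) and classifies
#' it as a spiral when `|winding| >= 2 * pi * min_turns` and the diameter of
#' its vertex set is below `diameter_frac` of its arc length (a wound-up
#' body is compact relative to its length).  On submerged substrates
#' (< 1.1% agar) spiral classification is disabled: windings are still
#' reported but no filament is classified as a spiral.
#'
#' @param state a [plate_state()], or a list of filaments plus `substrate`.
#' @param min_turns minimum number of full turns, default 2.
#' @param diameter_frac compactness threshold, default 0.5.
#' @return data.frame with columns `id`, `winding` (rad), `length_um`,
#'   `diameter_um`, `spiral` (logical); attribute `submerged` records
#'   whether classification was disabled.
#' @export
detect_spirals <- function(state, min_turns = 2, diameter_frac = 0.5) {
  stopifnot(inherits(state, "plate_state"), min_turns > 0)
  submerged <- state$substrate$submerged
  rows <- lapply(state$filaments, function(fil) {
    v <- filament_vertices(fil)
    w <- polyline_winding(v)
    diam <- point_set_diameter(v)
    data.frame(id = fil$id, winding = w, length_um = fil$length,
               diameter_um = diam,
               spiral = !submerged &&
                 abs(w) >= 2 * pi * min_turns &&
                 diam < diameter_frac * fil$length)
  })
  out <- do.call(rbind, rows)
  attr(out, "submerged") <- submerged
  out
}

#' Winding (total signed turning) of a polyline
#'
#' Sum of the signed heading changes between consecutive segments,
#' counterclockwise positive; a straight polyline has winding 0, a closed
#' counterclockwise loop about `2 * pi`.
#'
#' @param vertices numeric matrix with >= 3 rows (x, y).
#' @return total turning, rad.
#' @export
polyline_winding <- function(vertices) {
  stopifnot(is.matrix(vertices), nrow(vertices) >= 3L)
  dx <- diff(vertices[, 1]); dy <- diff(vertices[, 2])
  keep <- dx != 0 | dy != 0
  h <- atan2(dy[keep], dx[keep])
  if (length(h) < 2L) return(0)
  sum(wrap_angle(diff(h)))
}

#' Per-vertex table of a plate state
#'
#' One row per body vertex of every filament, in the export schema used by
#' the command-line pipeline.
#'
#' @param state a [plate_state()].
#' @return data.frame with columns `filament`, `vertex`, `x_um`, `y_um`,
#'   `time_s`.
#' @export
vertices_table <- function(state) {
  stopifnot(inherits(state, "plate_state"))
  rows <- lapply(state$filaments, function(fil) {
    v <- filament_vertices(fil)
    data.frame(filament = fil$id, vertex = seq_len(nrow(v)),
               x_um = v[, 1], y_um = v[, 2], time_s = state$clock)
  })
  do.call(rbind, rows)
}

#' @export
print.plate_state <- function(x, ...) {
  cat(sprintf("Plate simulation: %d filament(s), clock %.0f s\n",
              length(x$filaments), x$clock))
  cat(sprintf("  substrate: %.2f%% agar%s, kappa = %g rad/um\n",
              x$substrate$concentration,
              if (x$substrate$submerged) " (submerged)" else "",
              x$substrate$kappa))
  lens <- vapply(x$filaments, function(f) f$length, numeric(1))
  cat(sprintf("  filament length: %.1f-%.1f um\n", min(lens), max(lens)))
  invisible(x)
}

#' @export
plot.plate_state <- function(x, ..., col = NULL, asp = 1) {
  vs <- lapply(x$filaments, filament_vertices)
  all <- do.call(rbind, vs)
  if (is.null(col)) col <- grDevices::hcl.colors(max(2L, length(vs)), "Dark 3")
  plot(NA, xlim = range(all[, 1]), ylim = range(all[, 2]), asp = asp,
       xlab = "x (um)", ylab = "y (um)",
       main = sprintf("Plate at t = %.0f s", x$clock), ...)
  for (i in seq_along(vs))
    graphics::lines(vs[[i]], col = col[(i - 1L) %% length(col) + 1L],
                    lwd = 2)
  invisible(x)
}
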