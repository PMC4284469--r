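#' Full measurement pipeline for one track
#'
#' Chains the analysis steps applied to each time-lapse track: signed
#' velocity ([compute_velocity()]), reversal detection
#' ([detect_reversals()]), cycle segmentation ([segment_cycles()]), the
#' decay-law fit ([fit_decay()]), the pooled speed-distribution summary
#' ([summarize_distribution()]) and the displacement-duration table.
#'
#' @param trk a [track()].
#' @param window velocity smoothing window, frames.
#' @param hysteresis reversal-detection hysteresis, µm/s.
#' @param fit_mode [fit_decay()] mode.
#' @return an object of class `"track_analysis"`: list with `velocity`,
#'   `reversals`, `cycles`, `fit` (`NULL` when fewer than one full cycle is
#'   available), `distribution`, `displacement`.
#' @export
analyze_track <- function(trk, window = 3, hysteresis = 0.02,
                          fit_mode = "pooled") {
  stopifnot(inherits(trk, "track"))
  vs <- compute_velocity(trk, window = window)
  revs <- detect_reversals(vs, hysteresis = hysteresis)
  cycles <- segment_cycles(vs, revs)
  fit <- if (length(cycles))
    tryCatch(fit_decay(cycles, mode = fit_mode), error = function(e) NULL)
  else NULL
  disp <- if (length(cycles)) displacement_duration_table(cycles) else NULL
  structure(list(velocity = vs, reversals = revs, cycles = cycles,
                 fit = fit, distribution = summarize_distribution(vs),
                 displacement = disp),
            class = "track_analysis")
}

#' @export
print.track_analysis <- function(x, ...) {
  cat(sprintf("Track analysis: %d reversal(s), %d full cycle(s)\n",
              length(x$reversals), length(x$cycles)))
  if (!is.null(x$fit)) print(x$fit)
  invisible(x)
}
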