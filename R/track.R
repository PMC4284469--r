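#' Construct a tip trajectory
#'
#' A track is the timestamped 2-D position of one filament tip, as produced
#' by time-lapse tracking.
#'
#' @param times sample times, s; strictly increasing, length >= 3.
#' @param positions numeric matrix (n x 2) of tip positions, µm.
#' @param reference optional length-2 reference point, µm, fixing the origin
#'   of the signed 1-D coordinate (defaults to the first position).
#' @return an object of class `"track"`: list with `times`, `positions`,
#'   `reference`.
#' @export
track <- function(times, positions, reference = NULL) {
  times <- as.numeric(times)
  positions <- as.matrix(positions)
  if (length(times) < 3L) stop("a track needs at least 3 samples")
  if (!all(is.finite(times)) || any(diff(times) <= 0))
    stop("track 'times' must be finite and strictly increasing ",
         "(duplicate timestamps are invalid)")
  if (nrow(positions) != length(times) || ncol(positions) != 2L ||
      !all(is.finite(positions)))
    stop("'positions' must be a finite n x 2 matrix matching 'times'")
  if (is.null(reference)) reference <- positions[1L, ]
  structure(list(times = times, positions = positions,
                 reference = as.numeric(reference)),
            class = "track")
}

#' @export
print.track <- function(x, ...) {
  n <- length(x$times)
  cat(sprintf("Track: %d samples over %.0f s, frame interval %.2f s (median)\n",
              n, x$times[n] - x$times[1], stats::median(diff(x$times))))
  invisible(x)
}

#' Read a track from CSV
#'
#' Expects the header `frame,time_s,x_um,y_um` (one file per filament) and
#' validates monotone time.
#'
#' @param path CSV file path.
#' @param reference optional reference point, µm.
#' @return a [track()].
#' @export
read_track_csv <- function(path, reference = NULL) {
  d <- utils::read.csv(path)
  need <- c("frame", "time_s", "x_um", "y_um")
  if (!all(need %in% names(d)))
    stop("track file ", path, " must have columns ",
         paste(need, collapse = ", "))
  track(d$time_s, cbind(d$x_um, d$y_um), reference = reference)
}

#' Write a track to CSV
#'
#' Writes the `frame,time_s,x_um,y_um` schema read by [read_track_csv()],
#' with fixed numeric formatting so identical tracks produce byte-identical
#' files.
#'
#' @param x a [track()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_track_csv <- function(x, path) {
  stopifnot(inherits(x, "track"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("frame,time_s,x_um,y_um", con)
  writeLines(sprintf("%d,%.6f,%.6f,%.6f", seq_along(x$times), x$times,
                     x$positions[, 1], x$positions[, 2]), con)
  invisible(path)
}
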