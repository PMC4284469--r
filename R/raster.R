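## Binary rasters of plate states and pixel-distance spread statistics.
##
## Raster convention: row-major, origin at the top-left; pixel (r, c) has
## its centre at x = x_min + (c - 0.5) * px (rightwards) and
## y = y_max - (r - 0.5) * px (plate y decreases down the rows).

#' Rasterize a plate state to a binary image
#'
#' Marks as foreground every pixel whose centre lies within `width / 2` of
#' any filament's body centreline.  Deterministic for a fixed state.
#'
#' @param state a [plate_state()].
#' @param pixel_size pixel edge length, µm (> 0).
#' @param padding margin added around the filament bounding box, µm;
#'   defaults to the largest filament width.
#' @return integer matrix (0 background, 1 filament) of class
#'   `"plate_raster"`, with attributes `pixel_size_um`, `x_min_um`,
#'   `y_max_um` fixing the plate-coordinate frame.
#' @export
rasterize <- function(state, pixel_size, padding = NULL) {
  stopifnot(inherits(state, "plate_state"), is.numeric(pixel_size),
            pixel_size > 0)
  widths <- vapply(state$filaments, function(f) f$width, numeric(1))
  if (is.null(padding)) padding <- max(widths)
  verts <- lapply(state$filaments, filament_vertices,
                  spacing = min(pixel_size, min(widths)) / 2)
  all <- do.call(rbind, verts)
  x_min <- min(all[, 1]) - padding
  x_max <- max(all[, 1]) + padding
  y_min <- min(all[, 2]) - padding
  y_max <- max(all[, 2]) + padding
  nc <- max(1L, as.integer(ceiling((x_max - x_min) / pixel_size)))
  nr <- max(1L, as.integer(ceiling((y_max - y_min) / pixel_size)))
  img <- matrix(0L, nrow = nr, ncol = nc)
  cx <- x_min + (seq_len(nc) - 0.5) * pixel_size
  cy <- y_max - (seq_len(nr) - 0.5) * pixel_size
  for (i in seq_along(verts)) {
    v <- verts[[i]]
    r <- widths[i] / 2
    for (j in seq_len(nrow(v) - 1L)) {
      p0 <- v[j, ]; p1 <- v[j + 1L, ]
      c_rng <- which(cx >= min(p0[1], p1[1]) - r &
                     cx <= max(p0[1], p1[1]) + r)
      r_rng <- which(cy >= min(p0[2], p1[2]) - r &
                     cy <= max(p0[2], p1[2]) + r)
      if (!length(c_rng) || !length(r_rng)) next
      sub <- img[r_rng, c_rng, drop = FALSE]
      if (all(sub == 1L)) next
      grid <- cbind(rep(cx[c_rng], each = length(r_rng)),
                    rep(cy[r_rng], times = length(c_rng)))
      hit <- dist_point_segment(grid, p0, p1) <= r
      sub[hit] <- 1L
      img[r_rng, c_rng] <- sub
    }
  }
  attr(img, "pixel_size_um") <- pixel_size
  attr(img, "x_min_um") <- x_min
  attr(img, "y_max_um") <- y_max
  class(img) <- c("plate_raster", class(img))
  img
}

#' Radial spread statistics of a binary mask
#'
#' Mean and population standard deviation of the Euclidean distances of all
#' foreground pixel centres from an origin — the spread statistic used to
#' quantify how far filaments have propagated from their starting point.
#'
#' @param mask binary matrix (non-zero = foreground), row-major with origin
#'   at the top-left; pixel (r, c) centre is at `((c - 0.5), (r - 0.5)) *
#'   pixel_size` in the raster frame.
#' @param pixel_size pixel edge length, µm.
#' @param origin numeric length-2: origin in the raster frame, µm; must lie
#'   within the raster bounds.
#' @return list with `mean_um`, `sd_um` (population SD) and `n_pixels`.
#' @examples
#' m <- matrix(0, 10, 10); m[4, 3] <- 1   # centre offset (3, 4) um per
#' radial_spread_stats(m, 1, c(5.5, .5))  # unit pixels from this origin
#' @export
radial_spread_stats <- function(mask, pixel_size, origin) {
  stopifnot(is.matrix(mask), is.numeric(pixel_size), pixel_size > 0,
            is.numeric(origin), length(origin) == 2L)
  nr <- nrow(mask); nc <- ncol(mask)
  if (origin[1] < 0 || origin[1] > nc * pixel_size ||
      origin[2] < 0 || origin[2] > nr * pixel_size)
    stop("'origin' lies outside the raster bounds")
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty mask: no foreground pixels")
  x <- (idx[, 2] - 0.5) * pixel_size
  y <- (idx[, 1] - 0.5) * pixel_size
  d <- sqrt((x - origin[1])^2 + (y - origin[2])^2)
  list(mean_um = mean(d), sd_um = sqrt(mean((d - mean(d))^2)),
       n_pixels = length(d))
}

#' Radial spread of a simulated plate
#'
#' Convenience wrapper: rasterizes a plate state and computes
#' [radial_spread_stats()] about a point given in plate coordinates
#' (default the plate origin, where the inoculum is usually placed).
#'
#' @param state a [plate_state()].
#' @param pixel_size raster pixel size, µm.
#' @param origin origin in plate coordinates, µm.
#' @return as [radial_spread_stats()].
#' @export
plate_spread_stats <- function(state, pixel_size = 10, origin = c(0, 0)) {
  img <- rasterize(state, pixel_size)
  ox <- origin[1] - attr(img, "x_min_um")
  oy <- attr(img, "y_max_um") - origin[2]
  nr <- nrow(img); nc <- ncol(img)
  ox <- min(max(ox, 0), nc * pixel_size)
  oy <- min(max(oy, 0), nr * pixel_size)
  radial_spread_stats(unclass(img), pixel_size, c(ox, oy))
}

#' Write a plate raster as an 8-bit grayscale PNG
#'
#' Foreground pixels are written as 255, background as 0.  A JSON sidecar
#' (`<path>.json`) records the pixel size and plate-coordinate frame.
#'
#' @param raster a [rasterize()] result.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_raster_png <- function(raster, path) {
  stopifnot(inherits(raster, "plate_raster"))
  img <- matrix(as.numeric(raster != 0), nrow = nrow(raster))
  png::writePNG(img, target = path)
  meta <- list(pixel_size_um = attr(raster, "pixel_size_um"),
               x_min_um = attr(raster, "x_min_um"),
               y_max_um = attr(raster, "y_max_um"),
               foreground = 255L, background = 0L)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
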