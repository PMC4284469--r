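## Internal helpers shared across the package.

## Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
## state afterwards.  `seed = NULL` uses (and advances) the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

## Distances from points (n x 2 matrix) to the segment p0-p1.
dist_point_segment <- function(pts, p0, p1) {
  d <- p1 - p0
  len2 <- sum(d * d)
  if (len2 == 0) {
    return(sqrt((pts[, 1] - p0[1])^2 + (pts[, 2] - p0[2])^2))
  }
  tt <- ((pts[, 1] - p0[1]) * d[1] + (pts[, 2] - p0[2]) * d[2]) / len2
  tt <- pmin(1, pmax(0, tt))
  qx <- p0[1] + tt * d[1]
  qy <- p0[2] + tt * d[2]
  sqrt((pts[, 1] - qx)^2 + (pts[, 2] - qy)^2)
}

## Wrap angles to (-pi, pi].
wrap_angle <- function(a) {
  a <- (a + pi) %% (2 * pi) - pi
  a[a <= -pi] <- a[a <= -pi] + 2 * pi
  a
}

## Sample skewness (bias-uncorrected moment ratio).
sample_skewness <- function(x) {
  x <- x[is.finite(x)]
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s == 0) return(0)
  mean((x - m)^3) / s^3
}

## Diameter (max pairwise distance) of a 2-D point set, via its convex hull.
point_set_diameter <- function(pts) {
  pts <- pts[stats::complete.cases(pts), , drop = FALSE]
  if (nrow(pts) < 2) return(0)
  h <- grDevices::chull(pts)
  hp <- pts[h, , drop = FALSE]
  dx <- outer(hp[, 1], hp[, 1], "-")
  dy <- outer(hp[, 2], hp[, 2], "-")
  sqrt(max(dx * dx + dy * dy))
}
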