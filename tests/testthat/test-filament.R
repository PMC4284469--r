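polyline_length <- function(v) sum(sqrt(rowSums(diff(v)^2)))

test_that("filament construction satisfies the body invariants", {
  p <- anchor_15()
  fil <- new_filament(c(10, -5), heading = 0.7, length = 100, params = p)
  v <- filament_vertices(fil)
  expect_gte(nrow(v), 2)
  expect_true(all(sqrt(rowSums(diff(v)^2)) <= fil$seg + 1e-9))
  expect_equal(polyline_length(v), 100, tolerance = 1e-6)
  expect_equal(fil$length, 100)
  # centred at the requested origin
  expect_equal(colMeans(v[c(1, nrow(v)), ]), c(x = 10, y = -5),
               tolerance = 1e-9)
})

test_that("growth follows the doubling law and preserves the polyline", {
  p <- anchor_15()
  fil <- new_filament(c(0, 0), 0, 80, p)
  grow(fil, dt = 0, doubling_time = 3600)
  expect_equal(fil$length, 80)                     # dt = 0 identity
  grow(fil, dt = 3600, doubling_time = 3600)
  expect_equal(fil$length, 160, tolerance = 1e-9)  # exact doubling
  # arc-length oracle: dense resampling of the vertex polyline
  fil2 <- new_filament(c(0, 0), 1.1, 50, p)
  grow(fil2, dt = 5400, doubling_time = 3600, kappa = 0.002)
  expected <- 50 * 2^(5400 / 3600)
  dense <- filament_vertices(fil2, spacing = 0.05)
  expect_equal(polyline_length(dense), expected, tolerance = 1e-6)
  expect_equal(fil2$length, expected, tolerance = 1e-6)
})

test_that("growth appends equally at both ends", {
  p <- anchor_15()
  fil <- new_filament(c(0, 0), 0, 100, p)
  lo0 <- fil$s_lo; hi0 <- fil$s_hi
  grow(fil, dt = 1800, doubling_time = 3600)
  expect_equal(lo0 - fil$s_lo, fil$s_hi - hi0, tolerance = 1e-9)
})

test_that("curved extension follows a circular arc of radius 1/kappa", {
  # closed-form circle vs extended polyline: heading change after path
  # length L equals kappa * L, counterclockwise
  p <- anchor_15()
  kappa <- 0.004
  fil <- new_filament(c(0, 0), 0, 20, p, seg = 0.5)
  arc0 <- glidekin:::fil_arc_max(fil)
  added <- glidekin:::fil_extend(fil, 1L, 500, kappa = kappa)
  expect_equal(added, glidekin:::fil_arc_max(fil) - arc0)
  expect_equal(fil$h_hi, kappa * added, tolerance = 1e-9)
  tp <- glidekin:::fil_trail_points(fil)
  w <- polyline_winding(tp)
  expect_gt(w, 0)  # counterclockwise
  # every appended point lies on a circle of radius ~ 1/kappa: check via
  # a least-squares circle fit through the extension
  ext <- tp[tp[, 1]^2 + tp[, 2]^2 > 15^2, , drop = FALSE]
  # fit circle centre by least squares, compare radius
  A <- cbind(2 * ext[, 1], 2 * ext[, 2], 1)
  b <- ext[, 1]^2 + ext[, 2]^2
  sol <- qr.solve(A, b)
  radius <- sqrt(sol[3] + sol[1]^2 + sol[2]^2)
  expect_equal(radius, 1 / kappa, tolerance = 0.01)
})

test_that("trail extension sign convention gives uniform spatial chirality", {
  # extending at both ends must produce one consistently counterclockwise
  # curve (single-handed filament shape), not an S
  p <- anchor_15()
  fil <- new_filament(c(0, 0), 0, 40, p)
  glidekin:::fil_extend(fil, 1L, 300, kappa = 0.003)
  glidekin:::fil_extend(fil, -1L, 300, kappa = 0.003)
  fil$s_lo <- glidekin:::fil_arc_min(fil)
  fil$s_hi <- glidekin:::fil_arc_max(fil)
  fil$length <- fil$s_hi - fil$s_lo
  w <- polyline_winding(filament_vertices(fil))
  expect_equal(w, 0.003 * (fil$length - 40), tolerance = 0.02)
})
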