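# Shared fixtures and independent oracles for the test suite. Everything is
# generated in code; heavyweight synthetic subjects are cached per session.

fixture_cache <- new.env(parent = emptyenv())

# reduced-resolution synthetic subject for fast unit tests
small_params <- function(seed = 1, ...) {
  torso_params(n_theta = 96, n_y = 72, seed = seed, ...)
}

get_subject <- function(key, params) {
  if (is.null(fixture_cache[[key]]))
    fixture_cache[[key]] <- generate_torso(params)
  fixture_cache[[key]]
}

# independent Bezier oracle: de Casteljau recursive subdivision
de_casteljau <- function(p0, p1, p2, p3, t) {
  lerp <- function(a, b) (1 - t) * a + t * b
  a <- lerp(p0, p1); b <- lerp(p1, p2); c <- lerp(p2, p3)
  d <- lerp(a, b); e <- lerp(b, c)
  lerp(d, e)
}

# rotation matrix about a unit axis (Rodrigues)
rotation_about <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
}

random_rigid <- function() {
  list(R = rotation_about(rnorm(3), runif(1, 0.1, pi)),
       t = runif(3, -100, 100))
}

apply_rigid_landmarks <- function(lm, R, t) {
  out <- lapply(unclass(lm), function(p) drop(R %*% p) + t)
  class(out) <- "landmark_set"
  out
}

# axis-aligned box as a watertight mesh
box_mesh <- function(dx, dy, dz, origin = c(0, 0, 0)) {
  v <- rbind(c(0, 0, 0), c(dx, 0, 0), c(dx, dy, 0), c(0, dy, 0),
             c(0, 0, dz), c(dx, 0, dz), c(dx, dy, dz), c(0, dy, dz))
  v <- sweep(v, 2, origin, "+")
  f <- rbind(c(1, 3, 2), c(1, 4, 3), c(5, 6, 7), c(5, 7, 8),
             c(1, 2, 6), c(1, 6, 5), c(2, 3, 7), c(2, 7, 6),
             c(3, 4, 8), c(3, 8, 7), c(4, 1, 5), c(4, 5, 8))
  triangle_mesh(v, f)
}

# rectangular z = f(x, y) sheet (open surface)
sheet_mesh <- function(xr, yr, n = 20, fz = function(x, y) 0 * x) {
  xs <- seq(xr[1], xr[2], length.out = n)
  ys <- seq(yr[1], yr[2], length.out = n)
  gx <- rep(xs, times = n)
  gy <- rep(ys, each = n)
  v <- cbind(gx, gy, fz(gx, gy))
  id <- function(i, j) (j - 1L) * n + i
  faces <- list()
  for (j in seq_len(n - 1)) {
    i <- seq_len(n - 1)
    faces[[length(faces) + 1]] <- cbind(id(i, j), id(i + 1, j), id(i + 1, j + 1))
    faces[[length(faces) + 1]] <- cbind(id(i, j), id(i + 1, j + 1), id(i, j + 1))
  }
  triangle_mesh(v, do.call(rbind, faces))
}

# boundary_points object for n = 8 points on a circle in the z = 0 plane
circle_boundary_points <- function(r = 60, side = "left") {
  ang <- pi / 2 - (0:7) * pi / 4  # start superior, clockwise
  pts <- cbind(r * cos(ang + pi / 2), r * sin(ang + pi / 2), 0)
  rownames(pts) <- breastvol:::BOUNDARY_POINT_LABELS
  structure(list(points = pts, labels = rownames(pts), side = side),
            class = "boundary_points")
}

# distance from a point to a closed polyline (minimum over segments)
dist_to_polyline <- function(p, poly) {
  n <- nrow(poly)
  a <- poly
  b <- poly[c(2:n, 1), ]
  ab <- b - a
  ap <- sweep(-a, 2, p, "+")
  tt <- pmin(pmax(rowSums(ab * ap) / pmax(rowSums(ab^2), 1e-300), 0), 1)
  q <- a + ab * tt
  sqrt(min(rowSums(sweep(q, 2, p)^2)))
}

# planar chest wall spanning a circular boundary in the z = 0 plane: columns
# are vertical chords of the circle (the natural bchl = 0 loft)
disk_wall_grid <- function(r = 60, K = 24, M = 24, x_offset = 0) {
  grid <- vector("list", K)
  for (k in seq_len(K)) {
    x <- -r + 2 * r * (k - 1) / (K - 1)
    y <- sqrt(max(r^2 - x^2, 0))
    tt <- (0:M) / M
    grid[[k]] <- cbind(x + x_offset, y - 2 * y * tt, 0)
  }
  grid
}
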