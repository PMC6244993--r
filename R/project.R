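# Surface queries used by the boundary, lofting and validation stages:
# projection onto the mesh along the anterior (z) axis, and exact nearest
# point on a triangle mesh.

# Precompute per-face data for repeated (x, y) -> z queries against a mesh in
# frame coordinates.
make_z_projector <- function(mesh) {
  f <- mesh$faces
  v <- mesh$vertices
  x1 <- v[f[, 1], 1]; y1 <- v[f[, 1], 2]; z1 <- v[f[, 1], 3]
  x2 <- v[f[, 2], 1]; y2 <- v[f[, 2], 2]; z2 <- v[f[, 2], 3]
  x3 <- v[f[, 3], 1]; y3 <- v[f[, 3], 2]; z3 <- v[f[, 3], 3]
  denom <- (y2 - y3) * (x1 - x3) + (x3 - x2) * (y1 - y3)
  list(x1 = x1, y1 = y1, z1 = z1, x2 = x2, y2 = y2, z2 = z2,
       x3 = x3, y3 = y3, z3 = z3, denom = denom,
       xmin = pmin(x1, x2, x3), xmax = pmax(x1, x2, x3),
       ymin = pmin(y1, y2, y3), ymax = pmax(y1, y2, y3))
}

# z of the mesh surface above (x, y), along the +z (anterior) axis.
# which = "max" returns the most anterior intersection (the skin, not the
# back). Returns NA where the vertical line misses the mesh.
project_z <- function(proj, x, y, which = "max") {
  n <- length(x)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    xi <- x[i]; yi <- y[i]
    cand <- which(proj$xmin <= xi & proj$xmax >= xi &
                    proj$ymin <= yi & proj$ymax >= yi &
                    abs(proj$denom) > 1e-12)
    if (!length(cand)) next
    l1 <- ((proj$y2[cand] - proj$y3[cand]) * (xi - proj$x3[cand]) +
             (proj$x3[cand] - proj$x2[cand]) * (yi - proj$y3[cand])) /
      proj$denom[cand]
    l2 <- ((proj$y3[cand] - proj$y1[cand]) * (xi - proj$x3[cand]) +
             (proj$x1[cand] - proj$x3[cand]) * (yi - proj$y3[cand])) /
      proj$denom[cand]
    l3 <- 1 - l1 - l2
    tol <- -1e-9
    hit <- l1 >= tol & l2 >= tol & l3 >= tol
    if (!any(hit)) next
    z <- l1[hit] * proj$z1[cand[hit]] + l2[hit] * proj$z2[cand[hit]] +
      l3[hit] * proj$z3[cand[hit]]
    out[i] <- if (which == "max") max(z) else min(z)
  }
  out
}

#' Project points onto the mesh surface along the anterior axis
#'
#' For each query point, the vertical line through its (x, y) coordinates
#' (mesh in frame coordinates: z = anterior) is intersected with the mesh and
#' the most anterior intersection (the skin, not the back) is returned. Where
#' the line misses the mesh and \code{fallback = TRUE}, the exact nearest
#' point on the mesh is used instead (needed e.g. at the lateral silhouette,
#' where the surface is parallel to the axis).
#'
#' @param points n x 3 matrix (frame coordinates, mm).
#' @param mesh \code{triangle_mesh} in the same frame coordinates.
#' @param fallback use nearest-point projection where the axis ray misses.
#' @param max_dist error if any projected point ends up farther than this from
#'   its query (mm); \code{Inf} disables the check.
#' @return n x 3 matrix of surface points.
#' @export
project_onto_surface <- function(points, mesh, fallback = TRUE,
                                 max_dist = Inf) {
  p <- if (is.null(dim(points))) matrix(points, 1) else as.matrix(points)
  proj <- make_z_projector(mesh)
  z <- project_z(proj, p[, 1], p[, 2], which = "max")
  out <- cbind(p[, 1], p[, 2], z)
  miss <- is.na(z)
  if (any(miss)) {
    if (!fallback)
      stop("projection along the anterior axis misses the mesh for ",
           sum(miss), " point(s)")
    for (i in which(miss))
      out[i, ] <- nearest_point_on_mesh(p[i, ], mesh)$point
  }
  if (is.finite(max_dist)) {
    d <- sqrt(rowSums((out - p)^2))
    if (any(d > max_dist))
      stop("surface projection failed: ", sum(d > max_dist), " point(s) ",
           "farther than ", max_dist, " mm from the surface (max ",
           sprintf("%.1f", max(d)), " mm)")
  }
  out
}

# Exact closest points on a set of triangles to a single point p.
# Vectorised version of the standard closest-point-on-triangle construction
# (barycentric region classification). A, B, C: n x 3 corner matrices.
# Returns list(points = n x 3, dist2 = n).
closest_on_triangles <- function(p, A, B, C) {
  n <- nrow(A)
  P <- matrix(p, n, 3, byrow = TRUE)
  ab <- B - A; ac <- C - A; ap <- P - A
  d1 <- rowSums(ab * ap); d2 <- rowSums(ac * ap)
  bp <- P - B
  d3 <- rowSums(ab * bp); d4 <- rowSums(ac * bp)
  cp <- P - C
  d5 <- rowSums(ab * cp); d6 <- rowSums(ac * cp)
  va <- d3 * d6 - d5 * d4
  vb <- d5 * d2 - d1 * d6
  vc <- d1 * d4 - d3 * d2
  res <- matrix(NA_real_, n, 3)
  done <- rep(FALSE, n)
  set_res <- function(mask, pts) {
    mask <- mask & !done
    if (any(mask)) {
      res[mask, ] <<- pts[mask, , drop = FALSE]
      done[mask] <<- TRUE
    }
  }
  # vertex regions
  set_res(d1 <= 0 & d2 <= 0, A)
  set_res(d3 >= 0 & d4 <= d3, B)
  set_res(d6 >= 0 & d5 <= d6, C)
  # edge AB
  v <- d1 / (d1 - d3)
  set_res(vc <= 0 & d1 >= 0 & d3 <= 0, A + ab * v)
  # edge AC
  w <- d2 / (d2 - d6)
  set_res(vb <= 0 & d2 >= 0 & d6 <= 0, A + ac * w)
  # edge BC
  w2 <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
  set_res(va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0, B + (C - B) * w2)
  # interior
  denom <- va + vb + vc
  denom[denom == 0] <- 1
  vv <- vb / denom; ww <- vc / denom
  set_res(!done, A + ab * vv + ac * ww)
  list(points = res, dist2 = rowSums((res - P)^2))
}

# Precompute centroid/radius data for nearest-point prefiltering.
make_np_index <- function(mesh) {
  A <- face_corner(mesh, 1); B <- face_corner(mesh, 2)
  C <- face_corner(mesh, 3)
  ctr <- (A + B + C) / 3
  r <- sqrt(pmax(rowSums((A - ctr)^2), rowSums((B - ctr)^2),
                 rowSums((C - ctr)^2)))
  list(A = A, B = B, C = C, ctr = ctr, r = r)
}

nearest_point_index <- function(p, idx, exhaustive = FALSE) {
  dc <- sqrt(rowSums(sweep(idx$ctr, 2, p)^2))
  if (exhaustive) {
    cand <- seq_along(dc)
  } else {
    ub <- min(dc + idx$r)
    cand <- which(dc - idx$r <= ub + 1e-9)
  }
  cl <- closest_on_triangles(p, idx$A[cand, , drop = FALSE],
                             idx$B[cand, , drop = FALSE],
                             idx$C[cand, , drop = FALSE])
  j <- which.min(cl$dist2)
  list(point = cl$points[j, ], distance = sqrt(cl$dist2[j]), face = cand[j])
}

#' Nearest point on a triangle mesh
#'
#' Exact point-to-surface projection: returns the closest point on any
#' triangle of the mesh, the distance, and the face index. A centroid-radius
#' prefilter makes repeated queries cheap without changing the result.
#'
#' @param p length-3 point (mm).
#' @param mesh a \code{triangle_mesh}.
#' @param exhaustive if \code{TRUE}, test every triangle (reference path used
#'   by the test oracle).
#' @return list with \code{point}, \code{distance}, \code{face}.
#' @export
nearest_point_on_mesh <- function(p, mesh, exhaustive = FALSE) {
  nearest_point_index(p, make_np_index(mesh), exhaustive = exhaustive)
}
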