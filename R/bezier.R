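# Chest-wall simulation core: the vertical cubic Bezier framework spanning
# the breast boundary, and the lofted surface. The single tuning parameter is
# the Bezier curve handle length (BCHL), a fraction of the Euclidean distance
# between each curve's end points; both handles of a curve share it.

#' Cubic Bezier curve
#'
#' @param p0,p1,p2,p3 length-3 control points (mm). \code{p0}/\code{p3} are
#'   the end points on the boundary; \code{p1}/\code{p2} the handle points.
#' @return object of class \code{cubic_bezier}.
#' @export
cubic_bezier <- function(p0, p1, p2, p3) {
  pts <- lapply(list(p0 = p0, p1 = p1, p2 = p2, p3 = p3), function(p) {
    p <- as.numeric(p)
    if (length(p) != 3L || !all(is.finite(p)))
      stop("control points must be finite 3D points")
    p
  })
  structure(pts, class = "cubic_bezier")
}

#' Evaluate a cubic Bezier curve
#'
#' \eqn{B(t) = (1-t)^3 p_0 + 3(1-t)^2 t\, p_1 + 3(1-t) t^2 p_2 + t^3 p_3}.
#'
#' @param curve a \code{cubic_bezier}.
#' @param t parameter values in \code{[0, 1]} (error outside).
#' @return length(t) x 3 matrix of points.
#' @export
evaluate_bezier <- function(curve, t) {
  stopifnot(inherits(curve, "cubic_bezier"))
  if (any(t < 0 | t > 1))
    stop("Bezier parameter t must lie in [0, 1]")
  u <- 1 - t
  b0 <- u^3; b1 <- 3 * u^2 * t; b2 <- 3 * u * t^2; b3 <- t^3
  outer(b0, curve$p0) + outer(b1, curve$p1) +
    outer(b2, curve$p2) + outer(b3, curve$p3)
}

# Resolve a BCHL given either as a number in [0, 1] or a preset name.
resolve_bchl <- function(bchl) {
  if (is.character(bchl)) {
    presets <- c(bchl020 = 0.20, bchl033 = 0.33, bchl050 = 0.50)
    if (!bchl %in% names(presets))
      stop("unknown BCHL preset '", bchl, "' (use ",
           paste(names(presets), collapse = ", "), " or a number in [0, 1])")
    return(unname(presets[bchl]))
  }
  if (!is.numeric(bchl) || length(bchl) != 1L || is.na(bchl) ||
      bchl < 0 || bchl > 1)
    stop("bchl must be a fraction in [0, 1]")
  bchl
}

# Split the dense projected boundary polyline into the upper and lower arcs
# at the exact medial and lateral extreme parameters of the smooth spline
# (stored on the curve by fit_boundary_curve). Each arc is returned oriented
# medial -> lateral with a normalized-arc-length sampler.
split_boundary_arcs <- function(curve, side) {
  d <- curve$dense
  n <- nrow(d)
  if (is.null(curve$t_extreme))
    stop("boundary curve lacks extreme-point information")
  t_med <- if (side == "left") curve$t_extreme["hi"] else curve$t_extreme["lo"]
  t_lat <- if (side == "left") curve$t_extreme["lo"] else curve$t_extreme["hi"]
  p_med <- if (side == "left") curve$extreme_points$hi else
    curve$extreme_points$lo
  p_lat <- if (side == "left") curve$extreme_points$lo else
    curve$extreme_points$hi
  if (abs(t_med - t_lat) < 1e-9)
    stop("boundary cannot be split into two arcs (degenerate extreme points)")
  # dense sample parameters strictly between two split parameters, forward
  between <- function(t_a, t_b) {
    span <- (curve$t - t_a) %% 1
    lim <- (t_b - t_a) %% 1
    which(span > 1e-12 & span < lim - 1e-12)[
      order(span[span > 1e-12 & span < lim - 1e-12])]
  }
  arc1 <- rbind(p_med, d[between(t_med, t_lat), , drop = FALSE], p_lat)
  arc2 <- rbind(p_med,
                d[rev(between(t_lat, t_med)), , drop = FALSE], p_lat)
  arcs <- list(arc1, arc2)
  means <- vapply(arcs, function(a) mean(a[, 2]), numeric(1))
  upper <- arcs[[which.max(means)]]
  lower <- arcs[[which.min(means)]]
  sampler <- function(arc) {
    seglen <- sqrt(rowSums(diff(arc)^2))
    cum <- c(0, cumsum(seglen))
    total <- cum[length(cum)]
    function(u) {
      s <- pmin(pmax(u, 0), 1) * total
      i <- pmin(pmax(findInterval(s, cum, rightmost.closed = TRUE), 1L),
                nrow(arc) - 1L)
      w <- (s - cum[i]) / pmax(cum[i + 1] - cum[i], 1e-300)
      arc[i, , drop = FALSE] * (1 - w) + arc[i + 1, , drop = FALSE] * w
    }
  }
  list(upper = sampler(upper), lower = sampler(lower))
}

#' Build the vertical Bezier framework inside the boundary
#'
#' The boundary is split into an upper and a lower arc at its medial and
#' lateral extreme points. K vertical cubic Bezier curves connect the arcs at
#' matched normalized arc-length parameters (the first and last columns
#' degenerate to the split points). The upper handle direction of each curve
#' is the direction of the mesh surface just superior to the upper end point
#' (sampled along a 5-10 mm band above it, projected into the plane spanned by
#' the chord and the anterior axis, continued across the boundary); the lower
#' handle direction is its chord-reflection so the curve is symmetric when the
#' local surface is. Both handle lengths equal \code{bchl} times the chord
#' length.
#'
#' @param mesh \code{triangle_mesh} in frame coordinates.
#' @param curve a \code{boundary_curve}.
#' @param bchl Bezier curve handle length: fraction of the chord in
#'   \code{[0, 1]}, or a preset name (\code{"bchl020"}, \code{"bchl033"},
#'   \code{"bchl050"}).
#' @param K number of vertical curves (>= 3), end columns included.
#' @param band superior sampling band (mm) for the handle direction.
#' @return object of class \code{bezier_framework}.
#' @export
build_bezier_framework <- function(mesh, curve, bchl = 0.33, K = 32,
                                   band = c(5, 10)) {
  stopifnot(inherits(curve, "boundary_curve"))
  bchl <- resolve_bchl(bchl)
  if (!is.numeric(K) || K < 3) stop("K must be at least 3")
  arcs <- split_boundary_arcs(curve, curve$side)
  npi <- make_np_index(mesh)
  columns <- vector("list", K)
  zhat <- c(0, 0, 1)
  for (k in seq_len(K)) {
    u <- (k - 1) / (K - 1)
    p0 <- drop(arcs$upper(u))
    p3 <- drop(arcs$lower(u))
    chord <- p3 - p0
    clen <- vnorm(chord)
    if (clen < 1e-6) {
      columns[[k]] <- list(degenerate = TRUE, point = (p0 + p3) / 2)
      next
    }
    chat <- chord / clen
    # mean of surface samples in the band superior to p0 (nearest-point
    # queries seeded just above the end point: continuous at the silhouette)
    deltas <- seq(band[1], band[2], length.out = 4)
    qs <- t(vapply(deltas, function(dlt)
      nearest_point_index(c(p0[1], p0[2] + dlt, p0[3]), npi)$point,
      numeric(3)))
    qs <- qs[qs[, 2] > p0[2] + 1, , drop = FALSE]  # must end up superior
    if (nrow(qs) == 0L) {
      d0 <- chat  # no surface superior to the boundary: fall back to chord
    } else {
      raw <- p0 - colMeans(qs)
      # restrict to the plane spanned by the chord and the anterior axis
      e1 <- chat
      e2 <- zhat - sum(zhat * e1) * e1
      if (vnorm(e2) < 1e-9) e2 <- c(0, 0, 0) else e2 <- e2 / vnorm(e2)
      d0 <- sum(raw * e1) * e1 + sum(raw * e2) * e2
      if (vnorm(d0) < 1e-9) d0 <- chat else d0 <- d0 / vnorm(d0)
      if (sum(d0 * chat) < 0) d0 <- -d0
    }
    d1 <- d0 - 2 * sum(d0 * chat) * chat  # chord reflection
    h <- bchl * clen
    columns[[k]] <- list(degenerate = FALSE,
                         bezier = cubic_bezier(p0, p0 + h * d0,
                                               p3 + h * d1, p3),
                         chord = clen)
  }
  # ordering check: columns must progress monotonically medial -> lateral in
  # the frontal projection (crossing curves are reported, not repaired)
  xs <- vapply(columns, function(cl)
    if (cl$degenerate) cl$point[1] else cl$bezier$p0[1], numeric(1))
  if (!(all(diff(xs) >= -0.01) || all(diff(xs) <= 0.01)))
    warning("Bezier curves are not ordered medial to lateral in the frontal ",
            "projection; the loft may self-intersect")
  structure(list(columns = columns, bchl = bchl, K = K, side = curve$side,
                 curve = curve),
            class = "bezier_framework")
}

#' @export
print.bezier_framework <- function(x, ...) {
  cat(sprintf("bezier_framework: K = %d vertical curves, BCHL = %.2f (%s side)\n",
              x$K, x$bchl, x$side))
  invisible(x)
}

#' Loft the simulated chest-wall surface from the Bezier framework
#'
#' Each of the K curves is evaluated at M + 1 parameters and the resulting
#' grid is triangulated into a strip mesh (end columns collapse to the medial
#' and lateral boundary split points). Face normals are oriented anterior.
#'
#' @param framework a \code{bezier_framework}.
#' @param M samples per curve (grid rows = M + 1).
#' @param frame the \code{reference_frame} the framework lives in (stored for
#'   downstream world-coordinate export); defaults to the identity frame.
#' @return object of class \code{chest_wall}: the lofted
#'   \code{triangle_mesh} (frame coordinates in \code{$mesh_frame}, world in
#'   \code{$mesh}), the generating framework, the grid, and the boundary loop.
#' @export
loft_chest_wall <- function(framework, M = 32, frame = identity_frame()) {
  stopifnot(inherits(framework, "bezier_framework"))
  if (!is.numeric(M) || M < 2) stop("M must be at least 2")
  K <- framework$K
  tgrid <- (0:M) / M
  grid <- vector("list", K)
  for (k in seq_len(K)) {
    cl <- framework$columns[[k]]
    grid[[k]] <- if (cl$degenerate)
      matrix(cl$point, M + 1, 3, byrow = TRUE)
    else
      evaluate_bezier(cl$bezier, tgrid)
  }
  built <- grid_to_mesh(grid)
  mesh_f <- built$mesh
  # orient anterior (+z in frame coordinates)
  nz <- face_normals(mesh_f)[, 3]
  ar <- face_areas(mesh_f)
  if (sum(nz * ar) < 0)
    mesh_f$faces <- mesh_f$faces[, c(1, 3, 2)]
  structure(list(mesh = from_frame_coordinates(mesh_f, frame),
                 mesh_frame = mesh_f,
                 grid = grid, vertex_index = built$index,
                 framework = framework, frame = frame,
                 bchl = framework$bchl, side = framework$side,
                 K = K, M = M,
                 boundary_curve = framework$curve),
            class = "chest_wall")
}

# Triangulate a K-column grid (list of (M+1) x 3 matrices; degenerate columns
# have all rows equal) into a mesh. Shared/collapsed vertices are welded by
# construction. Returns the mesh and the vertex index matrix (K x (M+1)).
grid_to_mesh <- function(grid) {
  K <- length(grid)
  M1 <- nrow(grid[[1]])
  degen <- vapply(grid, function(g)
    max(abs(sweep(g, 2, g[1, ]))) < 1e-12, logical(1))
  verts <- list()
  nv <- 0L
  index <- matrix(0L, K, M1)
  for (k in seq_len(K)) {
    if (degen[k]) {
      nv <- nv + 1L
      verts[[length(verts) + 1L]] <- grid[[k]][1, , drop = FALSE]
      index[k, ] <- nv
    } else {
      verts[[length(verts) + 1L]] <- grid[[k]]
      index[k, ] <- nv + seq_len(M1)
      nv <- nv + M1
    }
  }
  V <- do.call(rbind, verts)
  faces <- vector("list", (K - 1) * (M1 - 1) * 2)
  nf <- 0L
  for (k in seq_len(K - 1)) {
    a <- index[k, ]; b <- index[k + 1, ]
    for (m in seq_len(M1 - 1)) {
      # quad (a[m], b[m], b[m+1], a[m+1]) split into two triangles
      if (a[m] != b[m] && b[m] != b[m + 1] && a[m] != b[m + 1]) {
        nf <- nf + 1L
        faces[[nf]] <- c(a[m], b[m], b[m + 1])
      }
      if (a[m] != b[m + 1] && b[m + 1] != a[m + 1] && a[m] != a[m + 1]) {
        nf <- nf + 1L
        faces[[nf]] <- c(a[m], b[m + 1], a[m + 1])
      }
    }
  }
  mesh <- triangle_mesh(V, do.call(rbind, faces[seq_len(nf)]), clean = FALSE)
  list(mesh = mesh, index = index)
}

#' @export
print.chest_wall <- function(x, ...) {
  cat(sprintf("chest_wall: BCHL = %.2f, %s side, %d x %d grid, area %.1f cm^2\n",
              x$bchl, x$side, x$K, x$M + 1, surface_area(x$mesh)))
  invisible(x)
}
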