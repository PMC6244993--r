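# Breast boundary: eight boundary points derived from the landmarks and the
# reference planes, and the closed interpolating curve through them, projected
# back onto the skin.

#' Boundary offset recipe
#'
#' The original method places five of the eight boundary points "at fixed
#' relative distances in respect to the landmarks and the reference planes"
#' without publishing the distances. This package makes the recipe explicit
#' configuration. All fractions are relative to the inter-midaxillary distance
#' \eqn{d_{MA}} (the only robust inter-landmark length) and to the medial-to-
#' lateral x span of the boundary:
#' \itemize{
#'   \item \code{parasternal}: x offset of the medial boundary line from the
#'     midline, as a fraction of \eqn{d_{MA}} (superior-medial, medial and the
#'     medial end of the inframammary points).
#'   \item \code{nipple_drop}: drop of the nipple-line level below the
#'     sternomanubrial level, fraction of \eqn{d_{MA}} (y of the medial point).
#'   \item \code{inframammary_drop}: drop of the inframammary level below the
#'     sternomanubrial level, fraction of \eqn{d_{MA}}.
#'   \item \code{inferior_extra}: additional drop of the central inferior
#'     point below the inframammary level (the fold is lowest centrally).
#'   \item \code{inferolateral_frac}, \code{inferior_frac},
#'     \code{inferomedial_frac}: x positions of the three inferior points as
#'     fractions of the medial-to-lateral span.
#' }
#' Defaults were chosen once to reproduce the published boundary figure
#' qualitatively on an adult torso.
#'
#' @param parasternal,nipple_drop,inframammary_drop,inferior_extra,inferolateral_frac,inferior_frac,inferomedial_frac
#'   numeric fractions in \code{[0, 1]}.
#' @return an object of class \code{boundary_offsets}.
#' @export
boundary_offsets <- function(parasternal = 0.02,
                             nipple_drop = 0.18,
                             inframammary_drop = 0.40,
                             inferior_extra = 0.02,
                             inferolateral_frac = 0.70,
                             inferior_frac = 0.45,
                             inferomedial_frac = 0.15) {
  vals <- list(parasternal = parasternal, nipple_drop = nipple_drop,
               inframammary_drop = inframammary_drop,
               inferior_extra = inferior_extra,
               inferolateral_frac = inferolateral_frac,
               inferior_frac = inferior_frac,
               inferomedial_frac = inferomedial_frac)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop("boundary offset '", nm, "' must be a fraction in [0, 1]")
  }
  structure(vals, class = "boundary_offsets")
}

BOUNDARY_POINT_LABELS <- c("superior_medial", "superior", "superolateral",
                           "lateral", "inferolateral", "inferior",
                           "inferomedial", "medial")

# is the closed polygon (n x 2, not repeating the first point) simple?
is_simple_polygon <- function(xy) {
  n <- nrow(xy)
  seg <- cbind(xy, xy[c(2:n, 1), ])
  cross2 <- function(ox, oy, ax, ay, bx, by)
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      # skip adjacent segments (shared endpoint)
      if (j == i + 1L || (i == 1L && j == n)) next
      d1 <- cross2(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4],
                   seg[j, 1], seg[j, 2])
      d2 <- cross2(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4],
                   seg[j, 3], seg[j, 4])
      d3 <- cross2(seg[j, 1], seg[j, 2], seg[j, 3], seg[j, 4],
                   seg[i, 1], seg[i, 2])
      d4 <- cross2(seg[j, 1], seg[j, 2], seg[j, 3], seg[j, 4],
                   seg[i, 3], seg[i, 4])
      if (((d1 > 0) != (d2 > 0)) && ((d3 > 0) != (d4 > 0)))
        return(FALSE)
    }
  }
  TRUE
}

# even-odd point-in-polygon test; poly is n x 2 (closed implicitly)
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    if ((poly[i, 2] > py) != (poly[j, 2] > py) &&
        px < (poly[j, 1] - poly[i, 1]) * (py - poly[i, 2]) /
        (poly[j, 2] - poly[i, 2]) + poly[i, 1])
      inside <- !inside
    j <- i
  }
  inside
}

#' Place the eight breast boundary points
#'
#' Three of the eight points are anchored directly on landmarks: the
#' sternomanubrial point shifted to the chosen side's parasternal line
#' (superior-medial), the side's superolateral landmark, and the side's
#' midaxillary landmark (lateral). The remaining five are placed by the
#' \code{\link{boundary_offsets}} recipe in the frontal plane and all eight
#' are projected onto the skin along the anterior axis (nearest-point fallback
#' at the lateral silhouette). Point order: superior-medial, superior,
#' superolateral, lateral, inferolateral, inferior, inferomedial, medial.
#'
#' @param mesh \code{triangle_mesh} in \strong{frame coordinates}.
#' @param landmarks \code{landmark_set} in frame coordinates (or world
#'   coordinates together with \code{frame}).
#' @param frame the \code{reference_frame}; if supplied, \code{mesh} and
#'   \code{landmarks} given in world coordinates are transformed first.
#' @param side \code{"left"} or \code{"right"} (the subject's side).
#' @param offsets a \code{boundary_offsets} recipe.
#' @param max_projection_dist guard (mm): error if a boundary point must move
#'   farther than this to reach the mesh.
#' @return object of class \code{boundary_points}: list with \code{points}
#'   (8 x 3, frame coordinates), \code{labels}, \code{side}.
#' @export
place_boundary_points <- function(mesh, landmarks, frame = NULL,
                                  side = c("left", "right"),
                                  offsets = boundary_offsets(),
                                  max_projection_dist = 60) {
  side <- match.arg(side)
  stopifnot(inherits(offsets, "boundary_offsets"))
  if (!is.null(frame)) {
    mesh <- to_frame_coordinates(mesh, frame)
    landmarks <- to_frame_coordinates(landmarks, frame)
  }
  sgn <- if (side == "right") 1 else -1
  d_ma <- vnorm(landmarks$midaxillary_R - landmarks$midaxillary_L)
  sl <- landmarks[[paste0("superolateral_", if (side == "right") "R" else "L")]]
  ma <- landmarks[[paste0("midaxillary_", if (side == "right") "R" else "L")]]
  y_sm <- landmarks$sternomanubrial[2]
  x_med <- sgn * offsets$parasternal * d_ma
  x_lat <- ma[1]
  y_mid <- y_sm - offsets$nipple_drop * d_ma
  y_inf <- y_sm - offsets$inframammary_drop * d_ma
  y_infc <- y_inf - offsets$inferior_extra * d_ma
  lerp <- function(f) x_med + f * (x_lat - x_med)
  tgt <- rbind(
    superior_medial = c(x_med, y_sm),
    superior        = c((x_med + sl[1]) / 2, y_sm),
    superolateral   = sl[1:2],
    lateral         = ma[1:2],
    inferolateral   = c(lerp(offsets$inferolateral_frac), y_inf),
    inferior        = c(lerp(offsets$inferior_frac), y_infc),
    inferomedial    = c(lerp(offsets$inferomedial_frac), y_inf),
    medial          = c(x_med, y_mid))
  # anterior-axis projection for the interior points; the lateral anchor sits
  # on the silhouette where the axis ray grazes, so it is projected to the
  # exact nearest surface point of its landmark instead (stable and on-skin)
  z0 <- max(mesh$vertices[, 3])
  z_seed <- c(z0, z0, sl[3], ma[3], z0, z0, z0, z0)
  pts <- cbind(tgt, z_seed)
  ray <- project_onto_surface(pts[-4, , drop = FALSE], mesh,
                              fallback = TRUE, max_dist = Inf)
  pts[-4, ] <- ray
  pts[4, ] <- nearest_point_on_mesh(ma, mesh)$point
  # guard: anchors must actually be near the mesh (catches landmarks far off
  # the surface); measured in the frontal plane plus anterior reach
  d_lm <- c(nearest_point_on_mesh(sl, mesh)$distance,
            nearest_point_on_mesh(ma, mesh)$distance,
            nearest_point_on_mesh(landmarks$sternomanubrial, mesh)$distance)
  if (any(d_lm > max_projection_dist))
    stop("landmark projection failure: a landmark lies ",
         sprintf("%.0f", max(d_lm)), " mm from the mesh surface")
  dxy <- sqrt(rowSums((pts[, 1:2] - tgt)^2))
  if (any(dxy > max_projection_dist))
    stop("boundary projection failure: point '",
         BOUNDARY_POINT_LABELS[which.max(dxy)], "' moved ",
         sprintf("%.0f", max(dxy)), " mm in the frontal plane")
  if (!is_simple_polygon(pts[, 1:2]))
    stop("boundary points form a self-intersecting polygon")
  rownames(pts) <- BOUNDARY_POINT_LABELS
  structure(list(points = pts, labels = BOUNDARY_POINT_LABELS, side = side),
            class = "boundary_points")
}

#' @export
print.boundary_points <- function(x, ...) {
  cat("boundary_points (", x$side, " side, frame coordinates, mm):\n",
      sep = "")
  print(round(x$points, 2))
  invisible(x)
}

# Closed uniform Catmull-Rom spline through control points P (n x 3).
# t in [0, 1) global parameter; returns points on the spline.
catmull_rom_closed <- function(P, t) {
  n <- nrow(P)
  t <- t %% 1
  u <- t * n
  seg <- pmin(floor(u), n - 1)
  s <- u - seg
  i0 <- ((seg - 1) %% n) + 1
  i1 <- (seg %% n) + 1
  i2 <- ((seg + 1) %% n) + 1
  i3 <- ((seg + 2) %% n) + 1
  p0 <- P[i0, , drop = FALSE]; p1 <- P[i1, , drop = FALSE]
  p2 <- P[i2, , drop = FALSE]; p3 <- P[i3, , drop = FALSE]
  m1 <- (p2 - p0) / 2
  m2 <- (p3 - p1) / 2
  s2 <- s * s; s3 <- s2 * s
  h00 <- 2 * s3 - 3 * s2 + 1
  h10 <- s3 - 2 * s2 + s
  h01 <- -2 * s3 + 3 * s2
  h11 <- s3 - s2
  h00 * p1 + h10 * m1 + h01 * p2 + h11 * m2
}

#' Fit the closed breast boundary curve
#'
#' A closed uniform Catmull-Rom spline (C1, interpolating, local) is fitted
#' through the eight boundary points in order, densely sampled, and each
#' sample re-projected onto the skin along the anterior axis so the boundary
#' lies on the mesh. Samples can then be drawn at normalized arc length.
#'
#' @param points a \code{boundary_points} object.
#' @param mesh \code{triangle_mesh} in frame coordinates.
#' @param n_dense number of dense samples of the spline (default 512).
#' @return object of class \code{boundary_curve} with the raw spline control
#'   points, the projected dense polyline, cumulative arc length and total
#'   \code{length} (mm).
#' @export
fit_boundary_curve <- function(points, mesh, n_dense = 512) {
  stopifnot(inherits(points, "boundary_points"))
  P <- points$points
  dup <- sqrt(rowSums((P - P[c(2:nrow(P), 1), ])^2))
  if (any(dup < 1e-6))
    stop("coincident consecutive boundary points (",
         paste(points$labels[dup < 1e-6], collapse = ", "), ")")
  t <- (seq_len(n_dense) - 1) / n_dense
  raw <- catmull_rom_closed(P, t)
  # re-projection uses the exact nearest point on the mesh: continuous in the
  # input (unlike an axis ray, which grazes at the lateral silhouette) and
  # idempotent for points already on the surface
  npi <- make_np_index(mesh)
  dense <- t(vapply(seq_len(n_dense), function(i)
    nearest_point_index(raw[i, ], npi)$point, numeric(3)))
  seglen <- sqrt(rowSums((dense - dense[c(2:n_dense, 1), ])^2))
  cum <- c(0, cumsum(seglen))
  if (!is_simple_polygon(dense[, 1:2]))
    stop("fitted boundary curve self-intersects in the frontal plane")
  # medial / lateral extreme parameters of the smooth spline (exact local
  # optimisation: an argmax over projected samples would tie-break unstably
  # along the flat silhouette of a tessellated torso)
  xr <- function(tt) catmull_rom_closed(P, tt)[, 1]
  refine <- function(i, maximum) {
    br <- t[i] + c(-2, 2) / n_dense
    stats::optimize(xr, br, maximum = maximum,
                    tol = 1e-10)[[if (maximum) "maximum" else "minimum"]] %% 1
  }
  t_hi <- refine(which.max(raw[, 1]), TRUE)
  t_lo <- refine(which.min(raw[, 1]), FALSE)
  ext_pt <- function(tt)
    nearest_point_index(drop(catmull_rom_closed(P, tt)), npi)$point
  structure(list(knots = P, side = points$side, t = t, raw = raw,
                 dense = dense, cumlen = cum,
                 length = cum[n_dense + 1],
                 t_extreme = c(lo = t_lo, hi = t_hi),
                 extreme_points = list(lo = ext_pt(t_lo), hi = ext_pt(t_hi))),
            class = "boundary_curve")
}

#' Evaluate the raw boundary spline
#'
#' The interpolating spline before re-projection onto the skin (knot k is at
#' parameter \code{(k - 1) / 8}).
#'
#' @param curve a \code{boundary_curve}.
#' @param t parameter(s) in \code{[0, 1)}, periodic.
#' @return points on the spline (n x 3).
#' @export
evaluate_boundary_spline <- function(curve, t) {
  catmull_rom_closed(curve$knots, t)
}

#' Sample the projected boundary curve
#'
#' Linear interpolation along the dense projected polyline at normalized arc
#' length \code{u} in \code{[0, 1)}.
#'
#' @param curve a \code{boundary_curve}.
#' @param u normalized arc length value(s).
#' @return n x 3 matrix of boundary points on the mesh.
#' @export
sample_boundary <- function(curve, u) {
  n <- nrow(curve$dense)
  s <- (u %% 1) * curve$length
  i <- findInterval(s, curve$cumlen, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), n)
  s0 <- curve$cumlen[i]
  s1 <- curve$cumlen[i + 1]
  w <- ifelse(s1 > s0, (s - s0) / (s1 - s0), 0)
  nxt <- (i %% n) + 1L
  curve$dense[i, , drop = FALSE] * (1 - w) +
    curve$dense[nxt, , drop = FALSE] * w
}

#' @export
print.boundary_curve <- function(x, ...) {
  cat(sprintf("boundary_curve (%s side): 8 knots, %d dense samples, arc length %.1f mm\n",
              x$side, nrow(x$dense), x$length))
  invisible(x)
}
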