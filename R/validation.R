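# Validation machinery: signed distance maps between a simulated and a true
# (breastless) chest wall, the area-times-distance volume-error statistic, and
# the landmark-repeatability measures and t-tests.

#' Signed distance map from a simulated wall to a true chest wall
#'
#' For every face of the simulated wall, the distance from the face centroid
#' to the nearest point on the true chest wall, signed by the anterior
#' component of (centroid - nearest point): positive faces lie in front of
#' (anterior to) the true wall, negative faces behind it. Faces whose nearest
#' point falls on an open boundary edge of the truth patch are flagged as
#' outside coverage and excluded from summary means (with a warning).
#'
#' @param sim a \code{chest_wall} or \code{triangle_mesh} (world
#'   coordinates).
#' @param truth true chest-wall \code{triangle_mesh} (world coordinates).
#' @param frame \code{reference_frame} defining the anterior axis; defaults to
#'   the wall's own frame (identity for a bare mesh).
#' @param exhaustive force the brute-force all-triangles nearest-point path.
#' @return object of class \code{distance_map}: data frame columns
#'   \code{distance} (mm), \code{area} (mm^2), \code{flagged}; attributes keep
#'   the frame and meshes.
#' @export
signed_distance_map <- function(sim, truth, frame = NULL,
                                exhaustive = FALSE) {
  if (inherits(sim, "chest_wall")) {
    if (is.null(frame)) frame <- sim$frame
    sim_mesh <- sim$mesh
  } else {
    sim_mesh <- sim
    if (is.null(frame)) frame <- identity_frame()
  }
  stopifnot(inherits(sim_mesh, "triangle_mesh"),
            inherits(truth, "triangle_mesh"))
  ctr <- face_centroids(sim_mesh)
  ar <- face_areas(sim_mesh)
  idx <- make_np_index(truth)
  # open boundary edges of the truth patch, for coverage flagging
  f <- truth$faces
  ea <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(ea[, 1], ea[, 2]), pmax(ea[, 1], ea[, 2]))
  open_key <- names(which(table(key) == 1L))
  edge_of_face <- matrix(key, ncol = 3)
  n <- nrow(ctr)
  dist <- numeric(n)
  flagged <- logical(n)
  ant <- frame$anterior
  for (i in seq_len(n)) {
    np <- nearest_point_index(ctr[i, ], idx, exhaustive = exhaustive)
    s <- sum((ctr[i, ] - np$point) * ant)
    dist[i] <- if (s >= 0) np$distance else -np$distance
    if (np$distance > 1e-9 && any(edge_of_face[np$face, ] %in% open_key)) {
      # nearest point on a face with an open edge: on that edge -> outside
      # the truth footprint
      A <- idx$A[np$face, ]; B <- idx$B[np$face, ]; C <- idx$C[np$face, ]
      corners <- rbind(A, B, C)
      keys <- edge_of_face[np$face, ]
      for (e in 1:3) {
        if (!(keys[e] %in% open_key)) next
        a <- corners[e, ]; b <- corners[(e %% 3) + 1, ]
        tpar <- sum((np$point - a) * (b - a)) / max(sum((b - a)^2), 1e-300)
        onseg <- a + pmin(pmax(tpar, 0), 1) * (b - a)
        if (vnorm(np$point - onseg) < 1e-6) flagged[i] <- TRUE
      }
    }
  }
  if (any(flagged))
    warning(sum(flagged), " face(s) fall outside the true-wall coverage ",
            "and are excluded from summary statistics")
  structure(data.frame(distance = dist, area = ar, flagged = flagged),
            class = c("distance_map", "data.frame"),
            frame = frame, sim_area_cm2 = surface_area(sim_mesh))
}

#' @export
print.distance_map <- function(x, ...) {
  ok <- !x$flagged
  cat(sprintf("distance_map: %d faces (%d flagged outside coverage)\n",
              nrow(x), sum(x$flagged)))
  cat(sprintf("  signed distance [mm]: mean %+.3f  sd %.3f  range %+.2f..%+.2f\n",
              stats::weighted.mean(x$distance[ok], x$area[ok]),
              stats::sd(x$distance[ok]),
              min(x$distance[ok]), max(x$distance[ok])))
  invisible(x)
}

#' Frontal-plane view of a distance map
#'
#' Scatter of face centroids in the frontal plane, red where the simulated
#' wall lies anterior to the truth, green where posterior; intensity scales
#' with |distance|.
#'
#' @param x a \code{distance_map}.
#' @param wall the \code{chest_wall} the map was computed from.
#' @param ... passed to \code{plot}.
#' @export
plot.distance_map <- function(x, wall, ...) {
  ctr <- face_centroids(to_frame_coordinates(wall$mesh, attr(x, "frame")))
  d <- x$distance
  a <- pmin(abs(d) / max(abs(d), 1e-9), 1)
  col <- ifelse(d >= 0, grDevices::rgb(1, 1 - a, 1 - a),
                grDevices::rgb(1 - a, 1, 1 - a))
  plot(ctr[, 1], ctr[, 2], col = col, pch = 15, asp = 1,
       xlab = "right [mm]", ylab = "superior [mm]",
       main = "simulated wall vs true chest wall", ...)
  invisible(x)
}

#' Volume error of a simulated chest wall
#'
#' The validation statistic: the surface area of the simulated wall times its
#' mean signed distance to the true chest wall, converted to ml. Positive
#' means the simulated wall sits anterior to the truth (the breast volume is
#' underestimated). The mean is area-weighted by default (loft faces vary in
#' size); with \code{weighted = FALSE} a plain per-face mean is used.
#'
#' @param dmap a \code{distance_map}.
#' @param wall optional \code{chest_wall} or \code{triangle_mesh} whose total
#'   area should be used (defaults to the area recorded in the map).
#' @param weighted area-weight the mean distance (default TRUE).
#' @return volume error in ml.
#' @export
volume_error <- function(dmap, wall = NULL, weighted = TRUE) {
  stopifnot(inherits(dmap, "distance_map"))
  ok <- !dmap$flagged
  if (!any(ok)) stop("distance map has no usable (covered) faces")
  m <- if (weighted)
    stats::weighted.mean(dmap$distance[ok], dmap$area[ok])
  else mean(dmap$distance[ok])
  area_cm2 <- if (is.null(wall)) attr(dmap, "sim_area_cm2")
  else surface_area(if (inherits(wall, "chest_wall")) wall$mesh else wall)
  volume_error_ml(area_cm2, m)
}

#' Volume error from summary numbers
#'
#' The raw arithmetic of the validation formula: a wall of area
#' \code{area_cm2} with a mean signed distance \code{mean_distance_mm} to the
#' true chest wall corresponds to a volume error of
#' \code{area_cm2 * mean_distance_mm / 10} ml (100 mm^2 per cm^2, 1000 mm^3
#' per ml). Applying it to a distance standard deviation instead of the mean
#' gives the spread of the volume error.
#'
#' @param area_cm2 simulated-wall surface area (cm^2).
#' @param mean_distance_mm mean signed distance (or its SD) in mm.
#' @return volume error in ml.
#' @examples
#' volume_error_ml(285, 1.80) # 51.3 ml
#' @export
volume_error_ml <- function(area_cm2, mean_distance_mm) {
  area_cm2 * mean_distance_mm / 10
}

#' Validate a simulated chest wall against a true chest wall
#'
#' Computes the signed distance map and summarises it in the style of the
#' method's validation table: wall surface area, mean and SD of the signed
#' distance, and the resulting volume error and its spread.
#'
#' @inheritParams signed_distance_map
#' @param weighted area-weight the mean (see \code{\link{volume_error}}).
#' @return object of class \code{chestwall_validation}.
#' @export
validate_chest_wall <- function(sim, truth, frame = NULL, weighted = TRUE) {
  dmap <- signed_distance_map(sim, truth, frame = frame)
  ok <- !dmap$flagged
  area <- attr(dmap, "sim_area_cm2")
  m <- if (weighted) stats::weighted.mean(dmap$distance[ok], dmap$area[ok])
  else mean(dmap$distance[ok])
  s <- stats::sd(dmap$distance[ok])
  structure(list(surface_area_cm2 = area,
                 mean_distance_mm = m,
                 sd_distance_mm = s,
                 volume_error_ml = volume_error_ml(area, m),
                 volume_error_spread_ml = volume_error_ml(area, s),
                 n_faces = sum(ok), n_flagged = sum(!ok),
                 distance_map = dmap),
            class = "chestwall_validation")
}

#' @export
print.chestwall_validation <- function(x, ...) {
  cat("Chest-wall validation\n")
  cat(sprintf("  surface area:    %8.1f cm^2\n", x$surface_area_cm2))
  cat(sprintf("  distance error:  %+8.2f +/- %.2f mm\n",
              x$mean_distance_mm, x$sd_distance_mm))
  cat(sprintf("  volume error:    %+8.1f +/- %.1f ml\n",
              x$volume_error_ml, x$volume_error_spread_ml))
  if (x$n_flagged > 0)
    cat(sprintf("  (%d faces outside truth coverage excluded)\n",
                x$n_flagged))
  invisible(x)
}

#' Export a distance map
#'
#' Writes the per-face signed distances as JSON and, optionally, a
#' color-mapped OBJ of the wall (red anterior / green posterior, intensity
#' proportional to |distance|).
#'
#' @param dmap a \code{distance_map}.
#' @param wall the \code{chest_wall} it belongs to.
#' @param json_path output JSON path.
#' @param obj_path optional color OBJ path.
#' @return invisibly, \code{json_path}.
#' @export
export_distance_map <- function(dmap, wall, json_path, obj_path = NULL) {
  jsonlite::write_json(list(
    distance_mm = dmap$distance, face_area_mm2 = dmap$area,
    flagged = dmap$flagged,
    surface_area_cm2 = attr(dmap, "sim_area_cm2")),
    json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(obj_path)) {
    mesh <- wall$mesh
    # per-vertex color from incident face distances
    dmax <- max(abs(dmap$distance), 1e-9)
    vcol <- matrix(0, nrow(mesh$vertices), 3)
    wsum <- numeric(nrow(mesh$vertices))
    for (c in 1:3) {
      vi <- mesh$faces[, c]
      d <- dmap$distance
      a <- pmin(abs(d) / dmax, 1)
      col <- cbind(ifelse(d >= 0, 1, 1 - a),
                   ifelse(d >= 0, 1 - a, 1),
                   1 - a)
      for (j in seq_along(vi)) {
        vcol[vi[j], ] <- vcol[vi[j], ] + col[j, ]
        wsum[vi[j]] <- wsum[vi[j]] + 1
      }
    }
    vcol <- vcol / pmax(wsum, 1)
    write_obj(mesh, obj_path, vertex_colors = vcol)
  }
  invisible(json_path)
}

#' Landmark placement deviation
#'
#' Distance between a reference and a repeated placement of one landmark,
#' with the axis restrictions of the repeatability analysis: midaxillary
#' landmarks count only the ventral-dorsal (anterior-axis) component, the
#' sternomanubrial landmark only the superior-inferior component, and
#' superolateral landmarks the full 3D Euclidean distance.
#'
#' @param p_ref,p_test length-3 points (world coordinates, mm).
#' @param landmark_type one of \code{"sternomanubrial"},
#'   \code{"superolateral"}, \code{"midaxillary"} (label suffixes \code{_L} /
#'   \code{_R} are accepted).
#' @param frame \code{reference_frame} supplying the axes.
#' @return object of class \code{landmark_deviation}: list with
#'   \code{deviation} (mm, >= 0), \code{restriction}, \code{landmark_type}.
#' @export
landmark_deviation <- function(p_ref, p_test, landmark_type, frame) {
  base <- sub("_[LR]$", "", landmark_type)
  diffv <- as.numeric(p_test) - as.numeric(p_ref)
  dev <- switch(base,
    midaxillary = abs(sum(diffv * frame$anterior)),
    sternomanubrial = abs(sum(diffv * frame$superior)),
    superolateral = vnorm(diffv),
    stop("unknown landmark type '", landmark_type, "'"))
  restriction <- switch(base,
                        midaxillary = "ventral-dorsal",
                        sternomanubrial = "superior-inferior",
                        superolateral = "none")
  structure(list(landmark_type = landmark_type, deviation = dev,
                 restriction = restriction),
            class = "landmark_deviation")
}

#' @export
print.landmark_deviation <- function(x, ...) {
  cat(sprintf("landmark_deviation: %s = %.2f mm (restriction: %s)\n",
              x$landmark_type, x$deviation, x$restriction))
  invisible(x)
}

#' Deviations between two complete landmark sets
#'
#' @param ref,test \code{landmark_set} objects (world coordinates).
#' @param frame \code{reference_frame} for the axis restrictions.
#' @return data frame with one row per landmark: label, deviation (mm),
#'   restriction.
#' @export
landmark_set_deviation <- function(ref, test, frame) {
  rows <- lapply(LANDMARK_LABELS, function(lb) {
    d <- landmark_deviation(ref[[lb]], test[[lb]], lb, frame)
    data.frame(landmark = lb, deviation_mm = d$deviation,
               restriction = d$restriction)
  })
  do.call(rbind, rows)
}

#' Paired and one-sample t-tests
#'
#' Classical (non-Welch) t-tests as used in the repeatability and
#' volume-error analyses: \code{paired_t_test} tests whether matched
#' deviations differ; \code{one_sample_t_test} tests whether a mean differs
#' from \code{mu}. Identically equal paired samples return t = 0, p = 1 (no
#' evidence of a difference); any other zero-variance input is an error
#' because the t statistic is undefined.
#'
#' @param x,y numeric vectors of equal length (n >= 2).
#' @return list with \code{statistic} (t), \code{df}, \code{p.value}
#'   (two-sided) and the mean difference / mean.
#' @export
paired_t_test <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2) stop("paired t-test needs n >= 2")
  d <- x - y
  if (stats::sd(d) == 0) {
    if (all(d == 0))
      return(list(statistic = 0, df = length(x) - 1L, p.value = 1,
                  mean_difference = 0))
    stop("zero-variance nonzero differences: t statistic undefined")
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p.value = tt$p.value, mean_difference = unname(tt$estimate))
}

#' @rdname paired_t_test
#' @param mu reference value for the one-sample test (default 0).
#' @export
one_sample_t_test <- function(x, mu = 0) {
  if (length(x) < 2) stop("one-sample t-test needs n >= 2")
  if (stats::sd(x) == 0)
    stop("constant sample: t statistic undefined")
  tt <- stats::t.test(x, mu = mu)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p.value = tt$p.value, mean = unname(tt$estimate))
}
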