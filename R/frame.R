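# Landmark-based anatomical reference frame: an orthonormal right/superior/
# anterior axis triple (equivalently the sagittal, transverse and frontal
# planes) anchored on the sternomanubrial point. Replaces the manual placement
# step of the original interactive workflow with a deterministic construction.

#' Build the anatomical reference frame from landmarks
#'
#' Convention (documented once, referenced everywhere): \code{x = right}
#' (toward the subject's right), \code{y = superior}, \code{z = anterior}.
#' The right axis is the unit vector from \code{midaxillary_L} to
#' \code{midaxillary_R}; the anterior axis is the component of
#' (sternomanubrial - midpoint of the midaxillaries) orthogonal to the right
#' axis; the superior axis completes the right-handed triple
#' (\code{right x superior = anterior}). The origin is the sternomanubrial
#' point. The sagittal plane is perpendicular to the right axis, the
#' transverse plane to the superior axis, and the frontal plane to the
#' anterior axis.
#'
#' @param landmarks a \code{landmark_set}.
#' @param min_angle_deg degeneracy guard: the sternomanubrial offset must make
#'   at least this angle (default 5 degrees) with the midaxillary axis.
#' @return an object of class \code{reference_frame} with fields
#'   \code{origin}, \code{right}, \code{superior}, \code{anterior}.
#' @export
build_reference_frame <- function(landmarks, min_angle_deg = 5) {
  stopifnot(inherits(landmarks, "landmark_set"))
  right <- landmarks$midaxillary_R - landmarks$midaxillary_L
  if (vnorm(right) < 1) stop("midaxillary landmarks coincide")
  right <- normalize(right)
  mid <- (landmarks$midaxillary_L + landmarks$midaxillary_R) / 2
  a0 <- landmarks$sternomanubrial - mid
  ant <- a0 - sum(a0 * right) * right
  if (vnorm(ant) < vnorm(a0) * sin(min_angle_deg * pi / 180) ||
      vnorm(ant) < 1e-9)
    stop("degenerate landmarks: sternomanubrial point is (nearly) collinear ",
         "with the midaxillary axis")
  ant <- normalize(ant)
  sup <- normalize(c(ant[2] * right[3] - ant[3] * right[2],
                     ant[3] * right[1] - ant[1] * right[3],
                     ant[1] * right[2] - ant[2] * right[1]))
  structure(list(origin = landmarks$sternomanubrial,
                 right = right, superior = sup, anterior = ant),
            class = "reference_frame")
}

#' @export
print.reference_frame <- function(x, ...) {
  cat("reference_frame (x = right, y = superior, z = anterior):\n")
  cat(sprintf("  origin   %8.2f %8.2f %8.2f\n",
              x$origin[1], x$origin[2], x$origin[3]))
  for (nm in c("right", "superior", "anterior"))
    cat(sprintf("  %-8s %8.4f %8.4f %8.4f\n",
                nm, x[[nm]][1], x[[nm]][2], x[[nm]][3]))
  invisible(x)
}

frame_rotation <- function(frame) {
  cbind(frame$right, frame$superior, frame$anterior)
}

#' Express geometry in frame coordinates (and back)
#'
#' Rigidly maps world coordinates into the reference frame: the origin goes to
#' (0, 0, 0) and the right/superior/anterior axes to x/y/z. Distances are
#' preserved. Methods exist for point matrices, \code{triangle_mesh} and
#' \code{landmark_set} objects. \code{from_frame_coordinates} is the exact
#' inverse.
#'
#' @param x points (n x 3 matrix), \code{triangle_mesh} or
#'   \code{landmark_set}.
#' @param frame a \code{reference_frame}.
#' @return object of the same type, in frame (resp. world) coordinates.
#' @export
to_frame_coordinates <- function(x, frame) UseMethod("to_frame_coordinates")

#' @export
to_frame_coordinates.default <- function(x, frame) {
  p <- if (is.null(dim(x))) matrix(x, 1) else as.matrix(x)
  sweep(p, 2, frame$origin) %*% frame_rotation(frame)
}

#' @export
to_frame_coordinates.triangle_mesh <- function(x, frame) {
  x$vertices <- to_frame_coordinates.default(x$vertices, frame)
  x
}

#' @export
to_frame_coordinates.landmark_set <- function(x, frame) {
  out <- lapply(unclass(x), function(p)
    drop(to_frame_coordinates.default(p, frame)))
  class(out) <- "landmark_set"
  out
}

#' @rdname to_frame_coordinates
#' @export
from_frame_coordinates <- function(x, frame) UseMethod("from_frame_coordinates")

#' @export
from_frame_coordinates.default <- function(x, frame) {
  p <- if (is.null(dim(x))) matrix(x, 1) else as.matrix(x)
  sweep(p %*% t(frame_rotation(frame)), 2, frame$origin, "+")
}

#' @export
from_frame_coordinates.triangle_mesh <- function(x, frame) {
  x$vertices <- from_frame_coordinates.default(x$vertices, frame)
  x
}

#' @export
from_frame_coordinates.landmark_set <- function(x, frame) {
  out <- lapply(unclass(x), function(p)
    drop(from_frame_coordinates.default(p, frame)))
  class(out) <- "landmark_set"
  out
}

# identity frame: world coordinates already follow the x-right / y-superior /
# z-anterior convention
identity_frame <- function() {
  structure(list(origin = c(0, 0, 0),
                 right = c(1, 0, 0),
                 superior = c(0, 1, 0),
                 anterior = c(0, 0, 1)),
            class = "reference_frame")
}
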