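# The five anatomical landmarks that anchor the breast boundary: one
# sternomanubrial, two superolateral (transition of the pectoral curve into
# the breast curvature), two midaxillary.

LANDMARK_LABELS <- c("sternomanubrial",
                     "superolateral_L", "superolateral_R",
                     "midaxillary_L", "midaxillary_R")

#' Landmark set
#'
#' The five labelled anatomical points used to define the reference frame and
#' the breast boundary: the sternomanubrial joint (superior boundary level),
#' the left/right superolateral breast transition, and the left/right
#' midaxillary points (lateral boundary). Coordinates in mm; the suffixes
#' \code{_L}/\code{_R} refer to the subject's own left/right.
#'
#' @param sternomanubrial,superolateral_L,superolateral_R,midaxillary_L,midaxillary_R
#'   length-3 numeric vectors (mm).
#' @return an object of class \code{landmark_set} (named list of points).
#' @export
landmark_set <- function(sternomanubrial, superolateral_L, superolateral_R,
                         midaxillary_L, midaxillary_R) {
  pts <- list(sternomanubrial = sternomanubrial,
              superolateral_L = superolateral_L,
              superolateral_R = superolateral_R,
              midaxillary_L = midaxillary_L,
              midaxillary_R = midaxillary_R)
  pts <- lapply(pts, function(p) {
    p <- as.numeric(p)
    if (length(p) != 3L || !all(is.finite(p)))
      stop("each landmark must be a finite 3D point")
    p
  })
  m <- do.call(rbind, pts)
  d <- as.matrix(stats::dist(m))
  diag(d) <- Inf
  if (min(d) <= 1)
    stop("landmarks closer than 1 mm: ",
         paste(LANDMARK_LABELS[which(d == min(d), arr.ind = TRUE)[1, ]],
               collapse = " / "))
  structure(pts, class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("landmark_set (mm):\n")
  for (nm in LANDMARK_LABELS)
    cat(sprintf("  %-16s %8.2f %8.2f %8.2f\n",
                nm, x[[nm]][1], x[[nm]][2], x[[nm]][3]))
  invisible(x)
}

#' Read / write landmark JSON
#'
#' The landmark file is a JSON object mapping the five label strings
#' (\code{sternomanubrial}, \code{superolateral_L}, \code{superolateral_R},
#' \code{midaxillary_L}, \code{midaxillary_R}) to \code{[x, y, z]} mm triples.
#'
#' @param path file path.
#' @return \code{read_landmarks}: a \code{landmark_set}.
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path))
    stop("landmark file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  missing <- setdiff(LANDMARK_LABELS, names(obj))
  if (length(missing))
    stop("landmark file lacks: ", paste(missing, collapse = ", "))
  do.call(landmark_set, obj[LANDMARK_LABELS])
}

#' @rdname read_landmarks
#' @param landmarks a \code{landmark_set}.
#' @export
write_landmarks <- function(landmarks, path) {
  jsonlite::write_json(unclass(landmarks), path,
                       auto_unbox = FALSE, digits = NA)
  invisible(path)
}

# Run expr with a temporarily seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Perturb landmarks with isotropic Gaussian noise
#'
#' Emulates rater variability in sticker placement: each landmark is displaced
#' by an independent isotropic 3D Gaussian with standard deviation \code{sd}
#' per axis. Deterministic given \code{seed}; the caller's RNG state is left
#' untouched.
#'
#' @param landmarks a \code{landmark_set}.
#' @param sd per-axis standard deviation (mm), >= 0.
#' @param seed integer seed.
#' @return a jittered \code{landmark_set}.
#' @export
jitter_landmarks <- function(landmarks, sd, seed = 1L) {
  if (!is.numeric(sd) || length(sd) != 1L || is.na(sd) || sd < 0)
    stop("sd must be a single non-negative number")
  if (sd == 0) return(landmarks)
  noise <- with_seed(seed, matrix(stats::rnorm(15, sd = sd), 5, 3))
  out <- landmarks
  for (i in seq_along(LANDMARK_LABELS))
    out[[LANDMARK_LABELS[i]]] <- landmarks[[LANDMARK_LABELS[i]]] + noise[i, ]
  out
}
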