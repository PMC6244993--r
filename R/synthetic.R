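# Synthetic subjects: parametric torsos with a smoothly blended
# half-ellipsoid breast of analytically known volume, anatomically placed
# landmarks, and the bare ("mastectomy-side") chest wall stored as ground
# truth. Every pipeline stage is testable against these without any scan data.

#' Parameters of a synthetic torso
#'
#' The trunk is an elliptic cylinder (semi-axes \code{trunk_half_width} along
#' x, \code{trunk_half_depth} along z, height \code{trunk_height} along y)
#' whose anterior-posterior semi-axis is scaled by a parabolic profile in
#' height, \eqn{f(y) = 1 - (d/B)\,(y/y_{ref})^2} with \code{d = profile_drop},
#' emulating the vertical convexity of a rib cage (\code{profile_drop = 0}
#' recovers an exact cylinder with straight vertical rulings). The breast is a
#' half-ellipsoid bump (semi-axes \code{breast_a} lateral, \code{breast_b}
#' vertical, \code{breast_c} anterior) added as an anterior displacement over
#' an elliptic footprint centred \code{breast_center_offset} mm lateral of the
#' midline at height 0; a C1 radial ramp of width \code{blend} fades the bump
#' at its rim so the breast-trunk transition (where the superolateral landmark
#' sits) is well defined. Without blending the bump volume is exactly
#' \eqn{\frac{2}{3}\pi a b c}; with blending the reduction factor is computed
#' by quadrature and reported.
#'
#' @param trunk_half_width,trunk_half_depth trunk semi-axes (mm).
#' @param trunk_height trunk length along y (mm).
#' @param profile_drop drop of the anterior semi-axis at \code{profile_ref} mm
#'   from the apex (mm); 0 gives an exact elliptic cylinder.
#' @param profile_ref reference height for \code{profile_drop} (mm).
#' @param breast_a,breast_b,breast_c breast semi-axes (mm).
#' @param breast_center_offset lateral offset of the breast centre (mm).
#' @param superior_margin distance (mm) between the top of the breast
#'   footprint and the sternomanubrial level: breast tissue ends at the
#'   superior boundary, so the landmark sits slightly above the footprint.
#' @param side which side carries a breast: \code{"left"}, \code{"right"},
#'   \code{"both"}, \code{"none"}.
#' @param blend rim blend width (mm), < min(breast_a, breast_b).
#' @param jitter_sd landmark jitter SD per axis (mm); 0 = exact anatomical
#'   positions.
#' @param n_theta,n_y tessellation resolution (circumferential x vertical).
#' @param seed integer seed fixing all randomness (the landmark jitter).
#' @return an object of class \code{torso_params}.
#' @export
torso_params <- function(trunk_half_width = 140, trunk_half_depth = 95,
                         trunk_height = 600,
                         profile_drop = 18, profile_ref = 150,
                         breast_a = 50, breast_b = 40, breast_c = 55,
                         breast_center_offset = 62,
                         superior_margin = 10,
                         side = c("left", "right", "both", "none"),
                         blend = 8, jitter_sd = 0,
                         n_theta = 160, n_y = 120, seed = 1L) {
  side <- match.arg(side)
  p <- list(trunk_half_width = trunk_half_width,
            trunk_half_depth = trunk_half_depth,
            trunk_height = trunk_height,
            profile_drop = profile_drop, profile_ref = profile_ref,
            breast_a = breast_a, breast_b = breast_b, breast_c = breast_c,
            breast_center_offset = breast_center_offset,
            superior_margin = superior_margin,
            side = side, blend = blend, jitter_sd = jitter_sd,
            n_theta = as.integer(n_theta), n_y = as.integer(n_y),
            seed = as.integer(seed))
  lens <- c("trunk_half_width", "trunk_half_depth", "trunk_height",
            "profile_ref", "breast_a", "breast_b", "breast_c",
            "breast_center_offset", "superior_margin")
  for (nm in lens)
    if (!is.numeric(p[[nm]]) || p[[nm]] <= 0)
      stop("'", nm, "' must be positive")
  if (p$profile_drop < 0) stop("'profile_drop' must be >= 0")
  if (p$blend < 0 || p$blend >= min(p$breast_a, p$breast_b))
    stop("'blend' must be in [0, min(breast_a, breast_b))")
  if (p$jitter_sd < 0) stop("'jitter_sd' must be >= 0")
  if (p$n_theta < 16 || p$n_y < 8) stop("tessellation too coarse")
  # the bump must stay on the front-facing trunk surface
  if ((p$breast_center_offset + p$breast_a) / p$trunk_half_width > 0.985)
    stop("breast footprint exceeds the trunk face (offset + a too large)")
  if (p$breast_b + p$superior_margin + 20 > p$trunk_height / 2)
    stop("breast footprint reaches the trunk ends")
  prof_end <- 1 - (p$profile_drop / p$trunk_half_depth) *
    (p$trunk_height / 2 / p$profile_ref)^2
  if (prof_end <= 0.05)
    stop("profile_drop collapses the trunk cross-section at its ends")
  structure(p, class = "torso_params")
}

# C1 rim ramp: 1 inside, smoothstep down to 0 at u = 1 over the blend zone.
blend_ramp <- function(u, u0) {
  s <- rep(1, length(u))
  zone <- u > u0
  w <- (u[zone] - u0) / (1 - u0)
  s[zone] <- 1 - (3 * w^2 - 2 * w^3)
  s[u >= 1] <- 0
  s
}

# bump height over the footprint; u = elliptic radius
bump_height <- function(u, c, u0) {
  h <- numeric(length(u))
  inside <- u < 1
  h[inside] <- c * sqrt(pmax(1 - u[inside]^2, 0)) * blend_ramp(u[inside], u0)
  h
}

#' Generate a synthetic subject
#'
#' Builds the tessellated torso (watertight, capped top and bottom), the bare
#' trunk, the five landmarks at their anatomical definitions (optionally
#' jittered), the true chest-wall patches (the bare trunk surface under each
#' breast footprint), and the analytic breast volume per side. Deterministic
#' given \code{params$seed}.
#'
#' @param params a \code{torso_params} object.
#' @return object of class \code{synthetic_subject}: \code{torso} and
#'   \code{trunk} meshes, \code{landmarks} (jittered) and
#'   \code{landmarks_true}, \code{true_wall} (list with \code{left} /
#'   \code{right} patch meshes), \code{analytic_volume_ml} (named vector),
#'   \code{blend_factor}, \code{params}.
#' @export
generate_torso <- function(params = torso_params()) {
  stopifnot(inherits(params, "torso_params"))
  p <- params
  A <- p$trunk_half_width; B <- p$trunk_half_depth
  H <- p$trunk_height
  f_prof <- function(y) 1 - (p$profile_drop / B) * (y / p$profile_ref)^2
  nt <- p$n_theta; ny <- p$n_y
  theta <- -pi + (seq_len(nt) - 0.5) * 2 * pi / nt  # symmetric under x -> -x
  yy <- seq(-H / 2, H / 2, length.out = ny)
  th <- rep(theta, times = ny)
  yv <- rep(yy, each = nt)
  X <- A * sin(th)
  Z <- B * f_prof(yv) * cos(th)
  verts <- cbind(X, yv, Z)
  vid <- function(i, j) (j - 1L) * nt + i  # i circumferential, j vertical
  faces <- vector("list", 2L * nt * (ny - 1L) + 2L * nt)
  nf <- 0L
  for (j in seq_len(ny - 1L)) {
    i2 <- c(2:nt, 1L)
    a <- vid(seq_len(nt), j); b <- vid(i2, j)
    cc <- vid(i2, j + 1L); d <- vid(seq_len(nt), j + 1L)
    nf <- nf + 1L; faces[[nf]] <- cbind(a, b, cc)
    nf <- nf + 1L; faces[[nf]] <- cbind(a, cc, d)
  }
  # caps
  c_bot <- nrow(verts) + 1L
  c_top <- nrow(verts) + 2L
  verts <- rbind(verts, c(0, -H / 2, 0), c(0, H / 2, 0))
  i2 <- c(2:nt, 1L)
  nf <- nf + 1L
  faces[[nf]] <- cbind(c_bot, vid(i2, 1L), vid(seq_len(nt), 1L))
  nf <- nf + 1L
  faces[[nf]] <- cbind(c_top, vid(seq_len(nt), ny), vid(i2, ny))
  fmat <- do.call(rbind, faces[seq_len(nf)])
  trunk <- triangle_mesh(verts, fmat, clean = FALSE)

  sides_with_breast <- switch(p$side,
                              left = "left", right = "right",
                              both = c("left", "right"), none = character(0))
  u0 <- if (p$blend > 0) 1 - p$blend / min(p$breast_a, p$breast_b) else 1
  torso <- trunk
  for (s in sides_with_breast) {
    sgn <- if (s == "right") 1 else -1
    xc <- sgn * p$breast_center_offset
    u <- sqrt(((torso$vertices[, 1] - xc) / p$breast_a)^2 +
                ((torso$vertices[, 2] - 0) / p$breast_b)^2)
    front <- torso$vertices[, 3] > 0
    h <- bump_height(u, p$breast_c, u0)
    h[!front] <- 0
    torso$vertices[, 3] <- torso$vertices[, 3] + h
  }

  # landmarks at their anatomical definitions on the generated geometry:
  # the sternomanubrial level marks the superior end of the breast tissue
  # (footprint top plus margin); the superolateral landmark sits at the outer
  # edge of the breast-trunk blend zone along the 45-degree superolateral
  # direction; the midaxillary points at the lateral extremes at armpit height
  y_sm <- p$breast_b + p$superior_margin
  zsurf <- function(x, y) {
    stopifnot(abs(x) <= A)
    B * f_prof(y) * cos(asin(x / A))
  }
  sl_point <- function(sgn) {
    x <- sgn * (p$breast_center_offset + (p$breast_a + p$blend) / sqrt(2))
    y <- (p$breast_b + p$blend) / sqrt(2)
    c(x, y, zsurf(x, y))
  }
  lm_true <- landmark_set(
    sternomanubrial = c(0, y_sm, zsurf(0, y_sm)),
    superolateral_L = sl_point(-1),
    superolateral_R = sl_point(1),
    midaxillary_L = c(-A, y_sm, 0),
    midaxillary_R = c(A, y_sm, 0))
  lm <- if (p$jitter_sd > 0)
    jitter_landmarks(lm_true, p$jitter_sd, seed = p$seed) else lm_true

  # true chest wall: the bare trunk surface behind each breast footprint,
  # generous enough to cover the whole boundary region of that side
  ctr <- face_centroids(trunk)
  d_ma <- 2 * A
  wall_patch <- function(sgn) {
    keep <- ctr[, 3] > -25 &
      sgn * ctr[, 1] > -15 &
      ctr[, 2] > y_sm - 0.50 * d_ma & ctr[, 2] < y_sm + 30
    triangle_mesh(trunk$vertices, trunk$faces[keep, , drop = FALSE],
                  clean = FALSE)
  }
  blend_factor <- if (p$blend > 0) {
    3 * stats::integrate(function(u)
      sqrt(pmax(1 - u^2, 0)) * blend_ramp(u, u0) * u,
      0, 1, rel.tol = 1e-10)$value
  } else 1
  v_one <- 2 / 3 * pi * p$breast_a * p$breast_b * p$breast_c *
    blend_factor / 1000
  vols <- c(left = if ("left" %in% sides_with_breast) v_one else 0,
            right = if ("right" %in% sides_with_breast) v_one else 0)
  structure(list(torso = torso, trunk = trunk,
                 landmarks = lm, landmarks_true = lm_true,
                 true_wall = list(left = wall_patch(-1),
                                  right = wall_patch(1)),
                 analytic_volume_ml = vols,
                 blend_factor = blend_factor,
                 params = p),
            class = "synthetic_subject")
}

#' @export
print.synthetic_subject <- function(x, ...) {
  p <- x$params
  cat(sprintf("synthetic_subject: %d-vertex torso, breast side = %s\n",
              nrow(x$torso$vertices), p$side))
  cat(sprintf("  breast semi-axes %g x %g x %g mm, blend %g mm (factor %.4f)\n",
              p$breast_a, p$breast_b, p$breast_c, p$blend, x$blend_factor))
  cat(sprintf("  analytic volume [ml]: left %.1f, right %.1f\n",
              x$analytic_volume_ml["left"], x$analytic_volume_ml["right"]))
  invisible(x)
}
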