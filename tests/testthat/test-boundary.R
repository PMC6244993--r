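# Breast boundary points and the closed boundary curve.

frame_pieces <- function(subj) {
  fr <- build_reference_frame(subj$landmarks)
  list(frame = fr,
       mesh_f = to_frame_coordinates(subj$torso, fr),
       lm_f = to_frame_coordinates(subj$landmarks, fr))
}

test_that("boundary points lie on the mesh with landmark-anchored positions", {
  subj <- get_subject("s1", small_params(1))
  fp <- frame_pieces(subj)
  bp <- place_boundary_points(fp$mesh_f, fp$lm_f, side = "left")
  expect_equal(nrow(bp$points), 8L)
  for (i in 1:8) {
    d <- nearest_point_on_mesh(bp$points[i, ], fp$mesh_f)$distance
    expect_lt(d, 2)
  }
  # anchor points near the projections of their landmarks
  sl <- bp$points["superolateral", ]
  expect_lt(sqrt(sum((sl[1:2] - fp$lm_f$superolateral_L[1:2])^2)), 2)
  la <- bp$points["lateral", ]
  expect_lt(sqrt(sum((la - fp$lm_f$midaxillary_L)^2)), 2)
  expect_true(breastvol:::is_simple_polygon(bp$points[, 1:2]))
})

test_that("landmarks far off the mesh give a projection error", {
  subj <- get_subject("s1", small_params(1))
  fp <- frame_pieces(subj)
  lm_bad <- fp$lm_f
  lm_bad$superolateral_L <- lm_bad$superolateral_L + c(0, 0, 500)
  expect_error(place_boundary_points(fp$mesh_f, lm_bad, side = "left"),
               "projection failure")
})

test_that("mirrored torso with flipped side mirrors the boundary points", {
  subj <- get_subject("s1", small_params(1))
  lm <- subj$landmarks
  mm <- subj$torso
  mm$vertices[, 1] <- -mm$vertices[, 1]
  mm$faces <- mm$faces[, c(1, 3, 2)]
  lm_m <- landmark_set(
    sternomanubrial = lm$sternomanubrial * c(-1, 1, 1),
    superolateral_L = lm$superolateral_R * c(-1, 1, 1),
    superolateral_R = lm$superolateral_L * c(-1, 1, 1),
    midaxillary_L = lm$midaxillary_R * c(-1, 1, 1),
    midaxillary_R = lm$midaxillary_L * c(-1, 1, 1))
  f1 <- build_reference_frame(lm)
  f2 <- build_reference_frame(lm_m)
  bp1 <- place_boundary_points(to_frame_coordinates(subj$torso, f1),
                               to_frame_coordinates(lm, f1), side = "left")
  bp2 <- place_boundary_points(to_frame_coordinates(mm, f2),
                               to_frame_coordinates(lm_m, f2),
                               side = "right")
  expect_equal(bp2$points %*% diag(c(-1, 1, 1)), bp1$points,
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("closed Catmull-Rom through circle points stays near the circle", {
  flat <- sheet_mesh(c(-90, 90), c(-90, 90), n = 5)
  bp <- circle_boundary_points(r = 60)
  curve <- fit_boundary_curve(bp, flat)
  radii <- sqrt(rowSums(curve$dense[, 1:2]^2))
  expect_lt(max(abs(radii - 60)), 0.02 * 60)
  # curve closes
  expect_equal(sample_boundary(curve, 0), sample_boundary(curve, 1),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("the spline interpolates its knots before re-projection", {
  flat <- sheet_mesh(c(-90, 90), c(-90, 90), n = 5)
  bp <- circle_boundary_points(r = 60)
  curve <- fit_boundary_curve(bp, flat)
  knot_params <- (0:7) / 8
  at_knots <- evaluate_boundary_spline(curve, knot_params)
  expect_equal(at_knots, bp$points, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("coincident consecutive boundary points are rejected", {
  flat <- sheet_mesh(c(-90, 90), c(-90, 90), n = 5)
  bp <- circle_boundary_points(r = 60)
  bp$points[2, ] <- bp$points[1, ]
  expect_error(fit_boundary_curve(bp, flat), "oincident")
})

test_that("re-projection onto the mesh is idempotent", {
  subj <- get_subject("s1", small_params(1))
  fp <- frame_pieces(subj)
  bp <- place_boundary_points(fp$mesh_f, fp$lm_f, side = "left")
  curve <- fit_boundary_curve(bp, fp$mesh_f)
  again <- t(apply(curve$dense, 1, function(p)
    nearest_point_on_mesh(p, fp$mesh_f)$point))
  expect_lt(max(abs(again - curve$dense)), 1e-6)
})

test_that("the nipple apex lies inside the frontal boundary polygon", {
  subj <- get_subject("s1", small_params(1))
  fp <- frame_pieces(subj)
  bp <- place_boundary_points(fp$mesh_f, fp$lm_f, side = "left")
  curve <- fit_boundary_curve(bp, fp$mesh_f)
  # breast apex: most anterior torso vertex
  apex <- fp$mesh_f$vertices[which.max(fp$mesh_f$vertices[, 3]), ]
  expect_true(breastvol:::point_in_polygon(apex[1], apex[2],
                                           curve$dense[, 1:2]))
})

test_that("boundary arc length scales linearly with the subject", {
  subj <- get_subject("s1", small_params(1))
  fp <- frame_pieces(subj)
  bp <- place_boundary_points(fp$mesh_f, fp$lm_f, side = "left")
  curve <- fit_boundary_curve(bp, fp$mesh_f)
  s <- 1.7
  mesh_s <- fp$mesh_f
  mesh_s$vertices <- mesh_s$vertices * s
  lm_s <- fp$lm_f
  for (nm in names(lm_s)) lm_s[[nm]] <- lm_s[[nm]] * s
  class(lm_s) <- "landmark_set"
  bp_s <- place_boundary_points(mesh_s, lm_s, side = "left")
  curve_s <- fit_boundary_curve(bp_s, mesh_s)
  expect_equal(curve_s$length / curve$length, s, tolerance = 1e-6)
})

test_that("boundary offsets are validated", {
  expect_error(boundary_offsets(parasternal = 1.2), "fraction")
  expect_error(boundary_offsets(nipple_drop = -0.1), "fraction")
})
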