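# Bezier evaluation, the vertical curve framework, and the lofted wall.

test_that("Bezier evaluation has exact endpoints and affine midpoints", {
  bz <- cubic_bezier(c(0, 0, 0), c(0, 10, 10), c(0, 20, 10), c(0, 30, 0))
  expect_equal(drop(evaluate_bezier(bz, 0)), bz$p0)
  expect_equal(drop(evaluate_bezier(bz, 1)), bz$p3)
  # collinear equally spaced control points: curve is the segment
  seg <- cubic_bezier(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2), c(3, 3, 3))
  expect_equal(drop(evaluate_bezier(seg, 0.5)), c(1.5, 1.5, 1.5),
               tolerance = 1e-12)
  expect_error(evaluate_bezier(bz, 1.5), "\\[0, 1\\]")
  expect_error(evaluate_bezier(bz, -0.1), "\\[0, 1\\]")
})

test_that("Bezier evaluation matches the de Casteljau oracle", {
  bz <- cubic_bezier(c(0, 0, 0), c(0, 10, 10), c(0, 20, 10), c(0, 30, 0))
  for (t in c(0.1, 0.25, 0.5, 0.75, 0.9)) {
    expect_equal(drop(evaluate_bezier(bz, t)),
                 de_casteljau(bz$p0, bz$p1, bz$p2, bz$p3, t),
                 tolerance = 1e-12)
  }
  set.seed(21)
  for (i in 1:20) {
    cp <- lapply(1:4, function(j) runif(3, -50, 50))
    bz2 <- cubic_bezier(cp[[1]], cp[[2]], cp[[3]], cp[[4]])
    t <- runif(1)
    expect_equal(drop(evaluate_bezier(bz2, t)),
                 de_casteljau(cp[[1]], cp[[2]], cp[[3]], cp[[4]], t),
                 tolerance = 1e-12)
  }
})

test_that("bchl presets resolve and invalid values error", {
  expect_equal(breastvol:::resolve_bchl("bchl020"), 0.20)
  expect_equal(breastvol:::resolve_bchl("bchl033"), 0.33)
  expect_equal(breastvol:::resolve_bchl("bchl050"), 0.50)
  expect_error(breastvol:::resolve_bchl(1.5), "\\[0, 1\\]")
  expect_error(breastvol:::resolve_bchl("bchl070"), "preset")
})

test_that("bchl = 0 gives straight chords; handle lengths follow the chord", {
  subj <- get_subject("s1", small_params(1))
  fr <- build_reference_frame(subj$landmarks)
  mesh_f <- to_frame_coordinates(subj$torso, fr)
  lm_f <- to_frame_coordinates(subj$landmarks, fr)
  bp <- place_boundary_points(mesh_f, lm_f, side = "left")
  curve <- fit_boundary_curve(bp, mesh_f)
  fw0 <- build_bezier_framework(mesh_f, curve, bchl = 0, K = 12)
  for (cl in fw0$columns) {
    if (cl$degenerate) next
    b <- cl$bezier
    mid <- drop(evaluate_bezier(b, 0.5))
    chord_mid <- (b$p0 + b$p3) / 2
    expect_equal(mid, chord_mid, tolerance = 1e-9)
    # every interior sample collinear with the chord (the degenerate cubic
    # stays on the segment, though not affinely parametrized)
    chord <- b$p3 - b$p0
    for (t in c(0.25, 0.75)) {
      v <- drop(evaluate_bezier(b, t)) - b$p0
      perp <- v - sum(v * chord) / sum(chord^2) * chord
      expect_lt(sqrt(sum(perp^2)), 1e-9)
    }
  }
  fw33 <- build_bezier_framework(mesh_f, curve, bchl = 0.33, K = 12)
  for (cl in fw33$columns) {
    if (cl$degenerate) next
    b <- cl$bezier
    chord <- sqrt(sum((b$p3 - b$p0)^2))
    expect_equal(sqrt(sum((b$p1 - b$p0)^2)), 0.33 * chord, tolerance = 1e-9)
    expect_equal(sqrt(sum((b$p2 - b$p3)^2)), 0.33 * chord, tolerance = 1e-9)
  }
})

test_that("a longer handle gives a more convex (more anterior) curve", {
  subj <- get_subject("s1", small_params(1))
  fr <- build_reference_frame(subj$landmarks)
  mesh_f <- to_frame_coordinates(subj$torso, fr)
  lm_f <- to_frame_coordinates(subj$landmarks, fr)
  bp <- place_boundary_points(mesh_f, lm_f, side = "left")
  curve <- fit_boundary_curve(bp, mesh_f)
  fw20 <- build_bezier_framework(mesh_f, curve, bchl = 0.20, K = 12)
  fw50 <- build_bezier_framework(mesh_f, curve, bchl = 0.50, K = 12)
  tt <- seq(0, 1, length.out = 21)
  for (k in seq_len(12)) {
    c20 <- fw20$columns[[k]]; c50 <- fw50$columns[[k]]
    if (c20$degenerate) next
    chord_z <- function(b, t) {  # anterior deviation from the chord
      pts <- evaluate_bezier(b, t)
      base <- outer(1 - t, b$p0) + outer(t, b$p3)
      max(pts[, 3] - base[, 3])
    }
    expect_gt(chord_z(c50$bezier, tt), chord_z(c20$bezier, tt))
  }
})

test_that("interior anterior displacement is monotone in bchl", {
  subj <- get_subject("s1", small_params(1))
  fr <- build_reference_frame(subj$landmarks)
  mesh_f <- to_frame_coordinates(subj$torso, fr)
  lm_f <- to_frame_coordinates(subj$landmarks, fr)
  bp <- place_boundary_points(mesh_f, lm_f, side = "left")
  curve <- fit_boundary_curve(bp, mesh_f)
  bchls <- seq(0, 0.5, by = 0.1)
  mids <- sapply(bchls, function(b) {
    fw <- build_bezier_framework(mesh_f, curve, bchl = b, K = 12)
    vapply(fw$columns, function(cl) {
      if (cl$degenerate) return(NA_real_)
      drop(evaluate_bezier(cl$bezier, 0.5))[3]
    }, numeric(1))
  })
  for (k in seq_len(nrow(mids))) {
    if (anyNA(mids[k, ])) next
    expect_true(all(diff(mids[k, ]) >= -1e-9))
  }
})

test_that("Bezier endpoints lie on the boundary curve", {
  subj <- get_subject("s1", small_params(1))
  fr <- build_reference_frame(subj$landmarks)
  mesh_f <- to_frame_coordinates(subj$torso, fr)
  lm_f <- to_frame_coordinates(subj$landmarks, fr)
  bp <- place_boundary_points(mesh_f, lm_f, side = "left")
  curve <- fit_boundary_curve(bp, mesh_f)
  fw <- build_bezier_framework(mesh_f, curve, bchl = 0.33, K = 16)
  dense <- curve$dense
  for (cl in fw$columns) {
    pts <- if (cl$degenerate) rbind(cl$point)
    else rbind(cl$bezier$p0, cl$bezier$p3)
    # tolerance reflects the dense-polyline discretization of the continuous
    # projected curve (the refined medial/lateral extreme points sit between
    # polyline samples)
    for (i in seq_len(nrow(pts)))
      expect_lt(dist_to_polyline(pts[i, ], dense), 0.02)
  }
})

test_that("planar boundary with bchl = 0 lofts to a planar wall", {
  flat <- sheet_mesh(c(-90, 90), c(-90, 90), n = 25)
  bp <- circle_boundary_points(r = 60)
  curve <- fit_boundary_curve(bp, flat)
  fw <- build_bezier_framework(flat, curve, bchl = 0, K = 16)
  wall <- loft_chest_wall(fw, M = 16)
  expect_lt(max(abs(wall$mesh$vertices[, 3])), 1e-6)
})

test_that("the loft boundary loop stays on the boundary curve", {
  subj <- get_subject("s1", small_params(1))
  wall <- simulate_chest_wall(subj$torso, subj$landmarks, side = "left",
                              bchl = 0.33, K = 24, M = 24)
  fr <- wall$frame
  dense <- wall$boundary_curve$dense
  ring <- rbind(
    t(vapply(wall$grid, function(g) g[1, ], numeric(3))),
    t(vapply(wall$grid, function(g) g[nrow(g), ], numeric(3))))
  for (i in seq_len(nrow(ring)))
    expect_lt(dist_to_polyline(ring[i, ], dense), 0.5)
})

test_that("simulate_chest_wall accepts presets and commutes with rigid motion", {
  subj <- get_subject("s1", small_params(1))
  wall <- simulate_chest_wall(subj$torso, subj$landmarks, side = "left",
                              bchl = "bchl050", K = 12, M = 12)
  expect_equal(wall$bchl, 0.50)
  bb <- apply(subj$torso$vertices, 2, range)
  wv <- wall$mesh$vertices
  expect_true(all(wv[, 1] >= bb[1, 1] - 1 & wv[, 1] <= bb[2, 1] + 1))
  expect_true(all(wv[, 2] >= bb[1, 2] - 1 & wv[, 2] <= bb[2, 2] + 1))
  set.seed(13)
  rt <- random_rigid()
  wall2 <- simulate_chest_wall(transform_mesh(subj$torso, rt$R, rt$t),
                               apply_rigid_landmarks(subj$landmarks,
                                                     rt$R, rt$t),
                               side = "left", bchl = "bchl050",
                               K = 12, M = 12)
  moved <- breastvol:::transform_points(wall$mesh$vertices, rt$R, rt$t)
  expect_equal(wall2$mesh$vertices, moved, tolerance = 1e-6)
  expect_error(simulate_chest_wall(subj$torso, subj$landmarks,
                                   side = "left", bchl = 1.5),
               "\\[0, 1\\]")
})
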