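# Distance maps, the volume-error statistic, landmark deviations, t-tests.

test_that("distance map of a surface against itself is zero", {
  bump <- sheet_mesh(c(-40, 40), c(-40, 40), n = 15,
                     fz = function(x, y) 10 * exp(-(x^2 + y^2) / 800))
  dm <- signed_distance_map(bump, bump)
  expect_true(all(abs(dm$distance) < 1e-9))
  expect_equal(volume_error(dm), 0, tolerance = 1e-9)
})

test_that("a plane shifted 1 mm anterior maps to +1 mm everywhere", {
  truth <- sheet_mesh(c(-60, 60), c(-60, 60), n = 20)
  sim <- sheet_mesh(c(-40, 40), c(-40, 40), n = 12,
                    fz = function(x, y) 0 * x + 1)
  dm <- signed_distance_map(sim, truth)
  expect_equal(dm$distance, rep(1, nrow(dm)), tolerance = 1e-9)
  # posterior shift flips the sign
  sim2 <- sheet_mesh(c(-40, 40), c(-40, 40), n = 12,
                     fz = function(x, y) 0 * x - 1)
  dm2 <- signed_distance_map(sim2, truth)
  expect_equal(dm2$distance, rep(-1, nrow(dm2)), tolerance = 1e-9)
})

test_that("accelerated nearest-point search matches the exhaustive oracle", {
  set.seed(31)
  truth <- sheet_mesh(c(-50, 50), c(-50, 50), n = 14,
                      fz = function(x, y)
                        6 * sin(x / 11) * cos(y / 13))
  sim <- sheet_mesh(c(-35, 35), c(-35, 35), n = 9,
                    fz = function(x, y)
                      4 + 3 * cos(x / 9) * sin(y / 8))
  dm_fast <- signed_distance_map(sim, truth)
  dm_slow <- signed_distance_map(sim, truth, exhaustive = TRUE)
  expect_equal(dm_fast$distance, dm_slow$distance, tolerance = 1e-6)
  # and the point query itself
  for (i in 1:20) {
    p <- runif(3, -30, 30)
    a <- nearest_point_on_mesh(p, truth)
    b <- nearest_point_on_mesh(p, truth, exhaustive = TRUE)
    expect_equal(a$distance, b$distance, tolerance = 1e-9)
  }
})

test_that("faces outside the truth footprint are flagged and excluded", {
  truth <- sheet_mesh(c(-20, 20), c(-20, 20), n = 8)
  sim <- sheet_mesh(c(-60, 60), c(-60, 60), n = 12,
                    fz = function(x, y) 0 * x + 2)
  expect_warning(dm <- signed_distance_map(sim, truth), "coverage")
  expect_gt(sum(dm$flagged), 0)
  expect_equal(volume_error(dm, weighted = FALSE),
               attr(dm, "sim_area_cm2") * 2 / 10, tolerance = 1e-6)
})

test_that("swapping simulated and true surfaces flips the mean sign", {
  truth <- sheet_mesh(c(-60, 60), c(-60, 60), n = 20)
  sim <- sheet_mesh(c(-40, 40), c(-40, 40), n = 12,
                    fz = function(x, y) 0 * x + 1.5)
  m1 <- mean(signed_distance_map(sim, truth)$distance)
  dm_rev <- suppressWarnings(signed_distance_map(truth, sim))
  m2 <- mean(dm_rev$distance[!dm_rev$flagged])
  expect_gt(m1, 0)
  expect_lt(m2, 0)
})

test_that("volume error formula reproduces the worked numbers", {
  expect_equal(volume_error_ml(285, 1.80), 51.3)
  expect_equal(signif(volume_error_ml(285, 3.77), 3), 107)
  expect_equal(volume_error_ml(0, 5), 0)
})

test_that("area-weighted volume error equals the per-face integral", {
  subj <- get_subject("s1", small_params(1))
  wall <- simulate_chest_wall(subj$torso, subj$landmarks, side = "left",
                              bchl = 0.33, K = 16, M = 16)
  dm <- signed_distance_map(wall, subj$true_wall$left)
  ok <- !dm$flagged
  integral_ml <- sum(dm$distance[ok] * dm$area[ok]) / 1000
  # identical up to the flagged-face area bookkeeping
  expect_equal(volume_error(dm),
               integral_ml * attr(dm, "sim_area_cm2") * 100 /
                 sum(dm$area[ok]),
               tolerance = 1e-9)
})

test_that("landmark deviations follow the axis-restriction rules", {
  fr <- breastvol:::identity_frame()
  expect_equal(landmark_deviation(c(1, 2, 3), c(1, 2, 3),
                                  "superolateral_L", fr)$deviation, 0)
  # pure superior shift of a midaxillary pair does not count
  expect_equal(landmark_deviation(c(0, 0, 0), c(0, 25, 0),
                                  "midaxillary_L", fr)$deviation, 0)
  expect_equal(landmark_deviation(c(0, 0, 0), c(0, 0, 4),
                                  "midaxillary_R", fr)$deviation, 4)
  # sternomanubrial counts only superior-inferior
  expect_equal(landmark_deviation(c(0, 0, 0), c(7, 3, 9),
                                  "sternomanubrial", fr)$deviation, 3)
  # superolateral: full 3D Euclidean distance (3-4-5)
  expect_equal(landmark_deviation(c(0, 0, 0), c(3, 4, 0),
                                  "superolateral_R", fr)$deviation, 5)
  expect_error(landmark_deviation(c(0, 0, 0), c(1, 1, 1), "nipple", fr),
               "unknown landmark")
  df <- landmark_set_deviation(
    landmark_set(c(0, 0, 80), c(-90, -20, 40), c(90, -20, 40),
                 c(-140, 0, 0), c(140, 0, 0)),
    landmark_set(c(0, 2, 80), c(-90, -20, 40), c(87, -16, 40),
                 c(-140, 25, 0), c(140, 0, 3)),
    fr)
  expect_equal(df$deviation_mm,
               c(2, 0, 5, 0, 3), tolerance = 1e-12)
})

test_that("paired t-test matches hand-computed values and edge rules", {
  r <- paired_t_test(c(2, 4, 6), c(1, 2, 3))  # differences 1, 2, 3
  expect_equal(r$statistic, 2 / (1 / sqrt(3)), tolerance = 1e-9)
  expect_equal(r$df, 2)
  expect_equal(r$p.value, 2 * (1 - pt(2 * sqrt(3), 2)), tolerance = 1e-9)
  expect_equal(round(r$statistic, 3), 3.464)
  expect_equal(round(r$p.value, 4), 0.0742)
  same <- paired_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  expect_error(paired_t_test(1, 1), "n >= 2")
  expect_error(paired_t_test(c(1, 2, 3), c(0, 1, 2)), "zero-variance")
  expect_error(paired_t_test(c(1, 2), c(1, 2, 3)), "equal length")
})

test_that("one-sample t-test matches the closed form", {
  r <- one_sample_t_test(1:5)
  expect_equal(r$statistic, 3 / (sqrt(2.5) / sqrt(5)), tolerance = 1e-9)
  expect_equal(r$df, 4)
  expect_equal(round(r$statistic, 3), 4.243)
  expect_equal(round(r$p.value, 4), 0.0132)
  sym <- one_sample_t_test(c(-3, 3))
  expect_equal(sym$statistic, 0)
  expect_equal(sym$p.value, 1)
  expect_error(one_sample_t_test(rep(2, 5)), "constant")
  expect_error(one_sample_t_test(7), "n >= 2")
})

test_that("paired t on (x, x + c) equals one-sample t of the differences", {
  set.seed(41)
  x <- rnorm(8)
  shift <- x + 1.5 + rnorm(8, sd = 0.3)
  a <- paired_t_test(x, shift)
  b <- one_sample_t_test(x - shift)
  expect_equal(a$statistic, b$statistic, tolerance = 1e-12)
  expect_equal(a$p.value, b$p.value, tolerance = 1e-12)
  expect_gte(a$p.value, 0)
  expect_lte(a$p.value, 1)
})

test_that("distance map exports JSON and a color OBJ", {
  subj <- get_subject("s1", small_params(1))
  wall <- simulate_chest_wall(subj$torso, subj$landmarks, side = "left",
                              bchl = 0.33, K = 10, M = 10)
  dm <- signed_distance_map(wall, subj$true_wall$left)
  jp <- withr::local_tempfile(fileext = ".json")
  op <- withr::local_tempfile(fileext = ".obj")
  export_distance_map(dm, wall, jp, op)
  parsed <- jsonlite::read_json(jp, simplifyVector = TRUE)
  expect_equal(length(parsed$distance_mm), nrow(dm))
  expect_true(any(grepl("^v .* [0-9.]+ [0-9.]+ [0-9.]+$", readLines(op))))
})
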