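test_that("acquisition speed planning reproduces the worked examples", {
  expect_equal(speed_factor(60, 45), tan(60 * pi / 180))
  expect_equal(round(speed_factor(60, 45), 2), 1.73)
  expect_equal(speed_factor(45, 45), 1)
  expect_equal(speed_factor(30, 60), 1 / 3)
  expect_error(speed_factor(0, 45), "\\(0, 90\\)")
  expect_error(speed_factor(45, 95), "\\(0, 90\\)")

  expect_equal(round(rescaled_angle(60, 1.3), 2), 53.11)
  expect_equal(rescaled_angle(37.3, 1), 37.3)
  expect_equal(rescaled_angle(60, 1.732), 45, tolerance = 1e-3)
  expect_error(rescaled_angle(60, 0), "positive")
})

test_that("speed factor and angle rescaling are mutually consistent", {
  for (th in c(10, 30, 45, 60, 80)) {
    for (th_new in c(20, 45, 70)) {
      k <- speed_factor(th, th_new)
      expect_equal(rescaled_angle(th, k), th_new, tolerance = 1e-9)
    }
    # accelerating by tan(theta) always lands on the preferred 45 degrees
    expect_equal(rescaled_angle(th, tan(th * pi / 180)), 45, tolerance = 1e-9)
  }
})

test_that("the speed factor follows from resolution changes", {
  expect_equal(k_from_resolutions(0.5, 0.5, 1, 1), 1)
  expect_equal(k_from_resolutions(0.23, 0.47, 1.37, 0.9),
               (0.47 / 0.23) * (1.37 / 0.9))
  expect_equal(k_from_resolutions(1, 1, 2, 1), 2)  # halving dt doubles speed
  expect_error(k_from_resolutions(0, 1, 1, 1), "positive")
})

test_that("streak extents follow the raster geometry", {
  expect_equal(streak_extents(45, 300, 100), c(ws = 100L, hs = 100L))
  expect_equal(streak_extents(45, 100, 100), c(ws = 100L, hs = 100L))
  expect_equal(streak_extents(30, 300, 100),
               c(ws = as.integer(ceiling(100 * tan(30 * pi / 180))), hs = 100L))
  expect_equal(streak_extents(30, 300, 100)[["ws"]], 58L)
  # degenerate conventions
  expect_equal(streak_extents(0, 40, 60), c(ws = 1L, hs = 60L))
  expect_equal(streak_extents(90, 40, 60), c(ws = 40L, hs = 1L))
  # negative angles by symmetry
  expect_equal(streak_extents(-30, 300, 100), streak_extents(30, 300, 100))
})

test_that("single-streak precision matches the one-pixel-offset geometry", {
  expect_equal(single_streak_precision(100, 100),
               (atan(100 / 99) - atan(1)) * 180 / pi)
  expect_equal(single_streak_precision(100, 100), 0.288, tolerance = 1e-2)
  expect_equal(single_streak_precision(1, 2), (atan(1) - atan(0.5)) * 180 / pi)
  expect_equal(single_streak_precision(1, 2), 18.43, tolerance = 1e-3)
  # branch symmetry: mirrored geometry gives the same precision
  expect_equal(single_streak_precision(40, 120), single_streak_precision(120, 40))
  expect_error(single_streak_precision(1, 1), "hs must be")
})

test_that("streak packing count picks the right branch", {
  # full-height streaks: limited by the spatial extent
  expect_identical(max_streak_count(300, 100, dx = 1.19, dt = 1,
                                    ws = 58, hs = 100, ds = 4), 89L)
  expect_identical(max_streak_count(100, 50, dx = 1, dt = 1,
                                    ws = 20, hs = 50, ds = 100), 1L)
  # full-width streaks: limited by the temporal extent
  expect_identical(max_streak_count(100, 100, dx = 1, dt = 1,
                                    ws = 100, hs = 60, dt_streak = 0.01), 10L)
  expect_warning(
    ns <- max_streak_count(10, 50, dx = 1, dt = 1, ws = 3, hs = 50, ds = 100),
    "too small")
  expect_identical(ns, 1L)
  expect_error(max_streak_count(100, 100, dx = 1, dt = 1, ws = 50, hs = 50),
               "inconsistent")
})

test_that("theoretical precision scales inversely with streak count", {
  expect_equal(finest_detectable_angle(0.288, 89), 0.288 / 89)
  expect_equal(finest_detectable_angle(0.5, 1), 0.5)
  expect_equal(finest_detectable_angle(0.5, 10), 2 * finest_detectable_angle(0.5, 20))
})

test_that("fractional velocity change reproduces the printed sensitivities", {
  # a 0.1-degree error at 45 degrees is ~0.35% in velocity
  expect_equal(dv_from_angle_change(45, 45.1), 0.0035, tolerance = 2e-2)
  # a 0.6-degree disagreement at ~83 degrees is ~8% in velocity
  expect_equal(abs(dv_from_angle_change(83, 82.4)), 0.080, tolerance = 2e-2)
  expect_equal(dv_from_angle_change(37, 37), 0)
  expect_error(dv_from_angle_change(0, 10), "nonzero")
  expect_error(dv_from_angle_change(45, 90), "\\(-90, 90\\)")
})

test_that("angle step for a target velocity change inverts the sensitivity", {
  expect_equal(angle_change_for_dv(45, 0.0035), 0.1, tolerance = 2e-2)
  expect_equal(angle_change_for_dv(30, 0), 0)
  expect_error(angle_change_for_dv(45, -1), "> -1")
  # mutual inverses over the domain
  for (th in c(10, 30, 45, 60, 80)) {
    for (dv in c(-0.5, -0.01, 0.001, 0.25, 0.8)) {
      d <- angle_change_for_dv(th, dv)
      th1 <- th + sign(dv) * d
      expect_equal(dv_from_angle_change(th, th1), dv, tolerance = 1e-9)
    }
  }
})

test_that("the tolerable angle step is maximal at 45 degrees", {
  dv <- 0.1
  grid <- c(10, 20, 30, 40, 45, 50, 60, 70, 80)
  deltas <- vapply(grid, angle_change_for_dv, numeric(1), dv = dv)
  expect_equal(grid[which.max(deltas)], 45)
})

test_that("precision reports keep delta_n below delta_s1", {
  for (th in c(5, 20, 45, 70, 85)) {
    for (geom in list(c(300, 100), c(100, 100), c(64, 512))) {
      rep <- precision_report(th, geom[1], geom[2], dx = 1.19, dt = 1)
      expect_lte(rep$delta_n, rep$delta_s1)
      expect_equal(rep$delta_n, rep$delta_s1 / rep$ns)
      expect_gte(rep$ns, 1L)
      expect_true(rep$ws >= 1 && rep$ws <= geom[1])
      expect_true(rep$hs >= 1 && rep$hs <= geom[2])
    }
  }
})
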