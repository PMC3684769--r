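test_that("generation is deterministic for a fixed spec and seed", {
  spec <- synthetic_spec(theta = 33, noise_sd = 0.1, seed = 99)
  a <- generate_streak_image(spec)
  b <- generate_streak_image(spec)
  expect_identical(a$pixels, b$pixels)
  c <- generate_streak_image(synthetic_spec(theta = 33, noise_sd = 0.1, seed = 100))
  expect_false(identical(a$pixels, c$pixels))
})

test_that("generated streaks carry their ground-truth angle", {
  # 216 lines so even near-vertical streaks sweep several pixels of space
  for (th in c(-75, -40, -2, 2, 10, 45, 88)) {
    img <- stripes(th, width = 72, height = 216)
    est <- fine_grid_argmax(sobel_filter_time(img), resolution = 0.01)
    expect_lt(abs(est - th), 0.05)
  }
})

test_that("vertical streaks (stagnant flow) are suppressed by vertical operators", {
  img <- stripes(0, width = 48, height = 48)
  expect_lt(max(abs(vertical_demean(img)$pixels)), 1e-9)
  expect_lt(max(abs(sobel_filter_time(img)$pixels)), 1e-9)
})

test_that("streak counts match the packing prediction", {
  for (th in c(5, 20, 35)) {
    spec <- synthetic_spec(theta = th, width = 120, height = 200,
                           streak_width = 4, streak_spacing = 12)
    img <- generate_streak_image(spec)
    # count full band cores along one scan line (edge slivers excluded)
    mid <- img$pixels[100, ]
    dark <- mid < spec$background_level - spec$contrast / 2
    r <- rle(dark)
    wx <- spec$streak_width / cos(th * pi / 180)
    runs <- sum(r$values & r$lengths >= wx - 1)
    # packing prediction with the spacing measured along the space axis
    ds_um <- spec$streak_spacing / cos(th * pi / 180) * spec$dx
    ns <- max_streak_count(spec$width, spec$height, spec$dx, spec$dt,
                           ws = 1, hs = spec$height, ds = ds_um)
    expect_lte(abs(runs - ns), 1)
  }
})

test_that("impossible streak geometries are rejected", {
  expect_error(generate_streak_image(synthetic_spec(theta = 0, width = 5,
                                                    height = 200)),
               "zero streaks")
  expect_error(synthetic_spec(streak_width = 6, streak_spacing = 6))
  expect_error(synthetic_spec(theta = 95))
  expect_error(synthetic_spec(contrast = 0))
})

test_that("phase offsets translate the pattern without changing the angle", {
  img0 <- stripes(30, width = 64, height = 64)
  spec <- synthetic_spec(theta = 30, width = 64, height = 64)
  img1 <- generate_streak_image(spec, phase_offset = 3)
  expect_false(identical(img0$pixels, img1$pixels))
  expect_lt(abs(fine_grid_argmax(sobel_filter_time(img1), resolution = 0.05) -
                fine_grid_argmax(sobel_filter_time(img0), resolution = 0.05)),
            0.11)
})

test_that("static vertical bands are annihilated by both vertical filters", {
  img <- stripes(40, width = 60, height = 60)
  banded <- add_static_band(img, c(20, 28), level = 0)
  d <- vertical_demean(banded)$pixels
  expect_lt(max(abs(d[, 20:28])), 1e-9)
  s <- sobel_filter_time(banded)$pixels
  expect_lt(max(abs(s[, 20:26])), 1e-9)  # band interior in cropped coordinates
  expect_error(add_static_band(img, c(55, 65), 0), "outside")
})

test_that("motion artifacts are slow horizontal bands that Sobel suppresses", {
  flat <- spacetime_image(matrix(1, 400, 60), 1, 1)
  art <- add_motion_artifact(flat, period_lines = 120, amplitude_level = 0.5,
                             duty = 0.5, seed = 4)
  # reproducible, and a no-op at zero amplitude
  art2 <- add_motion_artifact(flat, period_lines = 120, amplitude_level = 0.5,
                              duty = 0.5, seed = 4)
  expect_identical(art$pixels, art2$pixels)
  expect_identical(add_motion_artifact(flat, 120, 0)$pixels, flat$pixels)
  # bands survive vertical demeaning but not Sobel filtering
  vd <- vertical_demean(art)$pixels
  sb <- sobel_filter_time(art)$pixels
  expect_gt(sd(rowMeans(vd)), 0.05)              # rows still modulated
  expect_lt(max(abs(sb)), 0.15 * 0.5 * 8)        # slow slope, tiny response
  expect_error(add_motion_artifact(flat, 1, 0.5), "period_lines")
  expect_error(add_motion_artifact(flat, 100, 0.5, duty = 1.5), "duty")
})

test_that("multi-epoch sequences concatenate with continuous streak phase", {
  s30 <- synthetic_spec(theta = 30, width = 80, height = 100)
  s50 <- synthetic_spec(theta = 50, width = 80, height = 100)
  seq_img <- generate_sequence(list(s30, s50), n_lines = c(150, 150))
  expect_equal(dim(seq_img$pixels), c(300L, 80L))
  # one epoch reproduces the plain generator
  one <- generate_sequence(list(s30), n_lines = 100)
  expect_identical(one$pixels, generate_streak_image(s30)$pixels)
  # streak positions continue across the boundary: dark pixels of the last
  # line of epoch 1 and first line of epoch 2 nearly coincide
  r1 <- which(seq_img$pixels[150, ] < 1 - 0.3)
  r2 <- which(seq_img$pixels[151, ] < 1 - 0.3)
  expect_gt(length(intersect(r1, r2)) / length(union(r1, r2)), 0.5)
  expect_error(generate_sequence(list(), integer(0)), "at least one")
  s_wide <- synthetic_spec(theta = 50, width = 90, height = 100)
  expect_error(generate_sequence(list(s30, s_wide), c(100, 100)), "share")
})
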