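# Shared fixtures and independent oracles, built in code at test time.

# Clean stripe image shorthand.
stripes <- function(theta, width = 64, height = 64, streak_width = 4,
                    streak_spacing = 12, noise_sd = 0, seed = 1, ...) {
  generate_streak_image(synthetic_spec(
    theta = theta, width = width, height = height,
    streak_width = streak_width, streak_spacing = streak_spacing,
    noise_sd = noise_sd, seed = seed, ...
  ))
}

# Independent brute-force Radon oracle: explicit rotation of pixel-center
# coordinates and nearest-bin accumulation.  Shares no code with the
# package's interpolating line-sum engine.
brute_projection <- function(px, theta_deg, trim = TRUE, normalize = FALSE) {
  if (inherits(px, "spacetime_image")) px <- px$pixels
  h <- nrow(px); w <- ncol(px)
  th <- theta_deg * pi / 180
  cx <- (w + 1) / 2; cy <- (h + 1) / 2
  x <- rep(seq_len(w), each = h) - cx
  t <- rep(seq_len(h), times = w) - cy
  p <- x * cos(th) - t * sin(th)     # perpendicular offset of each pixel
  R <- ceiling(sqrt(w^2 + h^2) / 2) + 1
  bin <- round(p) + R + 1
  proj <- numeric(2 * R + 1)
  hits <- integer(2 * R + 1)
  vals <- as.vector(px)
  for (i in seq_along(bin)) {
    proj[bin[i]] <- proj[bin[i]] + vals[i]
    hits[bin[i]] <- hits[bin[i]] + 1L
  }
  names(proj) <- as.character(seq_along(proj) - 1 - R)
  if (normalize) proj <- proj / pmax(hits, 1L)
  if (trim) proj <- proj[hits > max(hits) / 2]
  proj
}

brute_variance_profile <- function(px, angles) {
  vapply(angles, function(a)
    stats::var(brute_projection(px, a, normalize = TRUE)), numeric(1))
}

# Exhaustive coarse-then-fine grid argmax of the projection variance, used
# as the reference the iterative search is compared against.
fine_grid_argmax <- function(image, resolution = 0.02, halfwidth = 1.5,
                             coarse = seq(-89.5, 89.5, by = 1)) {
  vp <- variance_profile(image, coarse)
  c0 <- vp$angles[vp$best_index]
  fine <- seq(c0 - halfwidth, c0 + halfwidth, by = resolution)
  vp2 <- variance_profile(image, fine)
  vp2$angles[vp2$best_index]
}

# Minimal hand-built velocity trace for unit tests of flagging/smoothing.
make_trace <- function(angles, dx = 1, dt = 1, step = 100, window = 100,
                       valid = rep(TRUE, length(angles))) {
  n <- length(angles)
  v <- ifelse(abs(angles) < 90, (dx / dt) * tan(angles * pi / 180), NA_real_)
  samples <- data.frame(
    segment_index = seq_len(n) - 1L,
    start_line = (seq_len(n) - 1L) * step,
    end_line = (seq_len(n) - 1L) * step + window,
    t_center_ms = ((seq_len(n) - 1L) * step + window / 2) * dt,
    angle_deg = angles, velocity_mm_s = v,
    peak_variance = 1, n_transforms = 28L, achieved_delta_deg = 0.703125,
    valid = valid
  )
  kymoradon:::velocity_trace(samples, window, step, dx, dt)
}
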