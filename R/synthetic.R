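#' Specification for a synthetic streak image
#'
#' Describes a ground-truth space-time image: dark RBC streaks (bands) at a
#' known angle on a bright plasma background, with trapezoidal band profiles
#' (1-pixel anti-aliased edges, matching the sharp one-to-two-pixel streak
#' edges of two-photon line-scans), optional additive Gaussian noise, and
#' acquisition metadata.  Used as ground truth throughout the test-suite and
#' for demos.
#'
#' @param theta True streak angle, degrees from the time axis, in (-90, 90).
#' @param width,height Image size in pixels (columns = space, rows = time).
#' @param streak_width Band width, pixels, measured perpendicular to the
#'   streak (>= 1).
#' @param streak_spacing Perpendicular center-to-center band separation,
#'   pixels (> `streak_width`).
#' @param contrast Luminance drop of a streak below the background (> 0).
#' @param background_level Background (plasma) luminance.
#' @param noise_sd Standard deviation of additive Gaussian noise (>= 0).
#' @param seed Integer seed for the noise generator.
#' @param dx Spatial resolution, um/pixel.
#' @param dt Line period, ms/line.
#' @param invert If `TRUE`, bright streaks on a dark background
#'   (RBC-labelled rather than plasma-labelled preparations).
#' @return An object of class `synthetic_spec` (a validated list).
#' @examples
#' spec <- synthetic_spec(theta = 45, noise_sd = 0.05, seed = 7)
#' img <- generate_streak_image(spec)
#' @export
synthetic_spec <- function(theta = 45, width = 112, height = 215,
                           streak_width = 4, streak_spacing = 12,
                           contrast = 0.6, background_level = 1,
                           noise_sd = 0, seed = 1L, dx = 1, dt = 1,
                           invert = FALSE) {
  stopifnot(is.numeric(theta), length(theta) == 1L, abs(theta) < 90,
            width >= 3, height >= 3,
            streak_width >= 1, streak_spacing > streak_width,
            contrast > 0, noise_sd >= 0, dx > 0, dt > 0)
  structure(list(theta = theta, width = as.integer(width),
                 height = as.integer(height),
                 streak_width = streak_width,
                 streak_spacing = streak_spacing,
                 contrast = contrast, background_level = background_level,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 dx = dx, dt = dt, invert = isTRUE(invert)),
            class = "synthetic_spec")
}

# Band field for global row indices t (0-based) and 0-based columns of a
# w-wide image.  The streak family is x = phase + t * tan(theta) (mod
# period_x, measured along the space axis); width_perp is the band width
# measured perpendicular to the streaks, with a 1-pixel (perpendicular)
# anti-aliasing ramp at each edge, so cov = 1 in the band core and 0 in the
# gaps.
streak_field <- function(theta, w, t_global, period_x, width_perp, phase) {
  th <- theta * pi / 180
  x <- matrix(rep(seq_len(w) - 1, each = length(t_global)),
              nrow = length(t_global))
  t <- matrix(rep(t_global, times = w), nrow = length(t_global))
  ux <- (x - phase - t * tan(th)) %% period_x
  wx <- width_perp / cos(th)                  # band width along x
  s <- ifelse(ux <= wx, pmin(ux, wx - ux), -pmin(ux - wx, period_x - ux)) *
    cos(th)                                   # signed perpendicular distance
  pmin(pmax(0.5 + s, 0), 1)
}

#' Generate a synthetic streak image
#'
#' Renders the streak pattern described by a [synthetic_spec()]: dark bands
#' along lines at the true angle, anti-aliased over one pixel at the band
#' edges, optionally shifted spatially by `phase_offset` (used to produce
#' replicate images whose streaks sit at different positions), plus seeded
#' additive Gaussian noise.  Identical spec and seed give bit-identical
#' images.
#'
#' @param spec A [synthetic_spec()].
#' @param phase_offset Spatial shift of the streak pattern, pixels.
#' @return A [spacetime_image()] with the spec's `dx` and `dt`.
#' @export
generate_streak_image <- function(spec, phase_offset = 0) {
  stopifnot(inherits(spec, "synthetic_spec"))
  th <- spec$theta * pi / 180
  period_x <- spec$streak_spacing / cos(th)
  extent_x <- (spec$width - 1) + (spec$height - 1) * abs(tan(th))
  if (extent_x < period_x)
    stop("geometry admits zero streaks: swept extent ", round(extent_x, 2),
         " px < streak period ", round(period_x, 2), " px along the scan line")
  cov <- streak_field(spec$theta, spec$width, seq_len(spec$height) - 1,
                      spec$streak_spacing / cos(th), spec$streak_width,
                      phase_offset)
  sgn <- if (spec$invert) +1 else -1
  px <- spec$background_level + sgn * spec$contrast * cov
  if (spec$noise_sd > 0) {
    px <- px + with_seed(spec$seed,
      matrix(stats::rnorm(length(px), sd = spec$noise_sd), nrow = nrow(px)))
  }
  spacetime_image(px, dx = spec$dx, dt = spec$dt)
}

#' Add a static vertical-band artifact
#'
#' Emulates a line-scan path that leaves the vessel: the affected columns are
#' set to the artifact luminance in every row, producing a strictly
#' time-invariant vertical band.  Both vertical demeaning and Sobel filtering
#' remove this artifact class.
#'
#' @param image A [spacetime_image()].
#' @param column_range Inclusive 1-based column range, `c(first, last)`.
#' @param level Artifact luminance.
#' @return The modified `spacetime_image`.
#' @export
add_static_band <- function(image, column_range, level) {
  validate_image(image)
  stopifnot(length(column_range) == 2L)
  cols <- seq.int(column_range[1], column_range[2])
  if (any(cols < 1) || any(cols > ncol(image$pixels)))
    stop("column_range outside image (1..", ncol(image$pixels), ")")
  image$pixels[, cols] <- level
  image
}

#' Add a time-varying horizontal-band (motion) artifact
#'
#' Emulates heartbeat- or respiration-driven brain motion: whole rows of the
#' image darken smoothly and quasi-periodically.  Pulses are raised-cosine
#' dips of width `duty * period_lines` lines, with seeded jitter of the pulse
#' centers (10 percent of the period), repeating every `period_lines` lines
#' -- at typical line periods of 1-2 ms, a period of a few hundred lines
#' corresponds to the 3-8 Hz cardiac band.  Vertical demeaning cannot remove
#' these bands; vertical Sobel filtering suppresses them because they vary
#' slowly along time.
#'
#' @param image A [spacetime_image()].
#' @param period_lines Pulse period in lines (>= 2).
#' @param amplitude_level Peak darkening in luminance units (>= 0; 0 is a
#'   no-op).
#' @param duty Fraction of the period occupied by each pulse, in (0, 1).
#' @param seed Integer seed for the jitter.
#' @return The modified `spacetime_image`.
#' @export
add_motion_artifact <- function(image, period_lines, amplitude_level,
                                duty = 0.4, seed = 1L) {
  validate_image(image)
  stopifnot(period_lines >= 2, duty > 0, duty < 1, amplitude_level >= 0)
  if (amplitude_level == 0) return(image)
  h <- nrow(image$pixels)
  n_pulse <- ceiling(h / period_lines) + 1L
  centers <- with_seed(seed,
    (seq_len(n_pulse) - 0.5) * period_lines +
      stats::rnorm(n_pulse, sd = 0.1 * period_lines))
  half <- duty * period_lines / 2
  dip <- numeric(h)
  rows <- seq_len(h)
  for (ctr in centers) {
    z <- abs(rows - ctr) / half
    in_pulse <- z < 1
    dip[in_pulse] <- pmax(dip[in_pulse], 0.5 * (1 + cos(pi * z[in_pulse])))
  }
  image$pixels <- image$pixels - amplitude_level * dip
  image
}

#' Concatenate synthetic epochs into one long sequence
#'
#' Builds a long line-scan sequence from successive epochs, each described by
#' its own [synthetic_spec()] and number of lines (so the streak angle, and
#' hence simulated velocity, can change between epochs).  The epochs render
#' one continuous RBC train: the streak spacing measured along the vessel
#' axis is fixed by the first epoch and the spatial phase is advanced across
#' epoch boundaries, so every streak continues smoothly where the angle
#' changes -- as real cells do when the flow speed steps.
#'
#' @param specs List of [synthetic_spec()] objects sharing `width`, `dx`,
#'   `dt`.
#' @param n_lines Integer vector, lines per epoch (same length as `specs`).
#' @return A [spacetime_image()] with `sum(n_lines)` rows.
#' @examples
#' seq_img <- generate_sequence(
#'   list(synthetic_spec(theta = 30), synthetic_spec(theta = 50)),
#'   n_lines = c(500, 500))
#' @export
generate_sequence <- function(specs, n_lines) {
  if (length(specs) == 0L) stop("specs must contain at least one epoch")
  if (length(n_lines) != length(specs))
    stop("n_lines must match specs in length")
  stopifnot(all(n_lines >= 1))
  w <- specs[[1]]$width
  for (s in specs) {
    stopifnot(inherits(s, "synthetic_spec"))
    if (s$width != w || s$dx != specs[[1]]$dx || s$dt != specs[[1]]$dt)
      stop("all epochs must share width, dx and dt")
  }
  phase <- 0
  t0 <- 0
  # one RBC train: the spacing along the vessel axis is set by the first
  # epoch and preserved when the angle (velocity) changes
  period_x <- specs[[1]]$streak_spacing / cos(specs[[1]]$theta * pi / 180)
  blocks <- vector("list", length(specs))
  for (k in seq_along(specs)) {
    s <- specs[[k]]
    cov <- streak_field(s$theta, w, t0 + seq_len(n_lines[k]) - 1,
                        period_x, s$streak_width, phase)
    sgn <- if (s$invert) +1 else -1
    px <- s$background_level + sgn * s$contrast * cov
    if (s$noise_sd > 0) {
      px <- px + with_seed(s$seed + k - 1L,
        matrix(stats::rnorm(length(px), sd = s$noise_sd), nrow = nrow(px)))
    }
    blocks[[k]] <- px
    # continuity: the next epoch's streak family must pass through the same
    # x positions at the boundary line, x = phase + t * tan(theta)
    if (k < length(specs)) {
      t_end <- t0 + n_lines[k]
      phase <- phase + t_end * (tan(s$theta * pi / 180) -
                                  tan(specs[[k + 1]]$theta * pi / 180))
    }
    t0 <- t0 + n_lines[k]
  }
  spacetime_image(do.call(rbind, blocks), dx = specs[[1]]$dx,
                  dt = specs[[1]]$dt)
}
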