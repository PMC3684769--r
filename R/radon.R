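# Reduce angles (degrees) modulo 180 into [-90, 90).  The Radon projection
# variance is 180-degree periodic, so this is lossless.
reduce_angle <- function(theta) {
  ((theta + 90) %% 180) - 90
}

# Full sinogram over a set of angles: ray sums plus per-ray in-image weight
# (effective ray length).  Internal; the C++ kernel does the summation.
radon_sinogram <- function(image, angles, r_step = 1) {
  p <- if (inherits(image, "spacetime_image")) image$pixels else as.matrix(image)
  storage.mode(p) <- "double"
  radon_sinogram_cpp(p, as.numeric(angles), r_step)
}

#' Radon projection of a space-time image at one angle
#'
#' Integrates the image along parallel rays at angle `theta` (degrees from
#' the time/vertical axis) about the image center, one ray per whole-pixel
#' offset `r`.  Rays are sampled at unit steps with bilinear interpolation;
#' samples outside the raster contribute zero.  A streak at angle `theta`
#' integrates coherently, so the projection taken at the streak angle is
#' maximally peaked across offsets.
#'
#' @param image A [spacetime_image()] (typically filtered) or a plain matrix.
#' @param theta Projection angle in degrees; reduced modulo 180 into
#'   \[-90, 90).
#' @param keep_short_rays If `FALSE` (default), drops rays whose length
#'   through the image support is at most half the longest ray; the stubs of
#'   zero-padded corner rays otherwise distort the projection variance at
#'   oblique angles.
#' @return A numeric vector of ray sums, named by their integer offset from
#'   the image center.
#' @export
radon_projection <- function(image, theta, keep_short_rays = FALSE) {
  stopifnot(length(theta) == 1L, is.finite(theta))
  theta <- reduce_angle(theta)
  sg <- radon_sinogram(image, theta, r_step = 1)
  proj <- sg$proj[, 1L]
  wt <- sg$weight[, 1L]
  names(proj) <- as.character(seq_along(proj) - 1L - sg$r_half)
  if (!keep_short_rays) proj <- proj[wt > max(wt) / 2]
  proj
}

#' Projection-variance profile over a set of angles
#'
#' For each requested angle, computes the variance across ray offsets of the
#' Radon projection.  The streak angle of the image is the angle at which
#' this variance is maximal.  Short corner rays (length through the image at
#' most half the longest ray) are excluded from the variance, each remaining
#' bin is normalized by its ray length so that featureless images give flat
#' profiles at every angle, and each projection is mean-centered.  Ties in
#' the argmax are broken in favour of the smallest `|theta|`, then the
#' earlier list position.
#'
#' @param image A [spacetime_image()] (typically Sobel-filtered) or a matrix.
#' @param angles Non-empty numeric vector of angles in degrees; reduced
#'   modulo 180 into \[-90, 90).
#' @return An object of class `variance_profile`: list with `angles`,
#'   `variances` and `best_index`.
#' @examples
#' img <- generate_streak_image(synthetic_spec(theta = 45))
#' vp <- variance_profile(sobel_filter_time(img), seq(-89, 89, by = 1))
#' vp$angles[vp$best_index]
#' @export
variance_profile <- function(image, angles) {
  if (length(angles) == 0L) stop("angle list must be non-empty")
  if (!all(is.finite(angles))) stop("angles must be finite")
  angles <- reduce_angle(as.numeric(angles))
  # offsets are oversampled at half-pixel spacing so the variance peak is
  # not aliased to the bin grid (sub-tenth-degree biases otherwise appear
  # on windows holding only a few streaks)
  sg <- radon_sinogram(image, angles, r_step = 0.5)
  variances <- vapply(seq_along(angles), function(a) {
    wt <- sg$weight[, a]
    keep <- wt > max(wt) / 2
    if (sum(keep) < 2L) return(0)
    v <- sg$proj[keep, a] / wt[keep]
    stats::var(v - mean(v))
  }, numeric(1))
  best_index <- order(-variances, abs(angles), seq_along(angles))[1L]
  structure(list(angles = angles, variances = variances,
                 best_index = best_index),
            class = "variance_profile")
}

#' @export
print.variance_profile <- function(x, ...) {
  cat(sprintf("<variance_profile> %d angles, peak %.6g at %.4f deg\n",
              length(x$angles), x$variances[x$best_index],
              x$angles[x$best_index]))
  invisible(x)
}

#' Variance-maximizing projection angle
#'
#' Evaluates [variance_profile()] over the given angles and returns the
#' argmax as an angle estimate.
#'
#' @inheritParams variance_profile
#' @return An object of class `angle_estimate`: list with `theta` (degrees),
#'   `peak_variance`, and a `valid` flag (`FALSE` when the image is
#'   structureless and every projection variance is essentially zero).
#' @export
best_angle <- function(image, angles) {
  vp <- variance_profile(image, angles)
  theta <- vp$angles[vp$best_index]
  pv <- vp$variances[vp$best_index]
  angle_estimate(theta, pv, valid = pv > degenerate_variance(image))
}

angle_estimate <- function(theta, peak_variance, valid = TRUE) {
  structure(list(theta = theta, peak_variance = peak_variance, valid = valid),
            class = "angle_estimate")
}

#' @export
print.angle_estimate <- function(x, ...) {
  cat(sprintf("<angle_estimate> theta = %.4f deg, peak variance = %.6g%s\n",
              x$theta, x$peak_variance, if (x$valid) "" else " [invalid]"))
  invisible(x)
}

# Variance level below which an image is considered structureless for the
# angle search: tied to the pixel variance so the test is invariant to
# affine luminance rescaling, with an absolute floor for all-constant input.
degenerate_variance <- function(image) {
  p <- if (inherits(image, "spacetime_image")) image$pixels else image
  max(1e-12, 1e-9 * stats::var(as.vector(p)))
}
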