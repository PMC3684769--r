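#' Space-time (line-scan) image
#'
#' A space-time image (kymograph) stacks successive line-scans of a vessel as
#' rows: row index is time (increasing downward), column index is position
#' along the scanned line.  A red blood cell moving along the vessel traces a
#' diagonal streak whose angle theta from the time (vertical) axis encodes its
#' velocity, `v = (dx/dt) * tan(theta)`.
#'
#' @param pixels Numeric matrix of luminance values, rows = time, columns =
#'   space.  At least 3 rows and 3 columns, all values finite.
#' @param dx Spatial resolution in micrometers per pixel (must be > 0).
#' @param dt Line period in milliseconds per line (must be > 0).
#' @param filter Provenance tag: which pre-processing filter produced the
#'   pixel values (`"none"` for raw data).
#'
#' @return An object of class `spacetime_image`: a list with elements
#'   `pixels`, `dx`, `dt` and `filter`.
#' @examples
#' img <- spacetime_image(matrix(runif(50 * 40), 50, 40), dx = 0.5, dt = 1)
#' dim(img$pixels)
#' @export
spacetime_image <- function(pixels, dx, dt, filter = "none") {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  img <- structure(
    list(pixels = pixels, dx = dx, dt = dt, filter = filter),
    class = "spacetime_image"
  )
  validate_image(img)
}

#' Validate a space-time image
#'
#' Checks the class invariants: a numeric matrix with at least 3 rows and 3
#' columns, all values finite, and strictly positive acquisition metadata.
#'
#' @param image A [spacetime_image()].
#' @return The image, invisibly unchanged, if all invariants hold.
#' @export
validate_image <- function(image) {
  if (!inherits(image, "spacetime_image"))
    stop("not a spacetime_image object")
  p <- image$pixels
  if (!is.matrix(p) || !is.numeric(p))
    stop("pixels must be a numeric matrix")
  if (nrow(p) < 3L)
    stop("image must have at least 3 rows (time samples); got ", nrow(p))
  if (ncol(p) < 3L)
    stop("image must have at least 3 columns (spatial samples); got ", ncol(p))
  if (!all(is.finite(p)))
    stop("image contains non-finite pixel values")
  if (!is.numeric(image$dx) || length(image$dx) != 1L || !is.finite(image$dx) ||
      image$dx <= 0)
    stop("dx (um/pixel) must be a single positive number")
  if (!is.numeric(image$dt) || length(image$dt) != 1L || !is.finite(image$dt) ||
      image$dt <= 0)
    stop("dt (ms/line) must be a single positive number")
  image
}

#' @export
print.spacetime_image <- function(x, ...) {
  cat(sprintf(
    "<spacetime_image> %d lines x %d pixels, dx = %g um/px, dt = %g ms/line, filter = %s\n",
    nrow(x$pixels), ncol(x$pixels), x$dx, x$dt, x$filter
  ))
  invisible(x)
}

#' @export
dim.spacetime_image <- function(x) dim(x$pixels)

#' Convert a streak angle to blood velocity
#'
#' The streak angle theta, measured in degrees from the time (vertical) axis,
#' maps to a signed velocity `v = (dx/dt) * tan(theta)`.  With dx in um/pixel
#' and dt in ms/line the result is in um/ms, which equals mm/s.  theta = 0
#' corresponds to stagnant flow (vertical streaks); |theta| approaching 90
#' corresponds to unmeasurably fast, near-horizontal streaks.
#'
#' @param theta Streak angle in degrees, strictly inside (-90, 90).
#' @param dx Spatial resolution, um/pixel (> 0).
#' @param dt Line period, ms/line (> 0).
#' @return Signed velocity in mm/s.
#' @examples
#' velocity_from_angle(59.5, dx = 0.23, dt = 1.37)  # about 0.29 mm/s
#' @seealso [angle_from_velocity()]
#' @export
velocity_from_angle <- function(theta, dx, dt) {
  stopifnot(is.numeric(theta), is.numeric(dx), is.numeric(dt))
  if (any(dx <= 0) || any(dt <= 0))
    stop("dx and dt must be positive")
  if (any(abs(theta) >= 90))
    stop("|theta| must be < 90 degrees: horizontal streaks are unmeasurably fast")
  (dx / dt) * tan(theta * pi / 180)
}

#' Convert a blood velocity to the streak angle it produces
#'
#' Inverse of [velocity_from_angle()]: `theta = atan(v * dt / dx)` in degrees.
#' Useful for predicting the streak angle a vessel will produce under given
#' acquisition settings.
#'
#' @param v Velocity in mm/s (signed).
#' @inheritParams velocity_from_angle
#' @return Streak angle in degrees, in (-90, 90).
#' @examples
#' angle_from_velocity(0.285, dx = 0.23, dt = 1.37)  # 59.5 degrees
#' @export
angle_from_velocity <- function(v, dx, dt) {
  stopifnot(is.numeric(v), is.numeric(dx), is.numeric(dt))
  if (any(dx <= 0) || any(dt <= 0))
    stop("dx and dt must be positive")
  atan(v * dt / dx) * 180 / pi
}
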