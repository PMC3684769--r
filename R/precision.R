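deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Acquisition speed-up factor to move between streak angles
#'
#' How much faster (k > 1) or slower (k < 1) the line-scan acquisition must
#' run so that a vessel currently producing streaks at `theta` produces them
#' at `theta_new`: `k = tan(theta) / tan(theta_new)`.  To land on the
#' preferred 45-degree angle, `k = tan(theta)`.
#'
#' @param theta Current streak angle, degrees, in (0, 90).
#' @param theta_new Desired streak angle, degrees, in (0, 90).
#' @return Numeric speed factor k.
#' @examples
#' speed_factor(60, 45)  # 1.73: image 73 percent faster
#' @export
speed_factor <- function(theta, theta_new) {
  check_open_angle(theta, "theta")
  check_open_angle(theta_new, "theta_new")
  tan(deg2rad(theta)) / tan(deg2rad(theta_new))
}

#' Streak angle after rescaling the acquisition speed
#'
#' If acquisition becomes `k` times faster (combined over spatial resolution
#' and line period), a streak currently at `theta` appears at
#' `arctan(tan(theta) / k)`.
#'
#' @param theta Current streak angle, degrees, in (-90, 90).
#' @param k Speed factor (> 0); see [k_from_resolutions()].
#' @return New streak angle in degrees.
#' @examples
#' rescaled_angle(60, 1.3)  # 53.11 degrees
#' @export
rescaled_angle <- function(theta, k) {
  stopifnot(is.numeric(theta), is.numeric(k))
  if (any(abs(theta) >= 90)) stop("theta must be inside (-90, 90) degrees")
  if (any(k <= 0)) stop("k must be positive")
  rad2deg(atan(tan(deg2rad(theta)) / k))
}

#' Speed factor implied by two acquisition settings
#'
#' `k = (dx_new / dx) * (dt / dt_new)`: coarser spatial sampling and shorter
#' line periods both speed up the effective acquisition.
#'
#' @param dx,dx_new Old and new spatial resolution, um/pixel.
#' @param dt,dt_new Old and new line period, ms/line.
#' @return Numeric speed factor k.
#' @export
k_from_resolutions <- function(dx, dx_new, dt, dt_new) {
  vals <- c(dx, dx_new, dt, dt_new)
  if (!all(is.finite(vals)) || any(vals <= 0))
    stop("all resolutions must be positive")
  (dx_new / dx) * (dt / dt_new)
}

#' Pixel extents of a single streak
#'
#' A streak at angle `theta0` in a `w` x `h` image spans
#' `ws = min(w, ceiling(h * tan(theta0)))` pixels in space and
#' `hs = min(h, ceiling(w * cot(theta0)))` pixels in time.  Degenerate
#' angles use the convention `(1, h)` at 0 degrees (vertical streak) and
#' `(w, 1)` at 90 degrees (horizontal streak).  Negative angles are handled
#' by symmetry on `|theta0|`.
#'
#' @param theta0 Streak angle, degrees, with `|theta0|` in \[0, 90\].
#' @param w,h Image width (space) and height (time) in pixels.
#' @return Integer vector `c(ws, hs)`.
#' @export
streak_extents <- function(theta0, w, h) {
  stopifnot(is.numeric(theta0), length(theta0) == 1L,
            w >= 1, h >= 1, w == round(w), h == round(h))
  a <- abs(theta0)
  if (a > 90) stop("|theta0| must be <= 90 degrees")
  if (a == 0) return(c(ws = 1L, hs = as.integer(h)))
  if (a == 90) return(c(ws = as.integer(w), hs = 1L))
  t <- tan(deg2rad(a))
  c(ws = as.integer(min(w, ceiling(h * t))),
    hs = as.integer(min(h, ceiling(w / t))))
}

#' Finest angle change detectable from a single streak
#'
#' Offsetting the end of a streak by one pixel along its longer dimension is
#' the smallest displacement the raster can represent, so the corresponding
#' angle change bounds the single-streak precision:
#' `arctan(ws / (hs - 1)) - arctan(ws / hs)` when `ws <= hs` (relatively
#' vertical streaks), and `arctan(ws / hs) - arctan((ws - 1) / hs)`
#' otherwise.
#'
#' @param ws,hs Streak extents in pixels, from [streak_extents()].
#' @return Angle change in degrees.
#' @examples
#' single_streak_precision(100, 100)  # about 0.288 degrees
#' @export
single_streak_precision <- function(ws, hs) {
  stopifnot(ws >= 1, hs >= 1)
  if (ws <= hs) {
    if (hs < 2) stop("hs must be >= 2 when ws <= hs")
    rad2deg(atan(ws / (hs - 1)) - atan(ws / hs))
  } else {
    if (ws < 2) stop("ws must be >= 2 when ws > hs")
    rad2deg(atan(ws / hs) - atan((ws - 1) / hs))
  }
}

#' Maximum number of streaks that fit in an image
#'
#' With a minimum inter-streak spacing, the image can hold at most `ns`
#' streaks.  Streaks spanning the full image height (`hs == h`) are limited
#' by the spatial extent: `ns = floor(w * dx / ds)`.  Streaks spanning the
#' full width (`ws == w`) are limited by the temporal extent:
#' `ns = floor(h * dt_ms / 1000 / dt_streak)` when the minimum inter-streak
#' time `dt_streak` (seconds) is given, or the equivalent spatial form
#' `floor(h * dx * ws / (ds * hs))` otherwise.  When both extents are full
#' (a corner-to-corner streak) the spatial branch is used.  The count is
#' floored at 1 (with a warning) so downstream precision numbers stay
#' defined.
#'
#' @param w,h Image width and height, pixels.
#' @param dx Spatial resolution, um/pixel.
#' @param dt Line period, ms/line.
#' @param ws,hs Streak extents from [streak_extents()].
#' @param ds Minimum inter-streak distance along space, um (default 4).
#' @param dt_streak Optional minimum inter-streak time, seconds.
#' @return Integer streak count >= 1.
#' @examples
#' max_streak_count(w = 300, h = 100, dx = 1.19, dt = 1,
#'                  ws = 58, hs = 100, ds = 4)  # 89
#' @export
max_streak_count <- function(w, h, dx, dt, ws, hs, ds = 4, dt_streak = NULL) {
  if (!is.numeric(ds) || ds <= 0) stop("ds must be positive")
  if (hs == h) {
    ns <- floor(w * dx / ds)
  } else if (ws == w) {
    if (!is.null(dt_streak)) {
      if (dt_streak <= 0) stop("dt_streak must be positive")
      ns <- floor((h * dt / 1000) / dt_streak)
    } else {
      ns <- floor(h * dx * ws / (ds * hs))
    }
  } else {
    stop("inconsistent streak extents: neither hs == h nor ws == w")
  }
  if (ns < 1) {
    warning("image too small to hold one streak at the given spacing; using ns = 1")
    ns <- 1
  }
  as.integer(ns)
}

#' Theoretical finest detectable angle change for an image
#'
#' If one of `ns` streaks changes angle by the single-streak limit while the
#' others are unchanged, the aggregate projection shifts detectably at
#' `delta_n = delta_s1 / ns`: precision improves linearly with the number of
#' streaks.
#'
#' @param delta_s1 Single-streak precision, degrees
#'   ([single_streak_precision()]).
#' @param ns Streak count (>= 1), from [max_streak_count()].
#' @return Angle change in degrees.
#' @export
finest_detectable_angle <- function(delta_s1, ns) {
  stopifnot(delta_s1 > 0, ns >= 1)
  delta_s1 / ns
}

#' Fractional velocity change implied by an angle change
#'
#' `dv/v = tan(theta1) / tan(theta0) - 1`, signed.  The baseline angle must
#' be nonzero (zero baseline velocity).
#'
#' @param theta0 Baseline streak angle, degrees, in (-90, 90), nonzero.
#' @param theta1 New streak angle, degrees, in (-90, 90).
#' @return Signed fractional velocity change (0.01 = 1 percent).
#' @examples
#' dv_from_angle_change(45, 45.1)  # about 0.0035 (0.35 percent)
#' @export
dv_from_angle_change <- function(theta0, theta1) {
  stopifnot(is.numeric(theta0), is.numeric(theta1))
  if (any(abs(c(theta0, theta1)) >= 90))
    stop("angles must be inside (-90, 90) degrees")
  if (any(theta0 == 0))
    stop("theta0 must be nonzero (zero baseline velocity)")
  tan(deg2rad(theta1)) / tan(deg2rad(theta0)) - 1
}

#' Angle step needed to resolve a target fractional velocity change
#'
#' Inverse of [dv_from_angle_change()]:
#' `delta = |arctan((dv + 1) * tan(theta0)) - theta0|`.  This is the largest
#' angle step-size the Radon search may use while still resolving a velocity
#' change of `dv`; it is maximal at `theta0 = 45` degrees, which is why
#' acquisition is ideally tuned to 45-degree streaks.
#'
#' @param theta0 Baseline streak angle, degrees, in (0, 90).
#' @param dv Target fractional velocity change (> -1); e.g. 0.001 for 0.1
#'   percent.
#' @return Angle step in degrees.
#' @examples
#' angle_change_for_dv(45, 0.0035)  # about 0.1 degrees
#' @export
angle_change_for_dv <- function(theta0, dv) {
  check_open_angle(theta0, "theta0")
  stopifnot(is.numeric(dv))
  if (any(dv <= -1)) stop("dv must be > -1")
  abs(rad2deg(atan((dv + 1) * tan(deg2rad(theta0)))) - theta0)
}

#' Precision report for an acquisition geometry
#'
#' Bundles the pixel-resolution precision calculus for one measured angle and
#' image geometry: streak extents, single-streak precision `delta_s1`,
#' maximum streak count `ns`, and the theoretical finest detectable angle
#' change `delta_n = delta_s1 / ns`.  The realistically attainable precision
#' lies between `delta_n` and `delta_s1`, since real images may hold fewer
#' streaks than the packing limit.
#'
#' @param theta0 Measured streak angle, degrees (sign ignored).
#' @param w,h Image width (space) and height (time), pixels.
#' @param dx Spatial resolution, um/pixel.
#' @param dt Line period, ms/line.
#' @param ds Minimum inter-streak distance, um (default 4).
#' @param dt_streak Optional minimum inter-streak time, seconds (used for
#'   full-width streaks).
#' @return An object of class `precision_report`: list with `theta0`, `w`,
#'   `h`, `dx`, `dt`, `ws`, `hs`, `delta_s1`, `ns`, `delta_n`, `ds`,
#'   `dt_streak`.
#' @examples
#' precision_report(theta0 = 30, w = 300, h = 100, dx = 1.19, dt = 1)
#' @export
precision_report <- function(theta0, w, h, dx, dt, ds = 4, dt_streak = NULL) {
  ext <- streak_extents(theta0, w, h)
  delta_s1 <- single_streak_precision(ext["ws"], ext["hs"])
  ns <- max_streak_count(w, h, dx, dt, ext["ws"], ext["hs"],
                         ds = ds, dt_streak = dt_streak)
  structure(list(
    theta0 = abs(theta0), w = w, h = h, dx = dx, dt = dt,
    ws = unname(ext["ws"]), hs = unname(ext["hs"]),
    delta_s1 = unname(delta_s1), ns = ns,
    delta_n = unname(finest_detectable_angle(delta_s1, ns)),
    ds = ds, dt_streak = dt_streak
  ), class = "precision_report")
}

#' @export
print.precision_report <- function(x, ...) {
  cat("<precision_report>\n")
  cat(sprintf("  geometry: %d x %d px, dx = %g um/px, dt = %g ms/line\n",
              x$w, x$h, x$dx, x$dt))
  cat(sprintf("  streak angle theta0 = %g deg -> extents ws = %d, hs = %d px\n",
              x$theta0, x$ws, x$hs))
  cat(sprintf("  single-streak precision delta_s1 = %.6g deg\n", x$delta_s1))
  cat(sprintf("  max streak count ns = %d (ds = %g um)\n", x$ns, x$ds))
  cat(sprintf("  finest detectable angle change delta_n = %.6g deg\n",
              x$delta_n))
  invisible(x)
}

check_open_angle <- function(theta, name) {
  if (!is.numeric(theta) || any(!is.finite(theta)) ||
      any(theta <= 0) || any(theta >= 90))
    stop(name, " must be strictly inside (0, 90) degrees")
  invisible(theta)
}
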