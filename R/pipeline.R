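#' Split a line-scan sequence into analysis windows
#'
#' Windows are `[k * step, k * step + window)` in 0-based line indices, for
#' `k = 0 ... floor((n_lines - window) / step)`; a short remainder at the
#' tail is dropped rather than padded.
#'
#' @param n_lines Total number of lines in the sequence (>= `window`).
#' @param window Window length in lines (>= 8).
#' @param step Hop between window starts in lines, `1 <= step <= window`.
#' @return A data frame with columns `start` and `end` (0-based, half-open).
#' @examples
#' nrow(segment_sequence(35000, 100, 25))  # 1397 windows
#' @export
segment_sequence <- function(n_lines, window, step) {
  stopifnot(window >= 8, step >= 1, step <= window)
  if (n_lines < window)
    stop("sequence has ", n_lines, " lines, shorter than one ", window,
         "-line window")
  k <- 0:((n_lines - window) %/% step)
  data.frame(start = k * step, end = k * step + window)
}

#' Windowed velocity estimation over a long line-scan sequence
#'
#' Runs the full velocimetry pipeline: the sequence is cut into overlapping
#' windows ([segment_sequence()]); each window is filtered (vertical Sobel by
#' default) and its streak angle found with the coarse-to-fine
#' [iterative_radon()] search; angles are converted to velocities with
#' [velocity_from_angle()].  Per-window failures and structureless windows
#' are flagged invalid, never abort the trace.
#'
#' The precision target is given either directly as an angle step-size
#' `target_delta` (degrees), or as a fractional velocity change `target_dv`
#' (e.g. 0.001 for 0.1 percent).  In the latter case each window first runs a
#' fixed 7-iteration pre-pass (step-size 0.7 degrees) to obtain a provisional
#' angle, converts `target_dv` to the window's required step via
#' [angle_change_for_dv()], and deepens the search if the requirement is
#' finer -- the required step depends on the angle itself, so it is computed
#' per window.  Provisional angles shallower than 0.5 degrees are clamped to
#' 0.5 for this conversion (the required step vanishes as the angle does).
#'
#' @param image A [spacetime_image()] holding the whole sequence.
#' @param window Window length in lines (default 100).
#' @param step Hop between windows in lines (default 25).
#' @param target_delta Angle step-size target, degrees in (0, 45].
#' @param target_dv Fractional velocity-change target (> 0).  Supply exactly
#'   one of `target_delta` and `target_dv`.
#' @param filter Pre-processing filter: `"sobel"` (default), `"vdemean"`, or
#'   `"none"`.
#' @return An object of class `velocity_trace`: list with `samples` (a data
#'   frame with columns `segment_index`, `start_line`, `end_line`,
#'   `t_center_ms`, `angle_deg`, `velocity_mm_s`, `peak_variance`,
#'   `n_transforms`, `achieved_delta_deg`, `valid`), plus `window`, `step`,
#'   `dx`, `dt` and a `summary` of valid/invalid counts.
#' @examples
#' seq_img <- generate_sequence(
#'   list(synthetic_spec(theta = 40, height = 400)), n_lines = 400)
#' tr <- estimate_trace(seq_img, window = 100, step = 100, target_delta = 0.5)
#' tr$samples$angle_deg
#' @export
estimate_trace <- function(image, window = 100, step = 25,
                           target_delta = NULL, target_dv = NULL,
                           filter = c("sobel", "vdemean", "none")) {
  validate_image(image)
  filter <- match.arg(filter)
  if (is.null(target_delta) == is.null(target_dv))
    stop("supply exactly one of target_delta and target_dv")
  if (!is.null(target_dv) && (!is.numeric(target_dv) || target_dv <= 0))
    stop("target_dv must be a positive fraction")
  segs <- segment_sequence(nrow(image$pixels), window, step)
  n <- nrow(segs)
  rows <- vector("list", n)
  for (k in seq_len(n)) {
    sub <- structure(list(
      pixels = image$pixels[(segs$start[k] + 1):segs$end[k], , drop = FALSE],
      dx = image$dx, dt = image$dt, filter = "none"
    ), class = "spacetime_image")
    res <- tryCatch(
      estimate_window(sub, filter, target_delta, target_dv),
      error = function(e) NULL
    )
    if (is.null(res)) {
      rows[[k]] <- data.frame(
        segment_index = k - 1L, start_line = segs$start[k],
        end_line = segs$end[k],
        t_center_ms = (segs$start[k] + window / 2) * image$dt,
        angle_deg = NA_real_, velocity_mm_s = NA_real_,
        peak_variance = NA_real_, n_transforms = NA_integer_,
        achieved_delta_deg = NA_real_, valid = FALSE
      )
    } else {
      vel <- if (res$valid && abs(res$theta) < 90)
        velocity_from_angle(res$theta, image$dx, image$dt)
      else NA_real_
      rows[[k]] <- data.frame(
        segment_index = k - 1L, start_line = segs$start[k],
        end_line = segs$end[k],
        t_center_ms = (segs$start[k] + window / 2) * image$dt,
        angle_deg = res$theta,
        velocity_mm_s = vel,
        peak_variance = res$peak_variance,
        n_transforms = res$n_transforms,
        achieved_delta_deg = res$achieved_delta,
        valid = res$valid && abs(res$theta) < 90
      )
    }
  }
  samples <- do.call(rbind, rows)
  velocity_trace(samples, window, step, image$dx, image$dt)
}

# One window: filter, then iterative search; for a dv target, a 7-iteration
# pre-pass fixes the provisional angle and the search is deepened in place.
estimate_window <- function(sub, filter, target_delta, target_dv) {
  f <- apply_filter(sub, filter)
  if (!is.null(target_delta)) return(iterative_radon(f, target_delta = target_delta))
  st <- iterative_radon_state(f)
  for (i in 1:7) st <- iterative_radon_step(st)
  theta0 <- max(abs(st$best_theta), 0.5)
  if (theta0 >= 90) theta0 <- 89.5
  delta_req <- angle_change_for_dv(theta0, target_dv)
  delta_req <- min(max(delta_req, 1e-6), 45)
  extra <- iterations_needed(delta_req) - st$i
  if (extra > 0) for (i in seq_len(extra)) st <- iterative_radon_step(st)
  iterative_radon_result(st)
}

velocity_trace <- function(samples, window, step, dx, dt) {
  structure(list(
    samples = samples, window_lines = window, step_lines = step,
    dx = dx, dt = dt,
    summary = c(n = nrow(samples), valid = sum(samples$valid),
                invalid = sum(!samples$valid))
  ), class = "velocity_trace")
}

#' @export
print.velocity_trace <- function(x, ...) {
  cat(sprintf(
    "<velocity_trace> %d windows of %d lines (step %d), %d valid / %d invalid\n",
    x$summary["n"], x$window_lines, x$step_lines,
    x$summary["valid"], x$summary["invalid"]))
  invisible(x)
}

#' Flag near-horizontal angle estimates as outliers
#'
#' Failed angle searches on artifact-dominated windows cluster at +/-90
#' degrees (horizontal structure from motion artifacts outcompetes the
#' streaks).  Samples with `|angle| >= 90 - boundary_margin` are marked
#' invalid; existing flags are preserved, and the operation is idempotent.
#'
#' @param trace A `velocity_trace` from [estimate_trace()].
#' @param boundary_margin Margin in degrees, in (0, 45).
#' @return The trace with updated `valid` flags and summary.
#' @export
flag_outliers <- function(trace, boundary_margin = 0.5) {
  stopifnot(inherits(trace, "velocity_trace"),
            boundary_margin > 0, boundary_margin < 45)
  s <- trace$samples
  bad <- !is.na(s$angle_deg) & abs(s$angle_deg) >= 90 - boundary_margin
  s$valid <- s$valid & !bad
  velocity_trace(s, trace$window_lines, trace$step_lines, trace$dx, trace$dt)
}

#' Moving-average smoothing of a velocity trace
#'
#' Centered moving average of the valid velocities over a time span, e.g. a
#' span covering several cardiac cycles to suppress heartbeat-driven
#' velocity pulsation.  Invalid samples are excluded from every mean and
#' keep their flags; a span shorter than the sample spacing returns the
#' trace unchanged with a warning.
#'
#' @param trace A `velocity_trace`.
#' @param span Averaging span in seconds (> 0).
#' @return The trace with smoothed `velocity_mm_s` for valid samples.
#' @export
smooth_trace <- function(trace, span) {
  stopifnot(inherits(trace, "velocity_trace"), is.numeric(span), span > 0)
  s <- trace$samples
  if (nrow(s) == 0L || sum(s$valid) == 0L) return(trace)
  spacing_s <- trace$step_lines * trace$dt / 1000
  if (span < spacing_s) {
    warning("span (", span, " s) shorter than the sample spacing (",
            spacing_s, " s); trace unchanged")
    return(trace)
  }
  t_s <- s$t_center_ms / 1000
  half <- span / 2
  v <- s$velocity_mm_s
  sm <- v
  for (i in which(s$valid)) {
    sel <- s$valid & abs(t_s - t_s[i]) <= half
    sm[i] <- mean(v[sel])
  }
  s$velocity_mm_s <- sm
  velocity_trace(s, trace$window_lines, trace$step_lines, trace$dx, trace$dt)
}
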