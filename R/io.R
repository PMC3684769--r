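#' Read a line-scan image from TIFF or plain text
#'
#' Reads a space-time image from a single- or multi-page grayscale TIFF
#' (pages are concatenated row-wise in page order, matching acquisitions
#' saved as stacks of line blocks) or from a whitespace-delimited numeric
#' text matrix.  Pixel values are kept in their native numeric range; no
#' rescaling is applied (the angle search is invariant to affine luminance
#' maps, and raw values ease cross-checking against the source file).
#'
#' @param path Path to a `.tif`/`.tiff` file or a text matrix.
#' @param dx Spatial resolution, um/pixel.
#' @param dt Line period, ms/line.
#' @return A [spacetime_image()].
#' @export
read_linescan <- function(path, dx, dt) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    info <- tiff::readTIFF(path, info = TRUE, payload = FALSE)
    # 8/16-bit: keep the native integer counts; 32-bit: stored as a
    # fixed-point encoding of [0, 1], read back as floating point
    as_is <- !any(info$bits.per.sample == 32L)
    pages <- tiff::readTIFF(path, all = TRUE, as.is = as_is)
    if (!is.list(pages)) pages <- list(pages)
    pages <- lapply(pages, function(pg) {
      if (length(dim(pg)) == 3L) {
        if (dim(pg)[3] > 1L)
          stop("color TIFF not supported: expected a grayscale line-scan image")
        pg <- pg[, , 1L]
      }
      pg
    })
    px <- do.call(rbind, pages)
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) stop("empty text matrix: ", path)
    rows <- suppressWarnings(
      lapply(strsplit(trimws(lines), "[ \t,]+"), as.numeric))
    ncols <- lengths(rows)
    if (length(unique(ncols)) != 1L)
      stop("ragged text matrix: rows have ", paste(unique(ncols), collapse = ", "),
           " fields")
    if (anyNA(unlist(rows)))
      stop("non-numeric values in text matrix: ", path)
    px <- do.call(rbind, rows)
  }
  spacetime_image(px, dx = dx, dt = dt)
}

#' Write a line-scan image to TIFF or plain text
#'
#' Text output (any extension other than `.tif`/`.tiff`) is a lossless
#' whitespace-delimited matrix.  TIFF output uses 32-bit samples encoding
#' values in \[0, 1\] to a precision of about 2e-10; values outside that
#' range are affinely rescaled with a warning (harmless for angle
#' estimation, which is invariant to affine luminance maps).
#'
#' @param image A [spacetime_image()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_linescan <- function(image, path) {
  validate_image(image)
  p <- image$pixels
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (min(p) < 0 || max(p) > 1) {
      warning("pixel values rescaled to [0, 1] for TIFF output")
      rng <- range(p)
      p <- if (diff(rng) > 0) (p - rng[1]) / diff(rng) else p * 0
    }
    tiff::writeTIFF(p, path, bits.per.sample = 32L)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(apply(p, 1L, function(r) paste(format(r, digits = 17),
                                              collapse = " ")), con)
  }
  invisible(path)
}

trace_csv_header <- c("segment_index", "start_line", "end_line", "t_center_ms",
                      "angle_deg", "velocity_mm_s", "peak_variance",
                      "n_transforms", "achieved_delta_deg", "valid")

#' Write a velocity trace to CSV
#'
#' One row per analysis window with the columns `segment_index, start_line,
#' end_line, t_center_ms, angle_deg, velocity_mm_s, peak_variance,
#' n_transforms, achieved_delta_deg, valid`; floating values carry at least
#' six significant digits and `valid` is written as `true`/`false`.
#'
#' @param trace A `velocity_trace` from [estimate_trace()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "velocity_trace"))
  s <- trace$samples
  num <- function(x) ifelse(is.na(x), "NA", vapply(x, function(v)
    format(v, digits = 9), character(1)))
  lines <- c(
    paste(trace_csv_header, collapse = ","),
    if (nrow(s) > 0) paste(
      s$segment_index, s$start_line, s$end_line, num(s$t_center_ms),
      num(s$angle_deg), num(s$velocity_mm_s), num(s$peak_variance),
      ifelse(is.na(s$n_transforms), "NA", s$n_transforms),
      num(s$achieved_delta_deg),
      ifelse(s$valid, "true", "false"), sep = ","
    )
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read back a velocity trace CSV
#'
#' Inverse of [write_trace()], restoring the sample table of a
#' `velocity_trace`.  Window geometry and acquisition metadata are not
#' stored in the CSV; they can be supplied to rebuild a full trace object.
#'
#' @param path CSV path written by [write_trace()].
#' @param window,step,dx,dt Optional trace metadata to restore.
#' @return A `velocity_trace`.
#' @export
read_trace <- function(path, window = NA, step = NA, dx = NA, dt = NA) {
  s <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(s), trace_csv_header))
    stop("not a velocity trace CSV: unexpected columns")
  s$valid <- s$valid == "true" | s$valid == "TRUE" | s$valid == TRUE
  velocity_trace(s, window, step, dx, dt)
}
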