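#' Thermal video container
#'
#' A calibrated temperature frame stack. Temperatures are plain degrees
#' Celsius; any count-to-temperature calibration lives at the I/O boundary
#' only, because the method exploits temperature *fluctuations*, not absolute
#' radiometric accuracy.
#'
#' @param frames 3-D numeric array, `time x rows x cols`, degrees Celsius.
#' @param fps frame rate in Hz (> 0).
#' @param origin_time acquisition start time in seconds.
#' @return An object of class `thermal_video` with fields `frames`, `fps`,
#'   `origin_time`.
#' @export
thermal_video <- function(frames, fps, origin_time = 0) {
  tv_assert(is.array(frames) && length(dim(frames)) == 3,
            "`frames` must be a 3-D array (time x rows x cols)", "tv_config_error")
  d <- dim(frames)
  tv_assert(d[1] >= 1 && d[2] >= 1 && d[3] >= 1,
            "video needs at least one frame with at least one pixel", "tv_config_error")
  tv_assert(all(is.finite(frames)), "frames contain non-finite values", "tv_config_error")
  tv_assert(is.numeric(fps) && length(fps) == 1 && is.finite(fps) && fps > 0,
            "`fps` must be a single positive number", "tv_config_error")
  structure(list(frames = frames, fps = fps, origin_time = origin_time),
            class = "thermal_video")
}

#' @export
print.thermal_video <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<thermal_video> %d frames, %d x %d px, %.6g fps, %.1f s, %.2f..%.2f degC\n",
              d[1], d[2], d[3], x$fps, d[1] / x$fps, min(x$frames), max(x$frames)))
  invisible(x)
}

n_frames <- function(video) dim(video$frames)[1]

#' Rectangular region of interest
#'
#' 0-based, half-open pixel rectangle `[row0, row0+height) x [col0, col0+width)`
#' with row increasing downward. All "vertical" motion in the package is the
#' row coordinate; one stated convention prevents sign errors in the
#' ballistocardiogram polarity.
#'
#' @param row0,col0 0-based integer indices of the top-left pixel.
#' @param height,width positive integer pixel counts.
#' @return An object of class `rect_roi`.
#' @export
rect_roi <- function(row0, col0, height, width) {
  v <- c(row0, col0, height, width)
  tv_assert(all(v == round(v)) && all(is.finite(v)),
            "ROI fields must be integers", "tv_config_error")
  tv_assert(row0 >= 0 && col0 >= 0, "ROI origin must be >= 0", "tv_config_error")
  tv_assert(height >= 1 && width >= 1, "ROI must be at least 1 x 1", "tv_config_error")
  structure(list(row0 = as.integer(row0), col0 = as.integer(col0),
                 height = as.integer(height), width = as.integer(width)),
            class = "rect_roi")
}

# 1-based row/col index vectors for subsetting R matrices.
roi_rows <- function(roi) seq.int(roi$row0 + 1L, roi$row0 + roi$height)
roi_cols <- function(roi) seq.int(roi$col0 + 1L, roi$col0 + roi$width)

roi_check_inside <- function(roi, nrow, ncol) {
  tv_assert(roi$row0 + roi$height <= nrow && roi$col0 + roi$width <= ncol,
            sprintf("ROI [%d,%d,%d,%d] does not fit a %d x %d frame",
                    roi$row0, roi$col0, roi$height, roi$width, nrow, ncol),
            "tv_config_error")
}

#' Parse a "row0,col0,height,width" ROI string
#' @param s character scalar such as `"40,32,24,64"` (0-based).
#' @return A [rect_roi()].
#' @export
parse_roi <- function(s) {
  v <- suppressWarnings(as.numeric(strsplit(trimws(s), ",")[[1]]))
  tv_assert(length(v) == 4 && all(is.finite(v)),
            "ROI string must be 'row0,col0,height,width'", "tv_config_error")
  rect_roi(v[1], v[2], v[3], v[4])
}

#' Uniformly sampled 1-D signal
#'
#' @param values finite numeric vector.
#' @param fs sampling rate in Hz (> 0).
#' @param t0 time of the first sample in seconds.
#' @return An object of class `signal_trace`.
#' @export
signal_trace <- function(values, fs, t0 = 0) {
  tv_assert(is.numeric(values) && length(values) >= 1, "empty signal", "tv_config_error")
  tv_assert(all(is.finite(values)), "signal contains non-finite values", "tv_config_error")
  tv_assert(is.numeric(fs) && length(fs) == 1 && is.finite(fs) && fs > 0,
            "`fs` must be a single positive number", "tv_config_error")
  structure(list(values = as.numeric(values), fs = fs, t0 = t0),
            class = "signal_trace")
}

trace_times <- function(trace) trace$t0 + (seq_along(trace$values) - 1) / trace$fs

#' Time-stamped instantaneous rate series
#'
#' Rates are per-minute. Construction enforces a physiological plausibility
#' band: 39-120 beats/min for `kind = "heart"`, 6-51 breaths/min for
#' `kind = "respiration"` (the analysis pass bands times 60). The band can be
#' overridden for non-physiological data. A zero-length series is allowed and
#' represents "no confident estimate".
#'
#' @param times seconds, strictly increasing.
#' @param rates per-minute rates, within `band`.
#' @param kind `"heart"` or `"respiration"`.
#' @param band length-2 plausibility band in per-minute units, or `NULL` for
#'   the kind-specific default.
#' @return An object of class `rate_series`.
#' @export
rate_series <- function(times, rates, kind = c("heart", "respiration"), band = NULL) {
  kind <- match.arg(kind)
  if (is.null(band)) band <- if (kind == "heart") c(39, 120) else c(6, 51)
  tv_assert(length(times) == length(rates), "times/rates length mismatch", "tv_config_error")
  if (length(times) > 0) {
    tv_assert(all(is.finite(times)) && all(is.finite(rates)),
              "non-finite times or rates", "tv_config_error")
    tv_assert(all(diff(times) > 0), "times must be strictly increasing", "tv_format_error")
    tv_assert(all(rates > 0), "rates must be positive", "tv_config_error")
    tv_assert(all(rates >= band[1] & rates <= band[2]),
              sprintf("rates outside plausibility band [%g, %g] per minute",
                      band[1], band[2]), "tv_config_error")
  }
  structure(list(times = as.numeric(times), rates = as.numeric(rates),
                 kind = kind, band = band),
            class = "rate_series")
}

#' @export
print.rate_series <- function(x, ...) {
  cat(sprintf("<rate_series: %s> %d estimates", x$kind, length(x$rates)))
  if (length(x$rates) > 0)
    cat(sprintf(", %.1f..%.1f /min over %.1f..%.1f s",
                min(x$rates), max(x$rates), min(x$times), max(x$times)))
  cat("\n")
  invisible(x)
}
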