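#' Read a thermal video from a 16-bit multi-page TIFF plus JSON sidecar
#'
#' The TIFF stores raw sensor counts; the sidecar supplies the affine
#' count-to-temperature calibration and the frame rate:
#' `temperature = counts * scale + offset`. This mirrors the de-facto
#' export path of scientific thermography software.
#'
#' @param path multi-page 16-bit TIFF file.
#' @param sidecar JSON file with keys `fps` (Hz), `scale` (K per count) and
#'   `offset` (degrees Celsius). Defaults to `<path>.json`.
#' @return A [thermal_video()].
#' @export
read_video <- function(path, sidecar = paste0(path, ".json")) {
  tv_assert(file.exists(path), sprintf("video file not found: %s", path), "tv_io_error")
  tv_assert(file.exists(sidecar), sprintf("sidecar not found: %s", sidecar), "tv_io_error")
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  for (key in c("fps", "scale", "offset"))
    tv_assert(!is.null(meta[[key]]) && is.finite(meta[[key]]),
              sprintf("sidecar is missing key '%s'", key), "tv_config_error")
  tv_assert(meta$fps > 0, "sidecar fps must be > 0", "tv_config_error")
  tv_assert(meta$scale > 0, "sidecar scale must be > 0", "tv_config_error")
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  dims <- vapply(pages, function(p) dim(p)[1:2], integer(2))
  tv_assert(all(dims[1, ] == dims[1, 1]) && all(dims[2, ] == dims[2, 1]),
            "TIFF pages differ in size", "tv_format_error")
  frames <- array(0, c(length(pages), dims[1, 1], dims[2, 1]))
  for (t in seq_along(pages))
    frames[t, , ] <- pages[[t]] * meta$scale + meta$offset
  thermal_video(frames, fps = meta$fps, origin_time = meta$origin_time %||% 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a thermal video as 16-bit multi-page TIFF plus JSON sidecar
#'
#' Inverse of [read_video()]: counts = `round((T - offset) / scale)` clipped
#' to `[0, 65535]`. The default calibration places `offset` just below the
#' video minimum with a 0.01 K/count quantization step (half-step round-trip
#' error 0.005 K, well below a 0.025 K camera noise floor).
#'
#' @param video a [thermal_video()].
#' @param path output TIFF path.
#' @param sidecar output JSON path; defaults to `<path>.json`.
#' @param scale K per count; widened automatically if the video range
#'   exceeds the 16-bit span.
#' @param offset degrees Celsius mapped to count 0.
#' @export
write_video <- function(video, path, sidecar = paste0(path, ".json"),
                        scale = NULL, offset = NULL) {
  stopifnot(inherits(video, "thermal_video"))
  rng <- range(video$frames)
  if (is.null(offset)) offset <- floor(rng[1])
  if (is.null(scale)) scale <- max(0.01, (rng[2] - offset) / 65535)
  pages <- vector("list", n_frames(video))
  for (t in seq_len(n_frames(video))) {
    counts <- round((video$frames[t, , ] - offset) / scale)
    counts <- pmin(pmax(counts, 0), 65535)
    pages[[t]] <- counts / 65535  # writeTIFF maps [0,1] onto 16-bit counts
  }
  ok <- tryCatch(tiff::writeTIFF(pages, path, bits.per.sample = 16L),
                 error = function(e) tv_stop(conditionMessage(e), "tv_io_error"))
  jsonlite::write_json(
    list(fps = video$fps, scale = scale, offset = offset,
         origin_time = video$origin_time),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(ok)
}

#' Read / write rate series CSV
#'
#' Plain CSV with columns `time_s,rate_per_min` and a `# kind: <heart|respiration>`
#' comment header, losslessly round-trippable at printed precision.
#'
#' @param path CSV file.
#' @param band optional plausibility band override passed to [rate_series()].
#' @return A [rate_series()].
#' @export
read_rate_csv <- function(path, band = NULL) {
  tv_assert(file.exists(path), sprintf("rate file not found: %s", path), "tv_io_error")
  hdr <- readLines(path, n = 5L)
  kindline <- grep("^#\\s*kind:", hdr, value = TRUE)
  kind <- if (length(kindline) > 0) trimws(sub("^#\\s*kind:", "", kindline[1])) else "heart"
  df <- read.csv(path, comment.char = "#")
  tv_assert(all(c("time_s", "rate_per_min") %in% names(df)),
            "rate CSV must have columns time_s,rate_per_min", "tv_format_error")
  tv_assert(nrow(df) > 0, "rate CSV has no data rows", "tv_degenerate_error")
  tv_assert(all(diff(df$time_s) > 0), "times in rate CSV are not strictly increasing",
            "tv_format_error")
  rate_series(df$time_s, df$rate_per_min, kind = kind, band = band)
}

#' @rdname read_rate_csv
#' @param series a [rate_series()].
#' @export
write_rate_csv <- function(series, path) {
  stopifnot(inherits(series, "rate_series"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# kind: %s", series$kind), con)
  writeLines("time_s,rate_per_min", con)
  if (length(series$times) > 0)
    writeLines(paste(format(series$times, trim = TRUE, scientific = FALSE),
                     format(series$rates, trim = TRUE, scientific = FALSE), sep = ","), con)
  invisible(path)
}

#' Export a feature track set as CSV (point_id, frame, x, y, valid)
#' @param tracks a `feature_tracks` object from [track_features()].
#' @param path output CSV path.
#' @export
write_tracks_csv <- function(tracks, path) {
  np <- dim(tracks$positions)[1]
  nf <- dim(tracks$positions)[2]
  df <- data.frame(
    point_id = rep(tracks$ids, each = nf),
    frame = rep(seq_len(nf) - 1L, times = np),
    x = as.vector(t(tracks$positions[, , 1])),
    y = as.vector(t(tracks$positions[, , 2])),
    valid = as.vector(t(tracks$valid)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
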