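#' Respiratory-rate branch configuration
#'
#' The respiratory waveform is the mean temperature of a nose region of
#' measurement (ROM), band-passed at 0.1-0.85 Hz (6-51 breaths/min).
#' Breath-to-breath intervals are searched over integer lags
#' `m in [ceil(fs/0.85), floor(fs/0.1)]` samples - exactly the periods the
#' pass band admits.
#'
#' @param band pass band in Hz.
#' @param rom_frac fraction of the tracked ROI area used as the centred ROM;
#'   a sub-rectangle improves SNR by avoiding ROI borders that slide off the
#'   nostrils.
#' @param stride samples between interval estimates; `NULL` means one
#'   estimate per second (`fs` samples).
#' @param search_radius template-search radius in px for [track_roi()].
#' @param min_corr minimum acceptable normalized correlation peak.
#' @param subharmonic_theta sub-harmonic disambiguation threshold in
#'   `[0, 1]`, or 0 to disable. A signal with breath interval T also scores
#'   highly at lags 2T and 3T (any T-periodic signal is 2T-periodic), so
#'   the fused posterior can carry near-equal peaks at integer multiples of
#'   the true interval. As in pitch estimation, the reported interval is the
#'   *smallest* integer sub-multiple of the posterior argmax whose local
#'   posterior mass reaches `subharmonic_theta` times the argmax mass.
#' @return An `rr_config` list.
#' @export
rr_config <- function(band = c(0.1, 0.85), rom_frac = 0.5, stride = NULL,
                      search_radius = 20, min_corr = 0.3,
                      subharmonic_theta = 0.5) {
  tv_assert(band[1] > 0 && band[1] < band[2], "invalid band", "tv_config_error")
  tv_assert(rom_frac > 0 && rom_frac <= 1, "rom_frac must be in (0, 1]", "tv_config_error")
  tv_assert(subharmonic_theta >= 0 && subharmonic_theta <= 1,
            "subharmonic_theta must be in [0, 1]", "tv_config_error")
  structure(list(band = band, rom_frac = rom_frac, stride = stride,
                 search_radius = search_radius, min_corr = min_corr,
                 subharmonic_theta = subharmonic_theta),
            class = "rr_config")
}

# Posterior mass in a +-3-lag neighbourhood of lag m.
local_mass <- function(posterior, m) {
  sum(posterior$probs[abs(posterior$lags - m) <= 3])
}

# Replace the fused argmax by its smallest integer sub-multiple that is
# comparably supported by the posterior (sub-harmonic disambiguation).
resolve_subharmonic <- function(posterior, m_hat, m_min, theta) {
  if (theta <= 0) return(m_hat)
  ref <- local_mass(posterior, m_hat)
  for (k in 3:2) {
    mk <- round(m_hat / k)
    if (mk >= m_min && local_mass(posterior, mk) >= theta * ref) return(mk)
  }
  m_hat
}

rr_lag_range <- function(fs, band) {
  m_min <- as.integer(ceiling(fs / band[2]))
  m_max <- as.integer(floor(fs / band[1]))
  tv_assert(m_min >= 2 && m_max > m_min,
            "sampling rate too low for the requested band", "tv_config_error")
  c(m_min, m_max)
}

#' Track a rectangular ROI across a video
#'
#' Rough motion compensation: the frame-1 ROI content is the template, and
#' every later frame is searched by normalized cross-correlation within
#' `search_radius` pixels of the previous position. Integer-pixel offsets
#' are sufficient here because the ROM averages tens of pixels.
#'
#' @param video a [thermal_video()].
#' @param roi [rect_roi()] valid in frame 1.
#' @param search_radius search half-width in px.
#' @param min_corr minimum correlation peak; below it tracking is declared
#'   lost (typed error naming the frame).
#' @return Integer matrix `n_frames x 2` of (row, col) offsets relative to
#'   frame 1, with attribute `peak` (per-frame correlation).
#' @export
track_roi <- function(video, roi, search_radius = 20, min_corr = 0.3) {
  stopifnot(inherits(video, "thermal_video"))
  d <- dim(video$frames)
  roi_check_inside(roi, d[2], d[3])
  stack <- aperm(video$frames, c(2, 3, 1))
  res <- .ncc_track_cpp(stack, roi$row0, roi$col0, roi$height, roi$width,
                        radius = as.integer(search_radius))
  if (isTRUE(res$flat_template))
    tv_stop("ROI template has no contrast: correlation is flat", "tv_tracking_error")
  bad <- which(res$peak < min_corr)
  if (length(bad) > 0)
    tv_stop(sprintf("ROI tracking lost at frame %d (peak correlation %.2f)",
                    bad[1], res$peak[bad[1]]), "tv_tracking_error")
  offsets <- res$offsets
  attr(offsets, "peak") <- res$peak
  offsets
}

#' Respiratory waveform: mean ROM temperature per frame
#'
#' The ROM is a centred sub-rectangle of the tracked ROI with
#' `rom_frac` times its area (aspect preserved). The waveform value at
#' frame t is the arithmetic mean of the in-ROM temperatures - the nasal
#' airflow signal.
#'
#' @param video a [thermal_video()].
#' @param roi the tracked [rect_roi()].
#' @param roi_track offsets from [track_roi()] (or `NULL` for a static ROI).
#' @param cfg an [rr_config()].
#' @return A [signal_trace()] at the video frame rate.
#' @export
rom_waveform <- function(video, roi, roi_track = NULL, cfg = rr_config()) {
  stopifnot(inherits(video, "thermal_video"))
  d <- dim(video$frames)
  if (is.null(roi_track)) roi_track <- matrix(0L, d[1], 2)
  s <- sqrt(cfg$rom_frac)
  hh <- max(1L, round(roi$height * s))
  ww <- max(1L, round(roi$width * s))
  dr0 <- roi$row0 + floor((roi$height - hh) / 2)
  dc0 <- roi$col0 + floor((roi$width - ww) / 2)
  vals <- numeric(d[1])
  for (t in seq_len(d[1])) {
    r <- dr0 + roi_track[t, 1]
    c <- dc0 + roi_track[t, 2]
    vals[t] <- mean(video$frames[t, (r + 1):(r + hh), (c + 1):(c + ww)])
  }
  signal_trace(vals, fs = video$fps, t0 = video$origin_time)
}

check_estimator_window <- function(window, m) {
  n <- length(window)
  tv_assert(n %% 2 == 1, "estimator window must have odd length", "tv_degenerate_error")
  tv_assert(m >= 1 && 2 * m + 1 <= n,
            sprintf("window of %d samples cannot support lag m = %d", n, m),
            "tv_degenerate_error")
  (n - 1) / 2  # index of w[0] minus 1 (0-based centre)
}

#' Breath-interval estimators on an adaptive centred window
#'
#' The analysis window `w` spans `[-m, m]` samples around the current
#' centre, re-sliced per candidate lag m ("adaptive window"). `w[v]` below
#' means `window[centre + v]`.
#'
#' * `estimator_ac`: adaptive-window autocorrelation
#'   `(1/m) * sum_{v=0..m} w[v] * w[v-m]` - correlation between the m
#'   samples right and left of the centre.
#' * `estimator_amdf`: reciprocal of the average magnitude difference
#'   `(1/m) * sum_{v=0..m} |w[v] - w[v-m]|` (guarded by epsilon 1e-12), so
#'   that, like the others, maxima mark the true interval.
#' * `estimator_map`: maximum amplitude pairs
#'   `max_{v in 0..m} (w[v] + w[v-m])` - an indirect peak detector, maximal
#'   when two peaks m samples apart lie in the window.
#'
#' @param window numeric vector of odd length `2M + 1` (centred slice of the
#'   band-passed waveform), with `M >= m`.
#' @param m candidate lag in samples.
#' @return A single numeric estimator value.
#' @export
estimator_ac <- function(window, m) {
  ctr <- check_estimator_window(window, m)
  v <- 0:m
  sum(window[ctr + 1 + v] * window[ctr + 1 + v - m]) / m
}

#' @rdname estimator_ac
#' @export
estimator_amdf <- function(window, m) {
  ctr <- check_estimator_window(window, m)
  v <- 0:m
  d <- sum(abs(window[ctr + 1 + v] - window[ctr + 1 + v - m])) / m
  1 / (d + 1e-12)
}

#' @rdname estimator_ac
#' @export
estimator_map <- function(window, m) {
  ctr <- check_estimator_window(window, m)
  v <- 0:m
  max(window[ctr + 1 + v] + window[ctr + 1 + v - m])
}

#' Convert estimator values over the lag range into a probability mass
#'
#' Shift-and-normalize: values are shifted to be non-negative (subtracting
#' the minimum) and normalized to sum to one, so each estimator can be read
#' as a discrete posterior over candidate breath intervals. An all-equal
#' input yields the uniform distribution.
#'
#' @param values finite numeric vector, one value per lag.
#' @param lags integer lags (samples) the values correspond to.
#' @return A `lag_posterior`: list with `lags`, `probs` (sums to 1).
#' @export
to_posterior <- function(values, lags = seq_along(values)) {
  tv_assert(length(values) >= 1 && all(is.finite(values)),
            "estimator values must be finite", "tv_degenerate_error")
  shifted <- values - min(values)
  s <- sum(shifted)
  probs <- if (s == 0) rep(1 / length(values), length(values)) else shifted / s
  structure(list(lags = as.integer(lags), probs = probs), class = "lag_posterior")
}

#' Bayesian fusion of the three lag posteriors
#'
#' Elementwise product of the three probability masses, renormalized:
#' the posterior of the interval given all three estimators, assuming
#' conditional independence. The fused interval is the posterior argmax
#' (ties to the smaller lag). If the product vanishes everywhere the fusion
#' is degenerate; the autocorrelation argmax is returned with
#' `degenerate = TRUE`.
#'
#' @param p_ac,p_amdf,p_map `lag_posterior` objects on identical lag grids.
#' @return List: `posterior` (`lag_posterior`), `m_hat` (samples),
#'   `degenerate`.
#' @export
fuse_bayes <- function(p_ac, p_amdf, p_map) {
  tv_assert(identical(p_ac$lags, p_amdf$lags) && identical(p_ac$lags, p_map$lags),
            "posteriors must share one lag grid", "tv_config_error")
  prod <- p_ac$probs * p_amdf$probs * p_map$probs
  s <- sum(prod)
  if (s == 0) {
    m_hat <- p_ac$lags[which.max(p_ac$probs)]
    return(list(posterior = to_posterior(p_ac$probs, p_ac$lags),
                m_hat = m_hat, degenerate = TRUE))
  }
  probs <- prod / s
  list(posterior = structure(list(lags = p_ac$lags, probs = probs),
                             class = "lag_posterior"),
       m_hat = p_ac$lags[which.max(probs)], degenerate = FALSE)
}

#' Estimate a respiratory-rate series from thermal video
#'
#' End-to-end respiratory branch: track the nose ROI, extract the mean-ROM
#' temperature waveform, band-pass it at 0.1-0.85 Hz, then at every
#' stride-spaced centre with full `[-m_max, m_max]` support evaluate the
#' three interval estimators for every candidate lag, fuse them, and
#' convert the fused interval to a rate: `RR = 60 * fs / m_hat`
#' breaths/min, stamped at the centre time.
#'
#' @param video a [thermal_video()].
#' @param roi nose [rect_roi()] (0-based).
#' @param cfg an [rr_config()].
#' @return A [rate_series()] of kind `"respiration"`.
#' @export
estimate_rr_series <- function(video, roi, cfg = rr_config()) {
  stopifnot(inherits(video, "thermal_video"))
  track <- pipeline_stage("roi_tracking",
                          track_roi(video, roi, cfg$search_radius, cfg$min_corr))
  trace <- pipeline_stage("rom_waveform", rom_waveform(video, roi, track, cfg))
  lr <- rr_lag_range(video$fps, cfg$band)
  n <- length(trace$values)
  tv_assert(n >= 2 * lr[2] + 1,
            sprintf("trace of %d samples cannot support m_max = %d (need %d)",
                    n, lr[2], 2 * lr[2] + 1), "tv_degenerate_error")
  filt <- pipeline_stage("bandpass",
                         butter_bandpass(trace, cfg$band[1], cfg$band[2]))
  stride <- cfg$stride %||% round(video$fps)
  centers <- seq(lr[2] + 1, n - lr[2], by = stride)
  lags <- lr[1]:lr[2]
  times <- rates <- numeric(0)
  for (ctr in centers) {
    win <- filt$values[(ctr - lr[2]):(ctr + lr[2])]
    e_ac <- e_amdf <- e_map <- numeric(length(lags))
    for (i in seq_along(lags)) {
      m <- lags[i]
      sub <- win[(lr[2] + 1 - m):(lr[2] + 1 + m)]
      e_ac[i] <- estimator_ac(sub, m)
      e_amdf[i] <- estimator_amdf(sub, m)
      e_map[i] <- estimator_map(sub, m)
    }
    fused <- fuse_bayes(to_posterior(e_ac, lags), to_posterior(e_amdf, lags),
                        to_posterior(e_map, lags))
    m_hat <- resolve_subharmonic(fused$posterior, fused$m_hat, lr[1],
                                 cfg$subharmonic_theta)
    rr <- 60 * video$fps / m_hat
    if (rr >= 6 && rr <= 51) {
      times <- c(times, trace$t0 + (ctr - 1) / video$fps)
      rates <- c(rates, rr)
    }
  }
  rate_series(times, rates, kind = "respiration")
}
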