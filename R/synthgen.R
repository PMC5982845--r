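#' Synthetic thermal scene configuration
#'
#' Describes a minimal thermal "head in front of a wall" scene: an elliptical
#' warm head (skin around 34 degC) over a cooler ambient background
#' (22.3 degC), with (i) a rigid vertical oscillation of the head at the
#' cardiac frequency - the ballistocardiographic motion the heart-rate branch
#' tracks - and (ii) an additive temperature modulation inside a nostril
#' rectangle at the respiratory frequency, cold during inspiration. A frozen
#' facial speckle field gives the tracker corners to hold on to, and i.i.d.
#' Gaussian sensor noise models the camera's thermal sensitivity (NETD).
#'
#' @param rows,cols frame size in pixels.
#' @param fps frame rate (Hz); 50 matches a typical research-grade camera.
#' @param duration scene length in seconds.
#' @param ambient_c,skin_c background and skin temperature (degC).
#' @param head_center,head_axes ellipse center (row, col) and semi-axes
#'   (rows, cols) in pixels; defaults scale with the frame.
#' @param texture_sd facial speckle contrast in K before smoothing.
#' @param hr_bpm heart rate (beats/min); `hr_bpm/60` must lie in (0.65, 2) Hz.
#' @param bcg_amp_px vertical oscillation amplitude in pixels. Real head
#'   ballistocardiograms are sub-pixel at usual camera geometry, so the
#'   default exercises the tracker below 1 px.
#' @param rr_bpm respiratory rate (breaths/min); `rr_bpm/60` in (0.1, 0.85) Hz.
#' @param nostril_roi [rect_roi()] receiving the respiratory modulation; must
#'   lie inside the head ellipse. Default: a small rectangle under the
#'   ellipse center.
#' @param nostril_amp_k peak respiratory modulation in K.
#' @param noise_sd_k Gaussian sensor noise SD in K (NETD; default 0.025 K).
#' @param drift_px_per_s slow vertical posture drift in px/s.
#' @param rr_waveform `"sine"` or `"asymmetric"` (fast inspiration cooling,
#'   slow expiratory recovery); the breath-interval estimators should not
#'   depend on a sinusoidal waveform.
#' @param seed integer RNG seed; the scene is a pure function of the config.
#' @return A `scene_config` list.
#' @export
scene_config <- function(rows = 128, cols = 128, fps = 50, duration = 60,
                         ambient_c = 22.3, skin_c = 34.0,
                         head_center = NULL, head_axes = NULL,
                         texture_sd = 0.8,
                         hr_bpm = 70, bcg_amp_px = 0.3,
                         rr_bpm = 15, nostril_roi = NULL, nostril_amp_k = 0.5,
                         noise_sd_k = 0.025, drift_px_per_s = 0,
                         rr_waveform = c("sine", "asymmetric"), seed = 1) {
  rr_waveform <- match.arg(rr_waveform)
  if (is.null(head_center)) head_center <- c(rows / 2, cols / 2)
  if (is.null(head_axes)) head_axes <- c(0.34 * rows, 0.24 * cols)
  if (is.null(nostril_roi)) {
    h <- max(3L, round(0.10 * head_axes[1]))
    w <- max(4L, round(0.30 * head_axes[2]))
    nostril_roi <- rect_roi(round(head_center[1] + 0.30 * head_axes[1]),
                            round(head_center[2] - w / 2), h, w)
  }
  cfg <- list(rows = rows, cols = cols, fps = fps, duration = duration,
              ambient_c = ambient_c, skin_c = skin_c,
              head_center = head_center, head_axes = head_axes,
              texture_sd = texture_sd, hr_bpm = hr_bpm, bcg_amp_px = bcg_amp_px,
              rr_bpm = rr_bpm, nostril_roi = nostril_roi,
              nostril_amp_k = nostril_amp_k, noise_sd_k = noise_sd_k,
              drift_px_per_s = drift_px_per_s, rr_waveform = rr_waveform,
              seed = as.integer(seed))
  class(cfg) <- "scene_config"
  validate_scene_config(cfg)
  cfg
}

validate_scene_config <- function(cfg) {
  f_hr <- cfg$hr_bpm / 60
  f_rr <- cfg$rr_bpm / 60
  tv_assert(f_hr > 0.65 && f_hr < 2,
            "hr_bpm/60 must lie in the cardiac band (0.65, 2) Hz", "tv_config_error")
  tv_assert(f_rr > 0.1 && f_rr < 0.85,
            "rr_bpm/60 must lie in the respiratory band (0.1, 0.85) Hz", "tv_config_error")
  tv_assert(cfg$bcg_amp_px >= 0, "bcg_amp_px must be >= 0", "tv_config_error")
  tv_assert(cfg$noise_sd_k >= 0, "noise_sd_k must be >= 0", "tv_config_error")
  tv_assert(cfg$skin_c > cfg$ambient_c,
            "skin must be warmer than the background", "tv_config_error")
  roi_check_inside(cfg$nostril_roi, cfg$rows, cfg$cols)
  # all four nostril corners must be inside the head ellipse
  r <- c(cfg$nostril_roi$row0, cfg$nostril_roi$row0 + cfg$nostril_roi$height - 1)
  cc <- c(cfg$nostril_roi$col0, cfg$nostril_roi$col0 + cfg$nostril_roi$width - 1)
  corners <- expand.grid(r = r, c = cc)
  inside <- ((corners$r - cfg$head_center[1]) / cfg$head_axes[1])^2 +
    ((corners$c - cfg$head_center[2]) / cfg$head_axes[2])^2 <= 1
  tv_assert(all(inside), "nostril_roi must lie inside the head ellipse", "tv_config_error")
  invisible(cfg)
}

# Run `expr` under a private RNG stream, restoring the caller's state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Frozen head texture: smoothed Gaussian speckle rescaled back to `sd_k`,
# restricted to the ellipse support.
make_speckle <- function(rows, cols, sd_k, mask) {
  raw <- matrix(rnorm(rows * cols), rows, cols)
  sm <- EBImage::gblur(raw, sigma = 1.2)
  sm <- sm / sd(sm) * sd_k
  sm * mask
}

ellipse_mask <- function(rows, cols, center, axes) {
  r <- matrix(seq_len(rows) - 1, rows, cols)
  c <- matrix(seq_len(cols) - 1, rows, cols, byrow = TRUE)
  ((r - center[1]) / axes[1])^2 + ((c - center[2]) / axes[2])^2 <= 1
}

# Periodic respiratory cooling waveform in [0, 1] as a function of phase in
# [0, 1): fast rise over the first 30% of the cycle (inspiration pulls cool
# air over the skin), slow raised-cosine recovery over the rest.
asym_breath <- function(phase) {
  p <- phase - floor(phase)
  ifelse(p < 0.3,
         0.5 * (1 - cos(pi * p / 0.3)),
         0.5 * (1 + cos(pi * (p - 0.3) / 0.7)))
}

# Sample a static template shifted down by `dy` rows (content moves toward
# larger row indices), bilinear in the vertical, background fill outside.
shift_rows_bilinear <- function(template, dy, fill) {
  rows <- nrow(template)
  k <- floor(dy)
  a <- dy - k
  src0 <- seq_len(rows) - k      # frame(r) = template(r - dy)
  src1 <- src0 - 1
  padrow <- rep(fill, ncol(template))
  pick <- function(idx) {
    out <- matrix(fill, rows, ncol(template))
    ok <- idx >= 1 & idx <= rows
    out[ok, ] <- template[idx[ok], ]
    out
  }
  (1 - a) * pick(src0) + a * pick(src1)
}

#' Generate a synthetic thermal scene with known ground truth
#'
#' Renders the scene described by a [scene_config()]: static head template
#' (ellipse at skin temperature plus frozen speckle) shifted vertically by
#' `bcg_amp_px * sin(2*pi*hr_bpm/60 * t) + drift` with bilinear sub-pixel
#' interpolation, respiratory term `-nostril_amp_k * w(rr_bpm/60 * t)` added
#' inside the nostril rectangle, and Gaussian sensor noise added last.
#' Deterministic for a fixed seed.
#'
#' @param cfg a [scene_config()].
#' @return A list: `video` ([thermal_video()]), `hr_truth` and `rr_truth`
#'   (constant [rate_series()] sampled at 1 Hz), `head_mask` (the generator's
#'   own ellipse support, for segmentation tests), `config`.
#' @export
generate_scene <- function(cfg) {
  stopifnot(inherits(cfg, "scene_config"))
  validate_scene_config(cfg)
  nf <- round(cfg$duration * cfg$fps)
  tv_assert(nf >= 1, "duration too short for one frame", "tv_config_error")
  mask <- ellipse_mask(cfg$rows, cfg$cols, cfg$head_center, cfg$head_axes)
  with_seed(cfg$seed, {
    speckle <- make_speckle(cfg$rows, cfg$cols, cfg$texture_sd, mask)
    template <- matrix(cfg$ambient_c, cfg$rows, cfg$cols)
    template[mask] <- cfg$skin_c
    template <- template + speckle
    t_s <- (seq_len(nf) - 1) / cfg$fps
    dy <- cfg$bcg_amp_px * sin(2 * pi * cfg$hr_bpm / 60 * t_s) +
      cfg$drift_px_per_s * t_s
    breath <- if (cfg$rr_waveform == "sine") {
      sin(2 * pi * cfg$rr_bpm / 60 * t_s)
    } else {
      asym_breath(cfg$rr_bpm / 60 * t_s)
    }
    nr <- roi_rows(cfg$nostril_roi)
    nc <- roi_cols(cfg$nostril_roi)
    frames <- array(0, c(nf, cfg$rows, cfg$cols))
    for (t in seq_len(nf)) {
      fr <- shift_rows_bilinear(template, dy[t], cfg$ambient_c)
      fr[nr, nc] <- fr[nr, nc] - cfg$nostril_amp_k * breath[t]
      if (cfg$noise_sd_k > 0)
        fr <- fr + matrix(rnorm(cfg$rows * cfg$cols, 0, cfg$noise_sd_k),
                          cfg$rows, cfg$cols)
      frames[t, , ] <- fr
    }
    truth_t <- seq(0, cfg$duration, by = 1)
    list(video = thermal_video(frames, cfg$fps),
         hr_truth = rate_series(truth_t, rep(cfg$hr_bpm, length(truth_t)), "heart"),
         rr_truth = rate_series(truth_t, rep(cfg$rr_bpm, length(truth_t)), "respiration"),
         head_mask = mask,
         config = cfg)
  })
}

#' Two-tone test frame
#'
#' Columns with 0-based index `< split_col` at `low_c`, the rest at `high_c`;
#' a minimal fixture with an exactly known optimal threshold.
#'
#' @param rows,cols frame size.
#' @param low_c,high_c the two temperatures, `low_c < high_c`.
#' @param split_col 0-based first column of the high tone.
#' @return A numeric matrix.
#' @export
generate_two_tone <- function(rows, cols, low_c, high_c, split_col) {
  tv_assert(low_c < high_c, "low_c must be < high_c", "tv_config_error")
  m <- matrix(high_c, rows, cols)
  if (split_col > 0) m[, seq_len(min(split_col, cols))] <- low_c
  m
}
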