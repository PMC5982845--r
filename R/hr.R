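#' Heart-rate branch configuration
#'
#' Defaults follow the study conditions of the method: a 0.65-5 Hz
#' Butterworth band (wide enough to keep cardiac harmonics, which sharpen
#' the periodicity score), a fundamental search band of 0.65-2 Hz
#' (39-120 beats/min resting range), 256-sample analysis windows at 50 fps
#' strided by 1 s, the first six principal components, and exclusion of the
#' 15% largest-L2 trajectories (gross motions such as posture shifts).
#'
#' @param band filter pass band in Hz.
#' @param hr_search_band fundamental readout band in Hz, inside `band`.
#' @param window_len analysis window length in samples.
#' @param stride window stride in samples.
#' @param n_components number of leading principal components scored.
#' @param l2_exclude_frac fraction of trajectories dropped by L2 norm.
#' @param max_features corner budget for [select_features()].
#' @param prune_percentile pooled percentile for [prune_erratic()].
#' @param quality,min_dist corner selection settings.
#' @param pyramid_levels,patch tracker settings.
#' @param n_classes Otsu classes for preprocessing.
#' @return An `hr_config` list.
#' @export
hr_config <- function(band = c(0.65, 5.0), hr_search_band = c(0.65, 2.0),
                      window_len = 256, stride = 50, n_components = 6,
                      l2_exclude_frac = 0.15, max_features = 100,
                      prune_percentile = 95, quality = 0.01, min_dist = 5,
                      pyramid_levels = 3, patch = 21, n_classes = 2) {
  tv_assert(l2_exclude_frac >= 0 && l2_exclude_frac < 1,
            "l2_exclude_frac must be in [0, 1)", "tv_config_error")
  tv_assert(hr_search_band[1] >= band[1] && hr_search_band[2] <= band[2],
            "hr_search_band must lie inside the filter band", "tv_config_error")
  structure(list(band = band, hr_search_band = hr_search_band,
                 window_len = window_len, stride = stride,
                 n_components = n_components, l2_exclude_frac = l2_exclude_frac,
                 max_features = max_features, prune_percentile = prune_percentile,
                 quality = quality, min_dist = min_dist,
                 pyramid_levels = pyramid_levels, patch = patch,
                 n_classes = n_classes),
            class = "hr_config")
}

#' Principal component score series of a trajectory window
#'
#' Columns are mean-centred; the components are projections onto the top-k
#' eigenvectors of the column covariance, ordered by decreasing variance.
#' Sign convention: the largest-magnitude loading of each component is
#' positive (PCA signs are otherwise arbitrary and would break
#' reproducibility). If `k` exceeds the numerical rank, the rank-limited set
#' is returned with attribute `rank_limited = TRUE`.
#'
#' @param x matrix, `window_len x n_points`.
#' @param k number of components requested.
#' @return List: `scores` (window_len x k_eff), `loadings`, `variance`
#'   (per-component), `rank_limited`.
#' @export
pca_components <- function(x, k) {
  tv_assert(is.matrix(x) && ncol(x) >= 1, "x must be a matrix", "tv_config_error")
  xc <- sweep(x, 2, colMeans(x))
  cv <- crossprod(xc) / max(nrow(x) - 1, 1)
  eg <- eigen(cv, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  rank <- sum(ev > max(ev[1], .Machine$double.eps) * 1e-10)
  rank <- max(rank, 1L)
  k_eff <- min(k, rank, ncol(x))
  load <- eg$vectors[, seq_len(k_eff), drop = FALSE]
  for (j in seq_len(k_eff)) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) load[, j] <- -load[, j]
  }
  list(scores = xc %*% load, loadings = load, variance = ev[seq_len(k_eff)],
       rank_limited = k_eff < k)
}

#' Drop the trajectories with the largest L2 norms
#'
#' Large-norm columns correspond to gross head movements (posture changes,
#' swallowing) that would dominate the covariance; `ceil(frac * n)` of them
#' are removed before the PCA. Ties drop the higher column index.
#'
#' @param x matrix of trajectory columns.
#' @param frac fraction to drop, in `[0, 1)`.
#' @return The retained columns, with attribute `dropped` (column indices).
#' @export
exclude_high_l2 <- function(x, frac = 0.15) {
  tv_assert(ncol(x) >= 2, "need at least two columns", "tv_config_error")
  if (frac == 0) { attr(x, "dropped") <- integer(0); return(x) }
  n_drop <- ceiling(frac * ncol(x))
  norms <- sqrt(colSums(x^2))
  drop_idx <- order(-norms, -seq_len(ncol(x)))[seq_len(n_drop)]
  out <- x[, -drop_idx, drop = FALSE]
  attr(out, "dropped") <- sort(drop_idx)
  out
}

#' Select the most periodic principal component
#'
#' For each component score series: amplitude spectrum, dominant frequency
#' in the search band, and peak-to-total ratio. The component with the
#' maximal ratio wins (ties to the lower index); its dominant frequency is
#' the cardiac fundamental.
#'
#' @param components matrix with one score series per column.
#' @param fs sampling rate in Hz.
#' @param search_band fundamental search band in Hz.
#' @param pad_to FFT length for the spectra.
#' @return List: `index`, `hr_hz`, `ratio`, `ratios` (all components).
#' @export
select_component <- function(components, fs, search_band, pad_to = 4096) {
  tv_assert(is.matrix(components) && ncol(components) >= 1,
            "need at least one component", "tv_config_error")
  tv_assert(any(components != 0), "all components are zero", "tv_degenerate_error")
  ratios <- numeric(ncol(components))
  doms <- numeric(ncol(components))
  for (j in seq_len(ncol(components))) {
    if (all(components[, j] == 0)) { ratios[j] <- -Inf; next }
    sp <- amplitude_spectrum(signal_trace(components[, j], fs), pad_to = pad_to)
    doms[j] <- dominant_frequency(sp, search_band)
    ratios[j] <- peak_to_total_ratio(sp, doms[j])
  }
  best <- which.max(ratios)
  list(index = best, hr_hz = doms[best], ratio = ratios[best], ratios = ratios)
}

#' Estimate a heart-rate series from thermal video
#'
#' End-to-end cardiac branch: per-frame preprocessing (Otsu segmentation +
#' contrast stretch), Shi-Tomasi corner selection in the lower-face ROI
#' (mouth excluded), pyramidal Lucas-Kanade tracking, erratic-point pruning,
#' then for every stride-spaced 256-sample window: band-pass each vertical
#' trajectory, drop the 15% largest-L2 columns, PCA, score the first six
#' components by peak-to-total periodicity, and read the heart rate as
#' 60 times the dominant frequency of the winning component. Estimates
#' outside the 39-120 beats/min plausibility band are dropped; each kept
#' estimate is stamped at its window centre and carries its periodicity
#' ratio (attribute `ratios`) so that low-confidence output is visible.
#'
#' @param video a [thermal_video()].
#' @param roi lower-face [rect_roi()] (0-based; chosen manually, as in
#'   clinical practice for this method).
#' @param mouth_exclusion optional [rect_roi()] excluded from corner search.
#' @param cfg an [hr_config()].
#' @return A [rate_series()] of kind `"heart"` with attributes `ratios` and
#'   `component_index` per estimate.
#' @export
estimate_hr_series <- function(video, roi, mouth_exclusion = NULL,
                               cfg = hr_config()) {
  stopifnot(inherits(video, "thermal_video"))
  nf <- n_frames(video)
  tv_assert(nf >= cfg$window_len,
            sprintf("video has %d frames; need at least window_len = %d",
                    nf, cfg$window_len), "tv_degenerate_error")
  pp <- pipeline_stage("preprocess", preprocess_video(video, cfg$n_classes))
  score <- pipeline_stage("feature_scoring",
                          shi_tomasi_score_map(pp$frames[1, , ]))
  seeds <- pipeline_stage("feature_selection",
                          select_features(score, roi, mouth_exclusion,
                                          max_n = cfg$max_features,
                                          quality = cfg$quality,
                                          min_dist = cfg$min_dist))
  tracks <- pipeline_stage("tracking",
                           track_features(pp$frames, seeds, video$fps,
                                          pyramid_levels = cfg$pyramid_levels,
                                          patch = cfg$patch))
  tracks <- pipeline_stage("pruning", prune_erratic(tracks, cfg$prune_percentile))
  vt <- pipeline_stage("trajectories", vertical_trajectories(tracks))
  if (ncol(vt$mat) < 10)
    tv_stop(sprintf("stage trajectories: only %d fully tracked points (need 10)",
                    ncol(vt$mat)), "tv_pipeline_error")
  starts <- seq(1, nf - cfg$window_len + 1, by = cfg$stride)
  times <- rates <- ratios <- comp_idx <- numeric(0)
  for (s in starts) {
    win <- vt$mat[s:(s + cfg$window_len - 1), , drop = FALSE]
    filt <- apply(win, 2, function(col)
      butter_bandpass(signal_trace(col, video$fps),
                      cfg$band[1], cfg$band[2])$values)
    kept <- exclude_high_l2(filt, cfg$l2_exclude_frac)
    pca <- pca_components(kept, cfg$n_components)
    sel <- select_component(pca$scores, video$fps, cfg$hr_search_band)
    bpm <- 60 * sel$hr_hz
    if (bpm >= 39 && bpm <= 120) {
      times <- c(times, video$origin_time + (s - 1 + (cfg$window_len - 1) / 2) / video$fps)
      rates <- c(rates, bpm)
      ratios <- c(ratios, sel$ratio)
      comp_idx <- c(comp_idx, sel$index)
    }
  }
  out <- rate_series(times, rates, kind = "heart")
  attr(out, "ratios") <- ratios
  attr(out, "component_index") <- comp_idx
  out
}

# Re-raise any stage failure as a pipeline error naming the stage, keeping
# the original condition class chain for programmatic handling.
pipeline_stage <- function(stage, expr) {
  withCallingHandlers(expr, error = function(e) {
    if (inherits(e, "tv_error") && !inherits(e, "tv_pipeline_error")) {
      stop(structure(
        class = c("tv_pipeline_error", class(e)),
        list(message = sprintf("stage %s: %s", stage, conditionMessage(e)),
             call = conditionCall(e), stage = stage)))
    }
  })
}
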