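#' Shi-Tomasi cornerness map
#'
#' At every pixel, the 2x2 structure tensor of Sobel gradients is summed
#' over a square window and scored by its *smaller* eigenvalue
#' `R = min(lambda1, lambda2)` (closed form for symmetric 2x2 matrices).
#' A patch is a trackable corner only when the tensor has two large
#' eigenvalues; edges are rank-1 and score ~0. Borders within the summing
#' half-window (plus the gradient margin) score 0.
#'
#' @param image 2-D numeric matrix, typically preprocessed to `[0, 1]`.
#' @param window odd window size >= 3 for tensor summation.
#' @return Numeric matrix of non-negative scores, same size as `image`.
#' @export
shi_tomasi_score_map <- function(image, window = 5) {
  tv_assert(window >= 3 && window %% 2 == 1, "window must be odd >= 3", "tv_config_error")
  tv_assert(nrow(image) > window + 2 && ncol(image) > window + 2,
            "image smaller than scoring window", "tv_degenerate_error")
  g <- sobel_gradients(image)
  ixx <- box_sum(g$gx * g$gx, window)
  iyy <- box_sum(g$gy * g$gy, window)
  ixy <- box_sum(g$gx * g$gy, window)
  tr <- ixx + iyy
  dis <- sqrt(pmax((ixx - iyy)^2 + 4 * ixy^2, 0))
  score <- pmax((tr - dis) / 2, 0)
  hw <- (window - 1) / 2 + 1  # +1: Sobel needs one pixel of margin
  score[c(seq_len(hw), nrow(score) - seq_len(hw) + 1), ] <- 0
  score[, c(seq_len(hw), ncol(score) - seq_len(hw) + 1)] <- 0
  score
}

# Sobel x (column) and y (row) derivatives via shifted-matrix sums;
# border rows/cols are zeroed by the caller.
sobel_gradients <- function(im) {
  nr <- nrow(im); nc <- ncol(im)
  z <- matrix(0, nr, nc)
  sh <- function(dr, dc) {  # im shifted so sh(dr,dc)[r,c] = im[r+dr, c+dc]
    out <- z
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs - dr, cs - dc] <- im[rs, cs]
    out
  }
  gx <- (sh(-1, 1) + 2 * sh(0, 1) + sh(1, 1)) -
        (sh(-1, -1) + 2 * sh(0, -1) + sh(1, -1))
  gy <- (sh(1, -1) + 2 * sh(1, 0) + sh(1, 1)) -
        (sh(-1, -1) + 2 * sh(-1, 0) + sh(-1, 1))
  list(gx = gx / 8, gy = gy / 8)
}

# Sum over a centred w x w window via 2-D cumulative sums.
box_sum <- function(m, w) {
  hw <- (w - 1) / 2
  nr <- nrow(m); nc <- ncol(m)
  cs <- apply(apply(m, 2, cumsum), 1, cumsum)  # transposed cumulative table
  cs <- t(cs)
  padded <- matrix(0, nr + 1, nc + 1)
  padded[-1, -1] <- cs
  r1 <- pmax(seq_len(nr) - hw, 1); r2 <- pmin(seq_len(nr) + hw, nr)
  c1 <- pmax(seq_len(nc) - hw, 1); c2 <- pmin(seq_len(nc) + hw, nc)
  out <- matrix(0, nr, nc)
  for (c in seq_len(nc)) {
    out[, c] <- padded[cbind(r2 + 1, c2[c] + 1)] - padded[cbind(r1, c2[c] + 1)] -
      padded[cbind(r2 + 1, c1[c])] + padded[cbind(r1, c1[c])]
  }
  out
}

#' Select the strongest well-separated corners inside an ROI
#'
#' Candidates are pixels of the score map inside `roi` (minus an optional
#' mouth-exclusion rectangle: lip and jaw motion during e.g. swallowing
#' corrupts the cardiac trajectories) whose score exceeds
#' `quality * max(score in roi)`. They are ranked by score and greedily
#' thinned so that no accepted pair lies closer than `min_dist` pixels; at
#' most `max_n` points are returned.
#'
#' @param score_map matrix from [shi_tomasi_score_map()].
#' @param roi [rect_roi()] restricting the search (0-based).
#' @param exclusion optional [rect_roi()] removed from the search.
#' @param max_n maximum number of features (100 is ample for thermal faces).
#' @param quality score threshold as a fraction of the in-ROI maximum.
#' @param min_dist minimum pairwise distance in pixels.
#' @return data.frame with columns `id`, `x`, `y` (0-based pixel coords,
#'   x = column), `score`, ordered by descending score.
#' @export
select_features <- function(score_map, roi, exclusion = NULL, max_n = 100,
                            quality = 0.01, min_dist = 5) {
  roi_check_inside(roi, nrow(score_map), ncol(score_map))
  inroi <- matrix(FALSE, nrow(score_map), ncol(score_map))
  inroi[roi_rows(roi), roi_cols(roi)] <- TRUE
  if (!is.null(exclusion))
    inroi[intersect(roi_rows(exclusion), seq_len(nrow(inroi))),
          intersect(roi_cols(exclusion), seq_len(ncol(inroi)))] <- FALSE
  smax <- max(score_map[inroi], 0)
  cand <- which(inroi & score_map > quality * smax & score_map > 0, arr.ind = TRUE)
  if (nrow(cand) == 0) tv_stop("no corner candidates above quality threshold",
                               "tv_feature_error")
  sc <- score_map[cand]
  ord <- order(-sc)
  cand <- cand[ord, , drop = FALSE]
  sc <- sc[ord]
  keep_r <- numeric(0); keep_c <- numeric(0); keep_s <- numeric(0)
  for (i in seq_len(nrow(cand))) {
    r <- cand[i, 1]; c <- cand[i, 2]
    if (length(keep_r) == 0 ||
        all((keep_r - r)^2 + (keep_c - c)^2 >= min_dist^2)) {
      keep_r <- c(keep_r, r); keep_c <- c(keep_c, c); keep_s <- c(keep_s, sc[i])
      if (length(keep_r) >= max_n) break
    }
  }
  data.frame(id = seq_along(keep_r), x = keep_c - 1, y = keep_r - 1,
             score = keep_s)
}

#' Track feature points across a preprocessed frame stack
#'
#' Frame-to-frame pyramidal Lucas-Kanade refinement with sub-pixel output.
#' Seeds come from the first frame only; a point whose residual diverges or
#' that exits the frame is flagged invalid from that frame onward and is
#' never re-acquired.
#'
#' @param frames 3-D array `time x rows x cols` of preprocessed gray levels,
#'   or the list returned by [preprocess_video()].
#' @param seeds data.frame from [select_features()].
#' @param fps frame rate of the stack (Hz).
#' @param pyramid_levels,patch,max_iter,eps tracker settings: pyramid depth,
#'   odd patch size in px, Lucas-Kanade iteration cap and convergence step.
#' @return A `feature_tracks` object: `positions` (n_points x n_frames x 2,
#'   `[ , , 1]` = x, `[ , , 2]` = y, 0-based), `valid` (n_points x n_frames),
#'   `fps`, `ids`.
#' @export
track_features <- function(frames, seeds, fps, pyramid_levels = 3, patch = 21,
                           max_iter = 30, eps = 0.01) {
  if (is.list(frames) && !is.null(frames$frames)) frames <- frames$frames
  tv_assert(is.array(frames) && length(dim(frames)) == 3,
            "`frames` must be a 3-D array", "tv_config_error")
  tv_assert(nrow(seeds) >= 1, "no seed points", "tv_feature_error")
  tv_assert(patch %% 2 == 1 && patch >= 5, "patch must be odd >= 5", "tv_config_error")
  stack <- aperm(frames, c(2, 3, 1))  # frame-contiguous for the C++ core
  res <- .klt_track_cpp(stack, as.matrix(seeds[, c("x", "y")]),
                        pyramid_levels = as.integer(pyramid_levels),
                        patch = as.integer(patch),
                        max_iter = as.integer(max_iter), eps = eps)
  nf <- dim(frames)[1]
  alive_per_frame <- colSums(res$valid)
  horizon <- min(256L, nf)
  if (any(alive_per_frame[seq_len(horizon)] == 0))
    tv_stop(sprintf("all feature points lost by frame %d",
                    which(alive_per_frame == 0)[1]), "tv_tracking_error")
  structure(list(positions = res$positions, valid = res$valid, fps = fps,
                 ids = seeds$id),
            class = "feature_tracks")
}

#' Vertical (row-coordinate) trajectories of fully tracked points
#'
#' The ballistocardiographic head motion is predominantly vertical, so only
#' the row coordinate is carried forward. Points that lost tracking at any
#' frame are excluded; each retained column is mean-removed.
#'
#' @param tracks a `feature_tracks` object.
#' @return List: `mat` (n_frames x n_points matrix of centred row
#'   coordinates), `fps`, `ids` of retained points.
#' @export
vertical_trajectories <- function(tracks) {
  stopifnot(inherits(tracks, "feature_tracks"))
  full <- rowSums(!tracks$valid) == 0
  nf <- dim(tracks$positions)[2]
  y <- matrix(0, nf, sum(full))
  for (j in seq_len(sum(full)))
    y[, j] <- tracks$positions[which(full)[j], , 2]
  if (ncol(y) > 0) y <- sweep(y, 2, colMeans(y))
  list(mat = y, fps = tracks$fps, ids = tracks$ids[full])
}

#' Drop erratically moving feature points
#'
#' A point's stability is summarized by its maximum inter-frame displacement
#' magnitude; points whose maximum strictly exceeds the given percentile of
#' these pooled per-point maxima are discarded (the pooled definition keeps
#' the threshold well defined when tracks have different valid lengths, and
#' the strict comparison means identical motion never loses a point). At
#' least 10 points always survive: if pruning would go lower, the most
#' stable points are kept instead.
#'
#' @param tracks a `feature_tracks` object with >= 2 frames.
#' @param percentile pooled-displacement percentile in `[0, 100]`.
#' @return A pruned `feature_tracks` object.
#' @export
prune_erratic <- function(tracks, percentile = 95) {
  stopifnot(inherits(tracks, "feature_tracks"))
  nf <- dim(tracks$positions)[2]
  tv_assert(nf >= 2, "need at least two frames", "tv_config_error")
  dx <- tracks$positions[, -1, 1, drop = FALSE] - tracks$positions[, -nf, 1, drop = FALSE]
  dy <- tracks$positions[, -1, 2, drop = FALSE] - tracks$positions[, -nf, 2, drop = FALSE]
  disp <- sqrt(dx^2 + dy^2)[, , 1, drop = TRUE]
  if (is.null(dim(disp))) disp <- matrix(disp, nrow = dim(tracks$positions)[1])
  both_valid <- tracks$valid[, -1, drop = FALSE] & tracks$valid[, -nf, drop = FALSE]
  disp[!both_valid] <- NA
  pmax_disp <- apply(disp, 1, function(v) if (all(is.na(v))) Inf else max(v, na.rm = TRUE))
  thr <- quantile(pmax_disp[is.finite(pmax_disp)], percentile / 100, names = FALSE)
  keep <- pmax_disp <= thr
  min_keep <- min(10L, length(keep))
  if (sum(keep) < min_keep)
    keep <- rank(pmax_disp, ties.method = "first") <= min_keep
  structure(list(positions = tracks$positions[keep, , , drop = FALSE],
                 valid = tracks$valid[keep, , drop = FALSE],
                 fps = tracks$fps, ids = tracks$ids[keep]),
            class = "feature_tracks")
}
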