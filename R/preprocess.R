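#' Multilevel Otsu thresholds
#'
#' Discriminant-analysis thresholding: histogram the image into `n_bins`
#' uniform bins over its value range and exhaustively search the bin
#' boundaries whose class split maximizes the between-class variance
#' (equivalently minimizes pooled within-class variance). With the usual
#' thermogram setting - skin warmer than the room - the top class isolates
#' the head.
#'
#' @param image 2-D numeric matrix (temperatures or normalized gray levels).
#' @param n_classes number of classes, 2..4.
#' @param n_bins histogram resolution (default 256).
#' @return A `threshold_set`: list with `levels` (ascending thresholds in
#'   image units) and `n_classes`.
#' @export
multilevel_otsu <- function(image, n_classes = 2, n_bins = 256) {
  tv_assert(is.matrix(image) && all(is.finite(image)), "image must be a finite matrix",
            "tv_config_error")
  tv_assert(n_classes >= 2 && n_classes <= 4, "n_classes must be 2..4", "tv_config_error")
  rng <- range(image)
  tv_assert(rng[2] > rng[1], "constant image: thresholds undefined", "tv_degenerate_error")
  tv_assert(length(unique(as.vector(image))) >= n_classes,
            "image has fewer distinct values than classes", "tv_degenerate_error")
  bin <- pmin(floor((image - rng[1]) / (rng[2] - rng[1]) * n_bins) + 1L, n_bins)
  p <- tabulate(bin, nbins = n_bins) / length(image)
  mids <- rng[1] + (seq_len(n_bins) - 0.5) * (rng[2] - rng[1]) / n_bins
  W <- cumsum(p)                # cumulative weight up to bin k
  M <- cumsum(p * mids)         # cumulative first moment
  cuts <- best_cuts(n_classes, n_bins, W, M)
  levels <- rng[1] + cuts * (rng[2] - rng[1]) / n_bins  # upper edge of cut bin
  structure(list(levels = levels, n_classes = n_classes), class = "threshold_set")
}

# Exhaustive between-class-variance maximization. Vectorized over the last
# cut; outer cuts looped (at most 254^2 iterations for 4 classes).
best_cuts <- function(n_classes, n_bins, W, M) {
  Wa <- c(0, W)                 # Wa[k+1] = weight of bins 1..k
  Ma <- c(0, M)
  seg <- function(a, b) {       # vectorized over b
    w <- Wa[b + 1] - Wa[a + 1]
    m <- Ma[b + 1] - Ma[a + 1]
    out <- numeric(length(b))
    pos <- w > 0
    out[pos] <- (m[pos]^2) / w[pos]
    out
  }
  if (n_classes == 2) {
    k <- seq_len(n_bins - 1)
    score <- seg(0, k) + seg(k, n_bins)
    return(k[which.max(score)])
  }
  if (n_classes == 3) {
    best <- -Inf; best_cuts <- NULL
    for (k1 in seq_len(n_bins - 2)) {
      k2 <- seq.int(k1 + 1, n_bins - 1)
      score <- seg(0, k1) + seg(k1, k2) + seg(k2, n_bins)
      i <- which.max(score)
      if (score[i] > best) { best <- score[i]; best_cuts <- c(k1, k2[i]) }
    }
    return(best_cuts)
  }
  best <- -Inf; best_cuts <- NULL
  for (k1 in seq_len(n_bins - 3)) {
    s1 <- seg(0, k1)
    for (k2 in seq.int(k1 + 1, n_bins - 2)) {
      k3 <- seq.int(k2 + 1, n_bins - 1)
      score <- s1 + seg(k1, k2) + seg(k2, k3) + seg(k3, n_bins)
      i <- which.max(score)
      if (score[i] > best) { best <- score[i]; best_cuts <- c(k1, k2, k3[i]) }
    }
  }
  best_cuts
}

#' Segment the head from the background
#'
#' Pixels above the top Otsu threshold, cleaned up by keeping the largest
#' connected component and filling its holes. The cleanup goes beyond bare
#' thresholding: isolated warm speckles would otherwise seed corner
#' detection on the background.
#'
#' @param frame 2-D numeric matrix.
#' @param thresholds a `threshold_set` from [multilevel_otsu()].
#' @return Logical matrix head mask.
#' @export
segment_head <- function(frame, thresholds) {
  stopifnot(inherits(thresholds, "threshold_set"))
  mask <- frame > max(thresholds$levels)
  if (!any(mask)) tv_stop("segmentation produced an empty mask", "tv_segmentation_error")
  lab <- EBImage::bwlabel(matrix(as.integer(mask), nrow(frame), ncol(frame)))
  counts <- tabulate(lab[lab > 0])
  keep <- which.max(counts)
  comp <- matrix(as.integer(lab == keep), nrow(frame), ncol(frame))
  filled <- EBImage::fillHull(comp)
  matrix(filled > 0, nrow(frame), ncol(frame))
}

#' Percentile-based linear contrast stretch inside a mask
#'
#' Gray levels at or below the `lo_pct` percentile of the in-mask pixels map
#' to 0, at or above `hi_pct` to 1, linearly in between; everything outside
#' the mask is set to 0 (background subtraction).
#'
#' @param frame 2-D numeric matrix.
#' @param mask logical matrix of the same size.
#' @param lo_pct,hi_pct percentiles in `[0, 100]`, `lo_pct < hi_pct`.
#' @param bounds_mask optional logical matrix over which the percentiles are
#'   computed (default: `mask` itself). Passing an eroded mask keeps the
#'   mapping stable over time: pixels on the face boundary are sub-pixel
#'   blends of skin and background whose in-and-out flicker would otherwise
#'   wobble the low percentile from frame to frame.
#' @return Numeric matrix in `[0, 1]`.
#' @export
contrast_stretch <- function(frame, mask, lo_pct = 1, hi_pct = 99,
                             bounds_mask = NULL) {
  tv_assert(lo_pct < hi_pct, "lo_pct must be < hi_pct", "tv_config_error")
  tv_assert(any(mask), "empty mask", "tv_degenerate_error")
  if (is.null(bounds_mask) || !any(bounds_mask)) bounds_mask <- mask
  q <- quantile(frame[bounds_mask], c(lo_pct, hi_pct) / 100, names = FALSE)
  tv_assert(q[2] > q[1], "zero in-mask dynamic range", "tv_degenerate_error")
  out <- (frame - q[1]) / (q[2] - q[1])
  out[out < 0] <- 0
  out[out > 1] <- 1
  out[!mask] <- 0
  out
}

#' Preprocess every frame of a thermal video
#'
#' Per frame: multilevel Otsu re-threshold, head segmentation, and in-mask
#' contrast stretch with background zeroed. Re-thresholding each thermogram
#' makes the pipeline invariant to slow global temperature offsets.
#'
#' @param video a [thermal_video()].
#' @param n_classes Otsu classes (default 2).
#' @param lo_pct,hi_pct stretch percentiles.
#' @param bounds_erosion diameter in px of the disc by which the mask is
#'   eroded before computing the stretch percentiles (0 disables). The
#'   stretch still covers, and the zeroing still uses, the full mask; only
#'   the percentile population is restricted to the face interior, away
#'   from boundary pixels that blend skin and background.
#' @return List: `frames` (3-D array of stretched frames in `[0,1]`),
#'   `first_mask` (head mask of frame 1).
#' @export
preprocess_video <- function(video, n_classes = 2, lo_pct = 1, hi_pct = 99,
                             bounds_erosion = 7) {
  stopifnot(inherits(video, "thermal_video"))
  nf <- n_frames(video)
  out <- array(0, dim(video$frames))
  first_mask <- NULL
  brush <- if (bounds_erosion >= 2) EBImage::makeBrush(bounds_erosion, "disc")
  for (t in seq_len(nf)) {
    fr <- video$frames[t, , ]
    th <- multilevel_otsu(fr, n_classes = n_classes)
    mask <- segment_head(fr, th)
    bmask <- if (!is.null(brush))
      EBImage::erode(matrix(as.integer(mask), nrow(fr)), brush) > 0
    out[t, , ] <- contrast_stretch(fr, mask, lo_pct, hi_pct, bounds_mask = bmask)
    if (t == 1L) first_mask <- mask
  }
  list(frames = out, first_mask = first_mask)
}
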