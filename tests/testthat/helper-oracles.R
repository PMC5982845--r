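# Independent brute-force oracles, written as literal loops so they share no
# code path with the implementation they check.

# Multilevel Otsu oracle: exhaustive search over all cut combinations of a
# uniform n_bins histogram, maximizing between-class variance computed from
# first principles.
brute_otsu <- function(image, n_classes, n_bins = 64) {
  rng <- range(image)
  bin <- pmin(floor((image - rng[1]) / (rng[2] - rng[1]) * n_bins) + 1L, n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  mids <- rng[1] + (seq_len(n_bins) - 0.5) * (rng[2] - rng[1]) / n_bins
  total <- sum(counts)
  mu_total <- sum(counts * mids) / total
  bcv <- function(cuts) {
    edges <- c(0, cuts, n_bins)
    v <- 0
    for (k in seq_len(length(edges) - 1)) {
      sel <- (edges[k] + 1):edges[k + 1]
      w <- sum(counts[sel]) / total
      if (w > 0) {
        mu <- sum(counts[sel] * mids[sel]) / sum(counts[sel])
        v <- v + w * (mu - mu_total)^2
      }
    }
    v
  }
  best <- -Inf
  best_cuts <- NULL
  combos <- utils::combn(n_bins - 1, n_classes - 1)
  for (j in seq_len(ncol(combos))) {
    v <- bcv(combos[, j])
    if (v > best) {
      best <- v
      best_cuts <- combos[, j]
    }
  }
  rng[1] + best_cuts * (rng[2] - rng[1]) / n_bins
}

# Literal transcriptions of the three interval estimators: w[v] indexed
# around the window centre, sums written as explicit loops.
brute_ac <- function(window, m) {
  ctr <- (length(window) + 1) / 2
  s <- 0
  for (v in 0:m) s <- s + window[ctr + v] * window[ctr + v - m]
  s / m
}

brute_amdf <- function(window, m) {
  ctr <- (length(window) + 1) / 2
  s <- 0
  for (v in 0:m) s <- s + abs(window[ctr + v] - window[ctr + v - m])
  1 / (s / m + 1e-12)
}

brute_map <- function(window, m) {
  ctr <- (length(window) + 1) / 2
  best <- -Inf
  for (v in 0:m) {
    val <- window[ctr + v] + window[ctr + v - m]
    if (val > best) best <- val
  }
  best
}

# Shi-Tomasi oracle at one pixel: Sobel gradients by literal convolution,
# structure tensor summed over the window, smaller eigenvalue via eigen().
brute_min_eig <- function(image, r, c, window = 5) {
  hw <- (window - 1) / 2
  sobel_x <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3) / 8
  sobel_y <- t(sobel_x)
  gxx <- gyy <- gxy <- 0
  for (dr in -hw:hw) for (dc in -hw:hw) {
    gx <- gy <- 0
    for (kr in -1:1) for (kc in -1:1) {
      v <- image[r + dr + kr, c + dc + kc]
      gx <- gx + v * sobel_x[kr + 2, kc + 2]
      gy <- gy + v * sobel_y[kr + 2, kc + 2]
    }
    gxx <- gxx + gx * gx
    gyy <- gyy + gy * gy
    gxy <- gxy + gx * gy
  }
  min(eigen(matrix(c(gxx, gxy, gxy, gyy), 2, 2), symmetric = TRUE)$values)
}

# Shared synthetic fixtures, built once per test run.
.scene_cache <- new.env(parent = emptyenv())

cached_scene <- function(key, ...) {
  if (is.null(.scene_cache[[key]]))
    .scene_cache[[key]] <- generate_scene(scene_config(...))
  .scene_cache[[key]]
}

# small default face ROIs for the 64 x 64 test scenes
test_face_roi <- function() rect_roi(32, 12, 24, 40)
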