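#' Zero-phase Butterworth band-pass filter
#'
#' Designs a Butterworth band-pass (3 dB corners at `f_lo`, `f_hi`) and
#' applies it forward and backward, so the net response is the squared
#' magnitude with zero phase: signals compared across channels and windows
#' keep their relative timing, at the cost of the corner gain becoming
#' 0.5 rather than 1/sqrt(2). Edge transients are handled by odd-reflection
#' padding sized to the slowest passband period.
#'
#' @param trace a [signal_trace()].
#' @param f_lo,f_hi 3 dB corner frequencies in Hz, `0 < f_lo < f_hi < fs/2`.
#' @param order filter order per pass (default 2).
#' @return A filtered [signal_trace()] of equal length.
#' @export
butter_bandpass <- function(trace, f_lo, f_hi, order = 2) {
  stopifnot(inherits(trace, "signal_trace"))
  fs <- trace$fs
  tv_assert(f_lo > 0 && f_lo < f_hi, "need 0 < f_lo < f_hi", "tv_config_error")
  tv_assert(f_hi < fs / 2, "upper corner must be below Nyquist", "tv_config_error")
  n <- length(trace$values)
  settle <- fs / (2 * pi * f_lo)  # impulse-response decay constant, samples
  tv_assert(n > 3 * settle,
            sprintf("trace too short (%d samples) for a %.3g Hz lower corner", n, f_lo),
            "tv_degenerate_error")
  flt <- signal::butter(order, c(f_lo, f_hi) / (fs / 2), type = "pass")
  pad <- min(n - 1, max(ceiling(3 * settle), 12))
  # remove the mean first: the pass band rejects DC anyway, and demeaning
  # kills the DC step transient that padding alone only attenuates
  x <- trace$values - mean(trace$values)
  # odd reflection about the end points suppresses the start-up transient
  left <- 2 * x[1] - x[seq(pad + 1, 2)]
  right <- 2 * x[n] - x[seq(n - 1, n - pad)]
  xp <- c(left, x, right)
  y <- signal::filter(flt$b, flt$a, xp)
  y <- rev(signal::filter(flt$b, flt$a, rev(y)))
  signal_trace(y[seq(pad + 1, pad + n)], fs = fs, t0 = trace$t0)
}

#' Amplitude spectrum of a short analysis window
#'
#' Hann taper, zero-padding to `pad_to` samples and FFT magnitude on the
#' non-negative frequency grid. With 256-sample windows at 50 Hz the raw
#' bin width (~0.2 Hz, i.e. ~12 beats/min) is far too coarse for bpm-level
#' readout, hence the interpolation by zero-padding.
#'
#' @param trace a [signal_trace()] with at least 2 samples.
#' @param pad_to FFT length (the window is zero-padded up to it; longer
#'   windows use their own length).
#' @return A `spectrum_1d` object: `freqs` (Hz, 0..fs/2), `amps`, `fs`,
#'   `nfft`.
#' @export
amplitude_spectrum <- function(trace, pad_to = 4096) {
  stopifnot(inherits(trace, "signal_trace"))
  x <- trace$values
  n <- length(x)
  tv_assert(n >= 2, "window too short for a spectrum", "tv_degenerate_error")
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  nfft <- max(pad_to, n)
  xw <- c(x * w, rep(0, nfft - n))
  X <- fft(xw)
  k <- 0:(floor(nfft / 2))
  structure(list(freqs = k * trace$fs / nfft, amps = Mod(X[k + 1]),
                 fs = trace$fs, nfft = nfft, n = n),
            class = "spectrum_1d")
}

#' Dominant frequency within a band
#'
#' Argmax of the amplitude spectrum restricted to `band`, refined by
#' three-point parabolic interpolation around the peak bin; exact ties go to
#' the lower frequency.
#'
#' @param spec a `spectrum_1d` from [amplitude_spectrum()].
#' @param band `c(f_min, f_max)` in Hz; must intersect the grid.
#' @return Frequency in Hz.
#' @export
dominant_frequency <- function(spec, band) {
  stopifnot(inherits(spec, "spectrum_1d"))
  idx <- which(spec$freqs >= band[1] & spec$freqs <= band[2])
  tv_assert(length(idx) > 0, "band contains no spectral bins", "tv_config_error")
  i <- idx[which.max(spec$amps[idx])]
  f <- spec$freqs[i]
  df <- spec$fs / spec$nfft
  if (i > 1 && i < length(spec$amps)) {
    a <- spec$amps[i - 1]; b <- spec$amps[i]; c <- spec$amps[i + 1]
    # refine only around a strict local maximum; on an exact tie the
    # unrefined (lower-frequency) bin stands
    if (a < b && c < b) {
      delta <- 0.5 * (a - c) / (a - 2 * b + c)
      delta <- max(min(delta, 0.5), -0.5)
      f <- f + delta * df
    }
  }
  f
}

#' Peak-to-total spectral power ratio
#'
#' Periodicity score: the fraction of total spectral power lying within
#' `half_width` of the dominant frequency or of its first harmonic (bands
#' clipped at Nyquist). Power is squared amplitude. A clean periodic signal
#' scores near 1; broadband noise scores near the bandwidth fraction.
#'
#' @param spec a `spectrum_1d`.
#' @param f_dom dominant frequency in Hz.
#' @param half_width half-width of each band in Hz (default 0.05).
#' @return Ratio in `[0, 1]`.
#' @export
peak_to_total_ratio <- function(spec, f_dom, half_width = 0.05) {
  stopifnot(inherits(spec, "spectrum_1d"))
  power <- spec$amps^2
  total <- sum(power)
  tv_assert(total > 0, "zero total spectral power", "tv_degenerate_error")
  sel <- abs(spec$freqs - f_dom) <= half_width |
    abs(spec$freqs - 2 * f_dom) <= half_width
  sum(power[sel]) / total
}
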