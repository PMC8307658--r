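# Stationary (undecimated) wavelet transform, implemented with circular
# convolution in the FFT domain. At level j the analysis filters are the
# base quadrature-mirror pair upsampled by 2^(j-1) (the "a trous" scheme);
# because |H(w)|^2 + |G(w)|^2 = 2 for an orthonormal pair, the adjoint
# (correlation) filters reconstruct perfectly with a factor 1/2 per level.

# 8-tap Daubechies filters (4 vanishing moments), unit-norm lowpass.
.db4_dec_lo <- c(-0.010597401785069032, 0.0328830116668852,
                 0.030841381835560764, -0.18703481171909309,
                 -0.027983769416859854, 0.6308807679298589,
                 0.7148465705529157, 0.2303778133088965)
.db4_dec_hi <- c(-0.2303778133088965, 0.7148465705529157,
                 -0.6308807679298589, -0.027983769416859854,
                 0.18703481171909309, 0.030841381835560764,
                 -0.0328830116668852, -0.010597401785069032)

.swt_filters <- function(wavelet) {
  if (!identical(wavelet, "db4"))
    stop("only the db4 wavelet is implemented")
  list(lo = .db4_dec_lo, hi = .db4_dec_hi)
}

# Frequency response of filter h upsampled by `up`, at the N DFT bins.
.filter_dft <- function(h, up, N) {
  omega <- 2 * pi * (seq_len(N) - 1) / N
  resp <- complex(length.out = N, real = 0)
  for (m in seq_along(h))
    resp <- resp + h[m] * exp(-1i * omega * up * (m - 1))
  resp
}

#' Stationary wavelet decomposition
#'
#' Decomposes a signal whose length is a multiple of `2^levels` into
#' per-level detail sequences `d1..dL` and a final approximation, all at the
#' input length (undecimated transform, periodic boundary).
#'
#' @param x Numeric vector; `length(x)` must be divisible by `2^levels`.
#' @param levels Number of decomposition levels.
#' @param wavelet Mother wavelet name (`"db4"`).
#' @return A list of class `"swt_decomposition"` with elements `details`
#'   (list of numeric vectors d1..dL), `approximation`, `levels`, `wavelet`
#'   and `n`.
#' @export
swt_decompose <- function(x, levels, wavelet = "db4") {
  N <- length(x)
  if (N %% 2^levels != 0)
    stop("signal length ", N, " is not divisible by 2^levels = ", 2^levels)
  filt <- .swt_filters(wavelet)
  A <- stats::fft(x)
  details <- vector("list", levels)
  for (j in seq_len(levels)) {
    up <- 2^(j - 1)
    H <- .filter_dft(filt$lo, up, N)
    G <- .filter_dft(filt$hi, up, N)
    details[[j]] <- Re(stats::fft(A * G, inverse = TRUE)) / N
    A <- A * H
  }
  structure(list(details = details,
                 approximation = Re(stats::fft(A, inverse = TRUE)) / N,
                 levels = levels, wavelet = wavelet, n = N),
            class = "swt_decomposition")
}

#' Stationary wavelet reconstruction
#'
#' Inverts [swt_decompose()] using the adjoint filters. Reconstructing from
#' unmodified coefficients reproduces the input to near machine precision;
#' detail levels or the approximation may be zeroed or thresholded first.
#'
#' @param dec An `"swt_decomposition"`, possibly with modified coefficients.
#' @return Numeric vector of length `dec$n`.
#' @export
swt_reconstruct <- function(dec) {
  stopifnot(inherits(dec, "swt_decomposition"))
  filt <- .swt_filters(dec$wavelet)
  N <- dec$n
  A <- stats::fft(dec$approximation)
  for (j in rev(seq_len(dec$levels))) {
    up <- 2^(j - 1)
    H <- .filter_dft(filt$lo, up, N)
    G <- .filter_dft(filt$hi, up, N)
    D <- stats::fft(dec$details[[j]])
    A <- (Conj(H) * A + Conj(G) * D) / 2
  }
  Re(stats::fft(A, inverse = TRUE)) / N
}

#' Dyadic analysis band of an SWT detail level
#'
#' Detail level `k` of an undecimated dyadic wavelet transform occupies the
#' band from `fs / 2^(k+1)` to `fs / 2^k`.
#'
#' @param fs Sampling rate in Hz.
#' @param level Detail level (>= 1).
#' @return Numeric pair `(low, high)` in Hz.
#' @examples
#' swt_band_edges(250, 3)  # c(15.625, 31.25)
#' @export
swt_band_edges <- function(fs, level) {
  stopifnot(fs > 0, level >= 1)
  c(fs / 2^(level + 1), fs / 2^level)
}

# Symmetric padding of x up to a multiple of 2^levels; returns the padded
# vector and the index range of the original samples.
.swt_pad <- function(x, levels) {
  N <- length(x)
  target <- ceiling(N / 2^levels) * 2^levels
  extra <- target - N
  left <- extra %/% 2
  right <- extra - left
  if (left > N || right > N)
    stop("validation error: signal too short for ", levels, "-level SWT")
  xp <- c(if (left) rev(x[seq_len(left)]) else numeric(0),
          x,
          if (right) rev(x[seq.int(N - right + 1, N)]) else numeric(0))
  list(x = xp, idx = seq.int(left + 1, left + N))
}

# Universal soft threshold sigma * sqrt(2 log N). The noise sd is the MAD
# estimate from the finest detail level (d1), which carries essentially no
# signal for band-limited physiological content; a per-level MAD would
# measure an oscillatory component itself and zero it out entirely.
.soft_threshold <- function(d, thr) sign(d) * pmax(abs(d) - thr, 0)

.noise_sigma <- function(d1) stats::median(abs(d1)) / 0.6745

# Full denoising record: reconstructed signal plus the thresholded detail
# sequences (cropped to the input length), which the feature battery reuses.
.swt_denoise_full <- function(x, levels, keep, wavelet = "db4",
                              threshold = c("universal", "none")) {
  threshold <- match.arg(threshold)
  if (!all(keep %in% seq_len(levels)))
    stop("keep levels must lie within 1..levels")
  if (length(x) < 2^levels)
    stop("validation error: signal too short for ", levels, "-level SWT")
  pad <- .swt_pad(x, levels)
  dec <- swt_decompose(pad$x, levels, wavelet)
  Np <- length(pad$x)
  thr <- .noise_sigma(dec$details[[1]]) * sqrt(2 * log(Np))
  for (j in seq_len(levels)) {
    if (j %in% keep) {
      if (threshold == "universal")
        dec$details[[j]] <- .soft_threshold(dec$details[[j]], thr)
    } else {
      dec$details[[j]] <- numeric(Np)
    }
  }
  dec$approximation <- numeric(Np)
  y <- swt_reconstruct(dec)
  details <- lapply(dec$details, function(d) d[pad$idx])
  list(signal = y[pad$idx], details = details, levels = levels, keep = keep)
}

#' Wavelet denoising by soft-thresholded detail reconstruction
#'
#' Pads the signal symmetrically to a multiple of `2^levels`, applies the
#' stationary wavelet transform, soft-thresholds the detail levels in
#' `keep` (per-level universal threshold with a MAD noise estimate), zeroes
#' every other level and the approximation, reconstructs and crops back to
#' the input length. With `keep = 3:8` at 250 Hz this retains roughly
#' 0.5--31.25 Hz (the ECG band); with `keep = 5:7`, roughly 1--8 Hz (the
#' ICC band).
#'
#' @param x Numeric vector.
#' @param fs Sampling rate in Hz (recorded for reference; the band split is
#'   dyadic in the sample domain).
#' @param levels Number of SWT levels.
#' @param keep Integer set of detail levels to retain.
#' @param wavelet Mother wavelet name.
#' @param threshold `"universal"` (default) or `"none"` (band selection only).
#' @return Denoised numeric vector, same length as `x`.
#' @export
swt_denoise <- function(x, fs, levels = 8, keep = 3:8, wavelet = "db4",
                        threshold = c("universal", "none")) {
  .swt_denoise_full(x, levels, keep, wavelet, match.arg(threshold))$signal
}
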