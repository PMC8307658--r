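# QRS detection on the denoised ECG, Hamilton-Tompkins style:
# bandpass -> differentiate -> rectify -> moving-window integrate ->
# adaptive dual thresholds with search-back, plus a refractory period.
# The detector works on relative amplitudes only, so it is invariant to
# rescaling the input.

#' Detect R-peaks in a (denoised) ECG
#'
#' @param ecg Numeric vector, ECG in mV (ideally the SWT-denoised signal).
#' @param fs Sampling rate in Hz.
#' @param refractory_ms Minimum distance between detections, ms.
#' @param band Detector pre-filter passband in Hz.
#' @return Integer vector of R-peak sample indices (1-based, ascending);
#'   empty when no QRS-like activity is found.
#' @export
detect_qrs <- function(ecg, fs, refractory_ms = 200, band = c(8, 16)) {
  N <- length(ecg)
  if (N < 2 * fs) stop("validation error: need at least 2 s of signal")
  if (all(ecg == 0) || stats::sd(ecg) == 0) return(integer(0))

  bf <- signal::butter(3, band / (fs / 2), type = "pass")
  y <- as.numeric(signal::filtfilt(bf, ecg))
  d <- c(0, diff(y))
  e <- abs(d)
  w <- max(1L, round(0.080 * fs))
  m <- as.numeric(stats::filter(e, rep(1 / w, w), sides = 2))
  m[is.na(m)] <- 0

  refr <- max(1L, round(refractory_ms / 1000 * fs))
  # candidate local maxima of the integrated signal
  peaks <- which(diff(sign(diff(m))) < 0) + 1L
  if (!length(peaks)) return(integer(0))

  spk <- max(m[seq_len(min(N, 2 * fs))]) * 0.5  # running signal-peak level
  npk <- mean(m[seq_len(min(N, 2 * fs))]) * 0.5 # running noise-peak level
  thr <- function() npk + 0.3125 * (spk - npk)

  det <- integer(0)
  rr_avg <- NA_real_
  last_considered <- integer(0)
  for (p in peaks) {
    if (length(det) && (p - det[length(det)]) < refr) next
    if (m[p] >= thr()) {
      det <- c(det, p)
      spk <- 0.875 * spk + 0.125 * m[p]
      if (length(det) >= 2) {
        rr <- diff(det)
        rr_avg <- mean(utils::tail(rr, 8))
      }
    } else {
      npk <- 0.875 * npk + 0.125 * m[p]
      last_considered <- c(last_considered, p)
      # search-back: if a beat is overdue, accept the best sub-threshold
      # candidate above half the threshold
      if (length(det) && !is.na(rr_avg) &&
          (p - det[length(det)]) > 1.5 * rr_avg) {
        cand <- last_considered[last_considered > det[length(det)] + refr]
        if (length(cand)) {
          best <- cand[which.max(m[cand])]
          if (m[best] > 0.5 * thr()) {
            det <- sort(c(det, best))
            spk <- 0.875 * spk + 0.125 * m[best]
            last_considered <- integer(0)
          }
        }
      }
    }
  }
  if (!length(det)) return(integer(0))

  # refine each detection to the absolute ECG maximum nearby (the MWI peak
  # lags the R wave by roughly the integration window)
  half <- round(0.100 * fs)
  ref <- vapply(det, function(p) {
    lo <- max(1L, p - half); hi <- min(N, p + half)
    as.integer(lo + which.max(abs(ecg[lo:hi])) - 1L)
  }, integer(1))
  ref <- sort(unique(ref))
  # enforce refractory period after refinement
  keep <- logical(length(ref))
  last <- -Inf
  for (i in seq_along(ref)) {
    if (ref[i] - last >= refr) {
      keep[i] <- TRUE
      last <- ref[i]
    }
  }
  ref[keep]
}

#' Instantaneous heart rate as a normalized frequency
#'
#' Converts R-peak indices into the per-sample instantaneous heart rate
#' `f(n)`, expressed in cycles/sample so that the phase `2*pi*f(n)*n` of
#' the Fourier-series circulation model is dimensionless. Between
#' consecutive peaks `r_i` and `r_{i+1}` the value is `1/(r_{i+1}-r_i)`;
#' before the first peak the first interval's value is held, and from the
#' last peak onward the last interval's value is held.
#'
#' @param r_peaks Integer vector of R-peak sample indices (ascending, >= 2).
#' @param fs Sampling rate in Hz (for the bpm conversion in summaries).
#' @param n_samples Length of the output sequence.
#' @return Numeric vector of length `n_samples`, cycles/sample.
#' @export
instantaneous_hr <- function(r_peaks, fs, n_samples) {
  if (length(r_peaks) < 2)
    stop(structure(class = c("pea_hr_undefined", "error", "condition"),
                   list(message = "HR undefined: fewer than 2 R-peaks",
                        call = sys.call(-1))))
  if (is.unsorted(r_peaks, strictly = TRUE))
    stop("r_peaks must be strictly increasing")
  f <- numeric(n_samples)
  iv <- 1 / diff(r_peaks)           # cycles/sample per RR interval
  for (i in seq_along(iv)) {
    lo <- max(1L, r_peaks[i])
    hi <- min(n_samples, r_peaks[i + 1] - 1L)
    if (lo <= hi) f[lo:hi] <- iv[i]
  }
  first <- min(r_peaks[1], n_samples)
  if (first > 1) f[seq_len(first - 1)] <- iv[1]
  lastp <- r_peaks[length(r_peaks)]
  if (lastp <= n_samples) f[lastp:n_samples] <- iv[length(iv)]
  f[f == 0] <- iv[length(iv)]  # guard for peaks beyond n_samples
  f
}
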