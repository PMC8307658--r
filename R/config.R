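#' Pipeline configuration
#'
#' Bundles every tunable parameter of the faPEA/unPEA pipeline: the
#' stationary-wavelet denoising setup for the ECG and the impedance
#' circulation component (ICC), the thoracic-impedance bandpass, the QRS
#' detector constants, the Kalman smoother configuration and the feature
#' parameters. Defaults follow the published configuration of the method;
#' all are exposed so deviations are explicit.
#'
#' @param fs Target sampling rate in Hz. Segments are canonicalized to this
#'   rate on load.
#' @param duration_s Segment duration in seconds.
#' @param swt_levels Number of stationary wavelet transform levels.
#' @param swt_wavelet Mother wavelet; only `"db4"` (8-tap Daubechies, 4
#'   vanishing moments) is built in.
#' @param ecg_keep Detail levels retained when denoising the ECG
#'   (d3--d8 spans roughly 0.5--31.25 Hz at 250 Hz).
#' @param icc_keep Detail levels retained when denoising the ICC
#'   (d5--d7 spans roughly 1--8 Hz at 250 Hz).
#' @param ti_band Passband in Hz for the thoracic-impedance bandpass.
#' @param kalman List with elements `K` (harmonics), `lambda` (state decay
#'   rate, 1/s), `sigma` (process-noise sd), `r_obs` (observation-noise
#'   variance; `NULL` means estimate per segment from the first difference
#'   of the filtered TI), `p0_scale` (initial state covariance scale;
#'   `NULL` means the variance of the filtered TI).
#' @param qrs List with `refractory_ms` (detector refractory period) and
#'   `band` (detector pre-filter passband in Hz).
#' @param features List of feature parameters: `amsa_band` (Hz), `amsa_tukey`
#'   (Tukey taper fraction), `highpower_band` (Hz), `fuzzen_m`, `fuzzen_r_sd`
#'   (tolerance as a fraction of the sd), `fuzzen_n` (fuzzy exponent),
#'   `sneo_window_ms`, `burg_order`, `crosspower_band` (Hz),
#'   `crosspower_window_s` (Welch sub-window length, seconds).
#' @return An object of class `"pea_config"` (a named list).
#' @export
pea_config <- function(fs = 250,
                       duration_s = 5,
                       swt_levels = 8,
                       swt_wavelet = "db4",
                       ecg_keep = 3:8,
                       icc_keep = 5:7,
                       ti_band = c(0.8, 10),
                       kalman = list(K = 5, lambda = 0.05, sigma = 0.01,
                                     r_obs = NULL, p0_scale = NULL),
                       qrs = list(refractory_ms = 200, band = c(8, 16)),
                       features = list(amsa_band = c(2, 30),
                                       amsa_tukey = 0.1,
                                       highpower_band = c(17.5, 40),
                                       fuzzen_m = 2,
                                       fuzzen_r_sd = 0.2,
                                       fuzzen_n = 2,
                                       sneo_window_ms = 50,
                                       burg_order = 4,
                                       crosspower_band = c(1, 8),
                                       crosspower_window_s = 1)) {
  stopifnot(fs > 0, duration_s > 0, swt_levels >= 1)
  if (!all(ecg_keep %in% seq_len(swt_levels)))
    stop("ecg_keep levels must lie within 1..swt_levels")
  if (!all(icc_keep %in% seq_len(swt_levels)))
    stop("icc_keep levels must lie within 1..swt_levels")
  if (!(length(ti_band) == 2 && ti_band[1] > 0 && ti_band[1] < ti_band[2] &&
        ti_band[2] < fs / 2))
    stop("ti_band must satisfy 0 < low < high < fs/2")
  stopifnot(kalman$K >= 1, kalman$lambda > 0, kalman$sigma > 0)
  cfg <- list(fs = fs, duration_s = duration_s, n_samples = round(fs * duration_s),
              swt_levels = swt_levels, swt_wavelet = swt_wavelet,
              ecg_keep = ecg_keep, icc_keep = icc_keep, ti_band = ti_band,
              kalman = kalman, qrs = qrs, features = features)
  class(cfg) <- "pea_config"
  cfg
}

#' @export
print.pea_config <- function(x, ...) {
  cat("faPEA/unPEA pipeline configuration\n")
  cat(sprintf("  fs = %g Hz, segment = %g s (%d samples)\n",
              x$fs, x$duration_s, x$n_samples))
  cat(sprintf("  SWT: %d levels, %s; ECG keeps d%s, ICC keeps d%s\n",
              x$swt_levels, x$swt_wavelet,
              paste(range(x$ecg_keep), collapse = "-"),
              paste(range(x$icc_keep), collapse = "-")))
  cat(sprintf("  TI bandpass: %g-%g Hz\n", x$ti_band[1], x$ti_band[2]))
  cat(sprintf("  Kalman: K = %d, lambda = %g, sigma = %g\n",
              x$kalman$K, x$kalman$lambda, x$kalman$sigma))
  invisible(x)
}
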