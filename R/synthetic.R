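# Synthetic faPEA/unPEA segment generator. Emulates the structure the
# pipeline assumes: organized QRS activity at a class-dependent heart rate
# and amplitude, a thoracic-impedance circulation component phase-locked to
# the heartbeats (strong in faPEA, weak or absent in unPEA), baseline
# wander, a respiration oscillation and broadband noise. It is the
# package's test bed: the clinical recordings the method was developed on
# are not redistributable.

#' Parameters of the synthetic segment generator
#'
#' Per-class entries are named vectors/lists with elements `faPEA` and
#' `unPEA`. Defaults encode the contrasts the pipeline is designed to
#' exploit: faPEA segments have larger, narrower QRS complexes at higher
#' heart rate and carry a heartbeat-locked impedance circulation component
#' (ICC) an order of magnitude stronger than unPEA.
#'
#' @param n_patients Patients per class, named `c(faPEA=, unPEA=)`.
#' @param segments_per_patient Inclusive integer range per class
#'   (list of length-2 vectors).
#' @param hr_bpm Heart-rate range in bpm per class (within 20--200).
#' @param ecg_amp_mV R-wave amplitude scale per class, mV.
#' @param qrs_width_ms QRS width range per class, ms.
#' @param icc_amp_mohm ICC amplitude scale per class, m-ohm (unPEA may be 0).
#' @param icc_harmonics Number of harmonics in the ICC ground truth.
#' @param coeff_lambda Decay rate (1/s) of the AR(1) modulation of the ICC
#'   Fourier coefficients; matches the smoother's state-decay prior.
#' @param coeff_mod_sd Relative sd of the AR(1) coefficient modulation.
#' @param baseline_wander_amp m-ohm amplitude of the slow TI drift.
#' @param baseline_wander_hz Frequency of the drift, Hz.
#' @param resp_rate_hz Respiration-like oscillation frequency, Hz.
#' @param resp_amp_mohm Respiration oscillation amplitude, m-ohm.
#' @param noise_sd_ecg Additive Gaussian noise sd on the ECG, mV.
#' @param noise_sd_ti Additive Gaussian noise sd on the TI, m-ohm.
#' @param rr_jitter_sd_ms Per-beat Gaussian jitter of RR intervals, ms.
#' @param amp_jitter_rel Relative segment-to-segment jitter of patient-level
#'   amplitude draws.
#' @param ti_dc_mohm DC level of the raw TI channel, m-ohm.
#' @param t_onset_max_s Segments are placed uniformly in `[0, t_onset_max_s]`
#'   from PEA onset.
#' @param contrast_by_onset If nonzero, the faPEA ICC/ECG amplitude is scaled
#'   by `1 + contrast_by_onset * t_onset/t_onset_max_s` (late segments closer
#'   to conversion show stronger mechanical activity).
#' @param fs Sampling rate, Hz.
#' @param duration_s Segment duration, s.
#' @return An object of class `"synth_params"`.
#' @export
synth_params <- function(n_patients = c(faPEA = 10, unPEA = 10),
                         segments_per_patient = list(faPEA = c(2, 6),
                                                     unPEA = c(2, 6)),
                         hr_bpm = list(faPEA = c(60, 120),
                                       unPEA = c(30, 70)),
                         ecg_amp_mV = c(faPEA = 0.8, unPEA = 0.3),
                         qrs_width_ms = list(faPEA = c(80, 120),
                                             unPEA = c(120, 200)),
                         icc_amp_mohm = c(faPEA = 50, unPEA = 5),
                         icc_harmonics = 3,
                         coeff_lambda = 0.05,
                         coeff_mod_sd = 0.1,
                         baseline_wander_amp = 200,
                         baseline_wander_hz = 0.08,
                         resp_rate_hz = 0.3,
                         resp_amp_mohm = 150,
                         noise_sd_ecg = 0.05,
                         noise_sd_ti = 5,
                         rr_jitter_sd_ms = 10,
                         amp_jitter_rel = 0.1,
                         ti_dc_mohm = 80000,
                         t_onset_max_s = 600,
                         contrast_by_onset = 0,
                         fs = 250, duration_s = 5) {
  p <- as.list(environment())
  for (cl in c("faPEA", "unPEA")) {
    if (any(p$hr_bpm[[cl]] < 20) || any(p$hr_bpm[[cl]] > 200))
      stop("hr_bpm must lie within 20-200 bpm")
    if (p$segments_per_patient[[cl]][1] < 1)
      stop("segments_per_patient must be >= 1")
  }
  amps <- c(p$ecg_amp_mV, p$icc_amp_mohm, p$baseline_wander_amp,
            p$resp_amp_mohm, p$noise_sd_ecg, p$noise_sd_ti)
  if (any(amps < 0)) stop("amplitudes must be non-negative")
  class(p) <- "synth_params"
  p
}

# Ricker (Mexican-hat) wavelet, peak 1 at t = 0. The visible complex spans
# roughly 4*s seconds, so s maps from the QRS width as width/4.
.ricker <- function(t, s) (1 - (t / s)^2) * exp(-t^2 / (2 * s^2))

#' Generate one synthetic PEA segment
#'
#' A pure function of `(label, params, seed)`. The ECG is a train of
#' Ricker-wavelet QRS surrogates at a jittered heart rate plus Gaussian
#' noise; the TI is DC + baseline drift + respiration sinusoid + a
#' heartbeat-locked harmonic sum (the ICC ground truth, with slowly varying
#' AR(1) Fourier coefficients) plus Gaussian noise. Ground truth is
#' attached as attributes `r_peaks_true`, `icc_true`, `f_true` and
#' `truth` (the drawn parameters).
#'
#' @param label `"faPEA"` or `"unPEA"`.
#' @param params A [synth_params()].
#' @param seed Integer seed.
#' @param patient_id Patient identifier for the segment.
#' @param t_onset Seconds from PEA onset.
#' @param draws Optional list of patient-level draws (`hr_bpm`, `ecg_amp`,
#'   `qrs_width_ms`, `icc_amp`) used to correlate segments within a patient;
#'   missing entries are drawn from `params`.
#' @return A [pea_segment()] with ground-truth attributes.
#' @export
simulate_pea_segment <- function(label, params = synth_params(), seed = 1,
                                 patient_id = "synth", t_onset = 0,
                                 draws = list()) {
  label <- match.arg(label, c("faPEA", "unPEA"))
  stopifnot(inherits(params, "synth_params"))
  set.seed(as.integer(as.numeric(seed) %% 2147483647))
  fs <- params$fs
  N <- round(fs * params$duration_s)
  tt <- (seq_len(N) - 1) / fs

  hr <- if (!is.null(draws$hr_bpm)) draws$hr_bpm else
    stats::runif(1, params$hr_bpm[[label]][1], params$hr_bpm[[label]][2])
  amp <- if (!is.null(draws$ecg_amp)) draws$ecg_amp else
    params$ecg_amp_mV[[label]]
  qw <- if (!is.null(draws$qrs_width_ms)) draws$qrs_width_ms else
    stats::runif(1, params$qrs_width_ms[[label]][1],
                 params$qrs_width_ms[[label]][2])
  icc_amp <- if (!is.null(draws$icc_amp)) draws$icc_amp else
    params$icc_amp_mohm[[label]]
  if (params$contrast_by_onset != 0 && label == "faPEA") {
    mult <- 1 + params$contrast_by_onset * t_onset / params$t_onset_max_s
    icc_amp <- icc_amp * mult
    amp <- amp * mult
  }

  # beat times: jittered RR train covering the segment
  rr <- 60 / hr
  beat_t <- stats::runif(1, 0, rr)
  repeat {
    nxt <- beat_t[length(beat_t)] + rr +
      stats::rnorm(1, 0, params$rr_jitter_sd_ms / 1000)
    if (nxt > params$duration_s + rr) break
    beat_t <- c(beat_t, nxt)
  }
  beat_t <- beat_t[beat_t < params$duration_s]
  r_peaks <- pmin(N, round(beat_t * fs) + 1L)

  s_qrs <- (qw / 1000) / 4
  ecg_clean <- numeric(N)
  for (bt in beat_t) ecg_clean <- ecg_clean + amp * .ricker(tt - bt, s_qrs)

  # instantaneous heart rate of the true beat train (cycles/sample)
  f_true <- if (length(r_peaks) >= 2)
    instantaneous_hr(r_peaks, fs, N) else rep(hr / 60 / fs, N)

  # heartbeat-locked harmonic ICC with slowly varying Fourier coefficients
  icc_true <- numeric(N)
  truth_coeffs <- NULL
  if (icc_amp > 0) {
    phi <- exp(-params$coeff_lambda / fs)
    innov_sd <- params$coeff_mod_sd * sqrt(1 - phi^2)
    nharm <- params$icc_harmonics
    ca <- matrix(0, N, nharm); cb <- matrix(0, N, nharm)
    n0 <- seq_len(N) - 1
    for (k in seq_len(nharm)) {
      theta <- stats::runif(1, 0, 2 * pi)
      ma <- cos(theta) / k; mb <- sin(theta) / k
      ar_a <- stats::filter(stats::rnorm(N, 0, innov_sd), phi,
                            method = "recursive")
      ar_b <- stats::filter(stats::rnorm(N, 0, innov_sd), phi,
                            method = "recursive")
      ca[, k] <- icc_amp * (ma + as.numeric(ar_a))
      cb[, k] <- icc_amp * (mb + as.numeric(ar_b))
      icc_true <- icc_true + ca[, k] * cos(k * 2 * pi * f_true * n0) +
        cb[, k] * sin(k * 2 * pi * f_true * n0)
    }
    truth_coeffs <- list(a = ca, b = cb)
  }

  ti <- params$ti_dc_mohm +
    params$baseline_wander_amp *
      sin(2 * pi * params$baseline_wander_hz * tt + stats::runif(1, 0, 2 * pi)) +
    params$resp_amp_mohm *
      sin(2 * pi * params$resp_rate_hz * tt + stats::runif(1, 0, 2 * pi)) +
    icc_true + stats::rnorm(N, 0, params$noise_sd_ti)
  ecg <- ecg_clean + stats::rnorm(N, 0, params$noise_sd_ecg)

  seg <- pea_segment(patient_id = patient_id, ecg = ecg, ti = ti, fs = fs,
                     label = label, t_onset = t_onset, canonicalize = FALSE)
  attr(seg, "r_peaks_true") <- r_peaks
  attr(seg, "icc_true") <- icc_true
  attr(seg, "f_true") <- f_true
  attr(seg, "ecg_clean") <- ecg_clean
  attr(seg, "truth") <- list(hr_bpm = hr, ecg_amp = amp, qrs_width_ms = qw,
                             icc_amp = icc_amp, coeffs = truth_coeffs)
  seg
}

#' Generate a labeled synthetic cohort
#'
#' Patients are disjoint between classes; segments of one patient share
#' patient-level draws (heart-rate base, amplitudes) with segment-level
#' jitter, so the patientwise cross-validation constraint is meaningful.
#'
#' @param params A [synth_params()].
#' @param seed Master integer seed; all per-segment seeds derive from it.
#' @return A [pea_dataset()] (provenance `"synthetic"`) with attribute
#'   `ground_truth`: a data.frame of the true per-segment parameters, plus
#'   list-columns are avoided by storing true R-peaks/ICC on each segment.
#' @export
simulate_pea_dataset <- function(params = synth_params(), seed = 1) {
  stopifnot(inherits(params, "synth_params"))
  seed <- as.numeric(seed) %% 2147483647
  segs <- list()
  truth <- list()
  pat_counter <- 0L
  for (cl in c("faPEA", "unPEA")) {
    npat <- params$n_patients[[cl]]
    for (p in seq_len(npat)) {
      pat_counter <- pat_counter + 1L
      pid <- sprintf("%s_P%03d", ifelse(cl == "faPEA", "fa", "un"), p)
      pseed <- (seed * 100003 + pat_counter * 1009) %% 2147483647
      set.seed(as.integer(pseed))
      draws <- list(
        hr_bpm = stats::runif(1, params$hr_bpm[[cl]][1],
                              params$hr_bpm[[cl]][2]),
        ecg_amp = params$ecg_amp_mV[[cl]],
        qrs_width_ms = stats::runif(1, params$qrs_width_ms[[cl]][1],
                                    params$qrs_width_ms[[cl]][2]),
        icc_amp = params$icc_amp_mohm[[cl]])
      rng <- params$segments_per_patient[[cl]]
      nseg <- if (rng[1] == rng[2]) rng[1] else
        sample(seq.int(rng[1], rng[2]), 1)
      onsets <- sort(stats::runif(nseg, 0, params$t_onset_max_s))
      for (s in seq_len(nseg)) {
        sdraws <- draws
        jit <- function(v) v * (1 + stats::rnorm(1, 0, params$amp_jitter_rel))
        sdraws$ecg_amp <- max(0, jit(draws$ecg_amp))
        sdraws$icc_amp <- max(0, jit(draws$icc_amp))
        sdraws$hr_bpm <- min(200, max(20, jit(draws$hr_bpm)))
        sseed <- (pseed + s * 7919) %% 2147483647
        seg <- simulate_pea_segment(cl, params, seed = sseed,
                                    patient_id = pid, t_onset = onsets[s],
                                    draws = sdraws)
        segs[[length(segs) + 1L]] <- seg
        tr <- attr(seg, "truth")
        truth[[length(truth) + 1L]] <-
          data.frame(patient_id = pid, label = cl, t_onset_s = onsets[s],
                     hr_bpm = tr$hr_bpm, ecg_amp_mV = tr$ecg_amp,
                     qrs_width_ms = tr$qrs_width_ms,
                     icc_amp_mohm = tr$icc_amp,
                     n_true_beats = length(attr(seg, "r_peaks_true")),
                     stringsAsFactors = FALSE)
      }
    }
  }
  ds <- pea_dataset(segs, provenance = "synthetic")
  attr(ds, "ground_truth") <- do.call(rbind, truth)
  ds
}
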