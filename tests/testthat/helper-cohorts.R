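# Shared synthetic cohorts, built once per test run. Cohort A carries the
# full set of class contrasts the pipeline is designed for (amplitude,
# heart rate, QRS width, circulation component); cohort B plants the
# contrast only in the impedance channel, leaving the ECG distributions
# identical across classes.

.cohort_cache <- new.env(parent = emptyenv())

cohort_a_features <- function() {
  if (is.null(.cohort_cache$a)) {
    params <- synth_params(n_patients = c(faPEA = 40, unPEA = 40))
    ds <- simulate_pea_dataset(params, seed = 20260101)
    .cohort_cache$a <- pea_features(ds)
  }
  .cohort_cache$a
}

cohort_b_features <- function() {
  if (is.null(.cohort_cache$b)) {
    params <- synth_params(
      n_patients = c(faPEA = 40, unPEA = 40),
      hr_bpm = list(faPEA = c(50, 100), unPEA = c(50, 100)),
      ecg_amp_mV = c(faPEA = 0.5, unPEA = 0.5),
      qrs_width_ms = list(faPEA = c(100, 160), unPEA = c(100, 160)),
      icc_amp_mohm = c(faPEA = 50, unPEA = 5))
    ds <- simulate_pea_dataset(params, seed = 20260202)
    .cohort_cache$b <- pea_features(ds)
  }
  .cohort_cache$b
}

# a small feature table with patient structure and a single perfect feature,
# for classifier/evaluation tests that do not need the signal pipeline
planted_feature_table <- function(n_patients = 30, seg_per_patient = 4,
                                  n_noise = 2, seed = 1) {
  set.seed(seed)
  rows <- list()
  for (p in seq_len(n_patients)) {
    lab <- if (p %% 2 == 0) "faPEA" else "unPEA"
    for (s in seq_len(seg_per_patient)) {
      rows[[length(rows) + 1]] <- data.frame(
        patient_id = sprintf("P%03d", p), label = lab,
        t_onset_s = stats::runif(1, 0, 600),
        oracle = as.integer(lab == "faPEA") + stats::rnorm(1, 0, 0.05))
    }
  }
  df <- do.call(rbind, rows)
  for (j in seq_len(n_noise)) df[[paste0("noise", j)]] <- stats::rnorm(nrow(df))
  df
}
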