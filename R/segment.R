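#' A paired 5-s ECG / thoracic-impedance segment
#'
#' Constructs and validates one PEA segment: concurrent ECG (mV) and
#' thoracic impedance (m-ohm) sampled at the same rate, tagged with the
#' patient it came from, its class label and its offset from PEA onset.
#' Segments are canonicalized (resampled) to 250 Hz / 1250 samples before
#' entering the pipeline.
#'
#' @param patient_id Non-empty string identifying the source patient.
#' @param ecg Numeric vector, ECG in mV.
#' @param ti Numeric vector, thoracic impedance in m-ohm; same length as `ecg`.
#' @param fs Sampling rate in Hz of `ecg` and `ti`.
#' @param label One of `"faPEA"`, `"unPEA"`, `"unknown"`.
#' @param t_onset Seconds elapsed from PEA onset (non-negative).
#' @param canonicalize If `TRUE` (default) resample to the canonical rate and
#'   validate the 5-s duration.
#' @param config A [pea_config()].
#' @return An object of class `"pea_segment"`.
#' @export
pea_segment <- function(patient_id, ecg, ti, fs, label = "unknown",
                        t_onset = 0, canonicalize = TRUE,
                        config = pea_config()) {
  if (!is.character(patient_id) || length(patient_id) != 1 ||
      !nzchar(patient_id))
    stop("patient_id must be a non-empty string")
  label <- match.arg(label, c("faPEA", "unPEA", "unknown"))
  if (length(ecg) != length(ti))
    stop("validation error: ecg and ti must have equal length (",
         length(ecg), " vs ", length(ti), ")")
  if (!is.numeric(ecg) || !is.numeric(ti) || anyNA(ecg) || anyNA(ti))
    stop("ecg and ti must be numeric with no missing values")
  if (!is.numeric(t_onset) || t_onset < 0)
    stop("t_onset must be a non-negative number of seconds")
  if (fs <= 0) stop("fs must be positive")
  seg <- structure(list(patient_id = patient_id, label = label,
                        t_onset = as.numeric(t_onset), fs = as.numeric(fs),
                        ecg = as.numeric(ecg), ti = as.numeric(ti)),
                   class = "pea_segment")
  if (canonicalize) seg <- canonicalize_segment(seg, config) else seg
}

#' Canonicalize a segment to the pipeline rate
#'
#' Resamples both channels to `config$fs` using polyphase rational
#' resampling with a zero-phase anti-aliasing filter and validates that the
#' result is exactly `config$duration_s` seconds long. Segments whose
#' duration differs are rejected rather than padded or cropped, since silent
#' padding would bias the waveform features. Canonicalization is idempotent:
#' a segment already at the target rate passes through unchanged.
#'
#' @param seg A [pea_segment()].
#' @param config A [pea_config()].
#' @return The canonical segment (fs = 250 Hz, 1250 samples by default).
#' @export
canonicalize_segment <- function(seg, config = pea_config()) {
  stopifnot(inherits(seg, "pea_segment"))
  fs_to <- config$fs
  if (seg$fs != fs_to) {
    frac <- .as_fraction(fs_to / seg$fs)
    seg$ecg <- .resample_poly(seg$ecg, frac[1], frac[2])
    seg$ti <- .resample_poly(seg$ti, frac[1], frac[2])
    seg$fs <- fs_to
  }
  if (length(seg$ecg) != config$n_samples)
    stop("validation error: segment of ", length(seg$ecg), " samples at ",
         fs_to, " Hz is not ", config$duration_s, " s long; refusing to ",
         "pad or crop")
  seg
}

# Rational approximation p/q of a resampling ratio.
.as_fraction <- function(ratio, max_den = 1000L) {
  for (q in seq_len(max_den)) {
    p <- ratio * q
    if (abs(p - round(p)) < 1e-9) return(c(as.integer(round(p)), q))
  }
  stop("cannot express resampling ratio ", ratio, " as a small fraction")
}

# Polyphase rational resampling; signal::resample uses an FIR anti-aliasing
# filter whose delay it compensates, giving a zero-phase result.
.resample_poly <- function(x, p, q) {
  if (p == q) return(x)
  y <- signal::resample(x, p, q)
  as.numeric(y)
}

#' @export
print.pea_segment <- function(x, ...) {
  cat(sprintf("PEA segment: patient %s, label %s, %g s from onset\n",
              x$patient_id, x$label, x$t_onset))
  cat(sprintf("  %d samples at %g Hz; ECG range [%.3g, %.3g] mV; TI range [%.4g, %.4g] mOhm\n",
              length(x$ecg), x$fs, min(x$ecg), max(x$ecg), min(x$ti), max(x$ti)))
  invisible(x)
}

#' @export
plot.pea_segment <- function(x, ...) {
  t <- seq_along(x$ecg) / x$fs
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(t, x$ecg, type = "l", xlab = "time (s)", ylab = "ECG (mV)",
                 main = sprintf("%s / %s", x$patient_id, x$label), ...)
  graphics::plot(t, x$ti, type = "l", xlab = "time (s)", ylab = "TI (mOhm)", ...)
  invisible(x)
}

#' A collection of PEA segments
#'
#' @param segments List of [pea_segment()] objects.
#' @param provenance `"file"` or `"synthetic"`.
#' @return An object of class `"pea_dataset"`.
#' @export
pea_dataset <- function(segments, provenance = c("file", "synthetic")) {
  provenance <- match.arg(provenance)
  if (!length(segments)) stop("a dataset must contain at least one segment")
  ok <- vapply(segments, inherits, logical(1), what = "pea_segment")
  if (!all(ok)) stop("all elements must be pea_segment objects")
  key <- vapply(segments, function(s) paste(s$patient_id, s$t_onset), "")
  if (anyDuplicated(key))
    stop("duplicate (patient_id, t_onset) pairs: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  structure(list(segments = segments, provenance = provenance),
            class = "pea_dataset")
}

#' @export
length.pea_dataset <- function(x) length(x$segments)

#' @export
print.pea_dataset <- function(x, ...) {
  labs <- vapply(x$segments, function(s) s$label, "")
  pats <- vapply(x$segments, function(s) s$patient_id, "")
  cat(sprintf("PEA dataset (%s): %d segments from %d patients\n",
              x$provenance, length(x$segments), length(unique(pats))))
  print(table(label = labs))
  invisible(x)
}

#' Segment metadata as a data frame
#'
#' @param x A [pea_dataset()].
#' @param ... Unused.
#' @return A data.frame with one row per segment: `patient_id`, `label`,
#'   `t_onset_s`, `fs`.
#' @export
as.data.frame.pea_dataset <- function(x, ...) {
  data.frame(patient_id = vapply(x$segments, function(s) s$patient_id, ""),
             label = vapply(x$segments, function(s) s$label, ""),
             t_onset_s = vapply(x$segments, function(s) s$t_onset, 0),
             fs = vapply(x$segments, function(s) s$fs, 0),
             stringsAsFactors = FALSE)
}

#' Read a segment dataset from disk
#'
#' Expects a directory containing a `metadata.csv` table with columns
#' `segment_file`, `patient_id`, `label`, `t_onset_s`, `fs`, and one
#' two-column CSV per segment (`ecg_mV`, `ti_mOhm`, one sample per row).
#' Every segment is canonicalized to the configured rate on load.
#'
#' @param path Directory holding `metadata.csv` and the segment files.
#' @param config A [pea_config()].
#' @return A [pea_dataset()] with provenance `"file"`.
#' @export
read_pea_dataset <- function(path, config = pea_config()) {
  meta_file <- file.path(path, "metadata.csv")
  if (!file.exists(meta_file)) stop("no metadata.csv under ", path)
  meta <- utils::read.csv(meta_file, stringsAsFactors = FALSE)
  need <- c("segment_file", "patient_id", "label", "t_onset_s", "fs")
  if (!all(need %in% names(meta)))
    stop("metadata.csv must have columns: ", paste(need, collapse = ", "))
  segs <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    f <- file.path(path, meta$segment_file[i])
    if (!file.exists(f))
      stop("load error: metadata row ", i, " (patient ", meta$patient_id[i],
           ") references missing file ", meta$segment_file[i])
    w <- utils::read.csv(f)
    if (!all(c("ecg_mV", "ti_mOhm") %in% names(w)))
      stop("load error: ", meta$segment_file[i],
           " lacks ecg_mV/ti_mOhm columns")
    segs[[i]] <- pea_segment(patient_id = as.character(meta$patient_id[i]),
                             ecg = w$ecg_mV, ti = w$ti_mOhm,
                             fs = meta$fs[i], label = meta$label[i],
                             t_onset = meta$t_onset_s[i], config = config)
  }
  pea_dataset(segs, provenance = "file")
}

#' Write a segment dataset to disk
#'
#' Inverse of [read_pea_dataset()]: writes `metadata.csv` plus one CSV per
#' segment. Samples are written with full double precision so that a
#' read-back reproduces them to text precision.
#'
#' @param ds A non-empty [pea_dataset()].
#' @param path Target directory (created if absent).
#' @return `path`, invisibly.
#' @export
write_pea_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "pea_dataset"))
  if (!length(ds$segments)) stop("refusing to write an empty dataset")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stop("cannot create directory ", path)
  files <- sprintf("segment_%04d.csv", seq_along(ds$segments))
  meta <- as.data.frame(ds)
  # 17 significant digits round-trip a double exactly through text
  meta$t_onset_s <- sprintf("%.17g", meta$t_onset_s)
  meta$fs <- sprintf("%.17g", meta$fs)
  meta <- cbind(segment_file = files, meta)
  utils::write.csv(meta, file.path(path, "metadata.csv"), row.names = FALSE,
                   quote = FALSE)
  for (i in seq_along(ds$segments)) {
    s <- ds$segments[[i]]
    df <- data.frame(ecg_mV = sprintf("%.17g", s$ecg),
                     ti_mOhm = sprintf("%.17g", s$ti))
    utils::write.csv(df, file.path(path, files[i]), row.names = FALSE,
                     quote = FALSE)
  }
  invisible(path)
}
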