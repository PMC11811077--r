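# Preprocessing: 50 Hz notch, resampling to 64 Hz, 0.5-30 Hz zero-phase
# Butterworth band-pass, sliding-window artifact suppression, one-hour
# segmentation. All stages operate per channel and preserve channel order.

#' Preprocessing configuration
#'
#' @param notch_hz mains frequency to notch out (`NULL` disables the stage).
#' @param notch_q quality factor of the second-order IIR notch.
#' @param target_fs sampling rate after resampling, Hz.
#' @param band band-pass edges (Hz); must satisfy 0 < lo < hi < target_fs/2.
#' @param butter_order Butterworth order for the band-pass.
#' @param artifact_window_s window length for artifact scoring, seconds.
#' @param artifact_z robust z-score threshold above which a window is
#'   treated as artifact and repaired.
#' @param segment_s segment length, seconds (one hour).
#' @return a list of class `preproc_config`.
#' @export
preproc_config <- function(notch_hz = 50, notch_q = 30, target_fs = 64,
                           band = c(0.5, 30), butter_order = 5,
                           artifact_window_s = 1, artifact_z = 5,
                           segment_s = 3600) {
  stopifnot(band[1] > 0, band[1] < band[2], band[2] < target_fs / 2,
            butter_order >= 1, artifact_window_s > 0, artifact_z > 0)
  structure(as.list(environment()), class = "preproc_config")
}

# RBJ second-order IIR notch at f0 with quality Q.
design_notch <- function(f0, fs, Q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

apply_rows <- function(rec, f) {
  first <- f(rec$data[1L, ])
  out <- matrix(0, nrow = nrow(rec$data), ncol = length(first))
  out[1L, ] <- first
  for (ch in seq_len(nrow(rec$data))[-1L]) out[ch, ] <- f(rec$data[ch, ])
  recording(out, fs = rec$fs, labels = rec$labels,
            subject_id = rec$subject_id, pma_weeks = rec$pma_weeks)
}

#' Mains notch filter
#'
#' Zero-phase (forward-backward) second-order IIR notch; attenuates the
#' mains tone by well over 20 dB while the 10 Hz passband gain stays within
#' 1 dB of unity.
#'
#' @param rec a [recording].
#' @param cfg a [preproc_config()].
#' @return the filtered recording.
#' @export
notch_filter <- function(rec, cfg = preproc_config()) {
  if (is.null(cfg$notch_hz)) return(rec)
  if (rec$fs <= 2 * cfg$notch_hz) {
    stop_value("fs = %g too low to notch %g Hz", rec$fs, cfg$notch_hz)
  }
  flt <- design_notch(cfg$notch_hz, rec$fs, cfg$notch_q)
  apply_rows(rec, function(x) zero_phase_filter(x, flt$b, flt$a))
}

#' Resample a recording
#'
#' Fourier-method resampling (band-limited sinc interpolation with an ideal
#' anti-alias response and exact output length `round(n * target_fs / fs)`).
#' Only downsampling (or identity) is supported.
#'
#' @inheritParams notch_filter
#' @return the recording at `cfg$target_fs`.
#' @export
resample_to <- function(rec, cfg = preproc_config()) {
  if (rec$fs < cfg$target_fs) {
    stop_value("upsampling %g -> %g Hz is not supported", rec$fs, cfg$target_fs)
  }
  if (rec$fs == cfg$target_fs) return(rec)
  m <- round(ncol(rec$data) * cfg$target_fs / rec$fs)
  out <- matrix(0, nrow = nrow(rec$data), ncol = m)
  for (ch in seq_len(nrow(rec$data))) out[ch, ] <- fft_resample(rec$data[ch, ], m)
  recording(out, fs = cfg$target_fs, labels = rec$labels,
            subject_id = rec$subject_id, pma_weeks = rec$pma_weeks)
}

butter_bandpass <- function(lo, hi, fs, order) {
  signal::butter(order, c(lo, hi) / (fs / 2), type = "pass")
}

#' Band-pass filter a recording
#'
#' Zero-phase Butterworth band-pass at `cfg$band`: the squared Butterworth
#' magnitude response (the forward-backward response) is applied in the
#' frequency domain, so the phase is exactly zero -- a deliberate choice
#' because several downstream features are phase-sensitive.
#'
#' @inheritParams notch_filter
#' @return the filtered recording.
#' @export
bandpass_filter <- function(rec, cfg = preproc_config()) {
  if (cfg$band[2] >= rec$fs / 2) {
    stop_value("band edge %g Hz at or above Nyquist (%g Hz)", cfg$band[2], rec$fs / 2)
  }
  flt <- butter_bandpass(cfg$band[1], cfg$band[2], rec$fs, cfg$butter_order)
  apply_rows(rec, function(x) zero_phase_filter(x, flt$b, flt$a))
}

#' Suppress high-variance artifacts
#'
#' Scores consecutive `artifact_window_s` windows per channel by a robust
#' z-score of the window RMS (median/MAD over the channel's windows);
#' windows exceeding `artifact_z` are repaired by interpolation between the
#' robust (median) levels of the flanking clean data. Clean recordings pass
#' through unchanged.
#'
#' @inheritParams notch_filter
#' @return list with `recording` (repaired) and `mask`, a data frame of
#'   repaired spans (`channel`, `start_s`, `end_s`).
#' @export
suppress_artifacts <- function(rec, cfg = preproc_config()) {
  w <- max(2L, round(cfg$artifact_window_s * rec$fs))
  n <- ncol(rec$data)
  nwin <- n %/% w
  mask <- list()
  data <- rec$data
  for (ch in seq_len(nrow(data))) {
    x <- data[ch, ]
    if (nwin < 3L) next
    rms <- sqrt(colMeans(matrix(x[seq_len(nwin * w)]^2, nrow = w)))
    med <- median(rms); s <- mad(rms)
    if (!is.finite(s) || s == 0) next
    z <- (rms - med) / s
    bad <- which(z > cfg$artifact_z)
    if (!length(bad)) next
    # merge adjacent bad windows into spans
    runs <- split(bad, cumsum(c(1, diff(bad) != 1)))
    for (r in runs) {
      i0 <- (min(r) - 1L) * w + 1L
      i1 <- min(max(r) * w, n)
      ctx <- max(1L, round(0.5 * rec$fs))
      left <- setdiff(max(1L, i0 - ctx):max(1L, i0 - 1L), i0:i1)
      right <- setdiff(min(n, i1 + 1L):min(n, i1 + ctx), i0:i1)
      # interpolate between the robust levels of the flanking clean data;
      # a spline through the raw noisy flank samples would swing across the
      # repaired gap, so the anchors are flank medians
      lv <- if (length(left)) median(x[left]) else 0
      rv <- if (length(right)) median(x[right]) else 0
      x[i0:i1] <- approx(c(i0 - 1L, i1 + 1L), c(lv, rv), xout = i0:i1)$y
      mask[[length(mask) + 1L]] <- data.frame(
        channel = rec$labels[ch], start_s = (i0 - 1L) / rec$fs, end_s = i1 / rec$fs)
    }
    data[ch, ] <- x
  }
  mask <- if (length(mask)) do.call(rbind, mask) else
    data.frame(channel = character(), start_s = numeric(), end_s = numeric())
  list(recording = recording(data, fs = rec$fs, labels = rec$labels,
                             subject_id = rec$subject_id, pma_weeks = rec$pma_weeks),
       mask = mask)
}

#' Cut a recording into non-overlapping fixed-length segments
#'
#' @inheritParams notch_filter
#' @return list of recordings of exactly `segment_s * fs` samples each; a
#'   trailing remainder is discarded, and a recording shorter than one
#'   segment yields an empty list with a warning.
#' @export
segment_hours <- function(rec, cfg = preproc_config()) {
  len <- round(cfg$segment_s * rec$fs)
  k <- ncol(rec$data) %/% len
  if (k < 1L) {
    warning(sprintf("recording %s shorter than one segment (%.1f s < %g s)",
                    rec$subject_id, duration_s(rec), cfg$segment_s))
    return(list())
  }
  lapply(seq_len(k), function(i) {
    seg <- recording(rec$data[, ((i - 1L) * len + 1L):(i * len), drop = FALSE],
                     fs = rec$fs, labels = rec$labels,
                     subject_id = rec$subject_id, pma_weeks = rec$pma_weeks)
    attr(seg, "segment_index") <- i
    seg
  })
}

#' Full preprocessing pipeline for one referential recording
#'
#' Fixed stage order: notch -> resample -> band-pass -> artifact
#' suppression -> segmentation. The bipolar montage is derived *after*
#' preprocessing (linear stages commute with the electrode subtraction).
#'
#' @inheritParams notch_filter
#' @return list with `segments` (list of one-hour recordings) and `mask`
#'   (artifact spans, in post-resampling time).
#' @export
preprocess_recording <- function(rec, cfg = preproc_config()) {
  # The three linear stages are fused in the frequency domain: notch
  # response at the native rate, spectrum truncation (resampling), band-pass
  # response at the target rate. Identical to applying notch_filter(),
  # resample_to() and bandpass_filter() in sequence -- the intermediate
  # inverse/forward FFT pairs cancel exactly -- at a third of the FFT cost.
  if (!is.null(cfg$notch_hz) && rec$fs <= 2 * cfg$notch_hz) {
    stop_value("fs = %g too low to notch %g Hz", rec$fs, cfg$notch_hz)
  }
  if (rec$fs < cfg$target_fs) {
    stop_value("upsampling %g -> %g Hz is not supported", rec$fs, cfg$target_fs)
  }
  if (cfg$band[2] >= cfg$target_fs / 2) {
    stop_value("band edge %g Hz at or above Nyquist (%g Hz)", cfg$band[2], cfg$target_fs / 2)
  }
  n <- ncol(rec$data)
  m <- round(n * cfg$target_fs / rec$fs)
  nresp <- if (!is.null(cfg$notch_hz)) {
    flt <- design_notch(cfg$notch_hz, rec$fs, cfg$notch_q)
    filter_response_sq(flt$b, flt$a, n)
  }
  bflt <- butter_bandpass(cfg$band[1], cfg$band[2], cfg$target_fs, cfg$butter_order)
  bresp <- filter_response_sq(bflt$b, bflt$a, m)
  out <- apply_rows_resized(rec, cfg$target_fs, m, function(x) {
    X <- fft(x)
    if (!is.null(nresp)) X <- X * nresp
    Re(fft(spectrum_resize(X, m) * bresp, inverse = TRUE)) / n
  })
  sup <- suppress_artifacts(out, cfg)
  list(segments = segment_hours(sup$recording, cfg), mask = sup$mask)
}

apply_rows_resized <- function(rec, fs, m, f) {
  out <- matrix(0, nrow = nrow(rec$data), ncol = m)
  for (ch in seq_len(nrow(rec$data))) out[ch, ] <- f(rec$data[ch, ])
  recording(out, fs = fs, labels = rec$labels,
            subject_id = rec$subject_id, pma_weeks = rec$pma_weeks)
}
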