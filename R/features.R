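# Quantitative EEG features: 86 per channel and one-hour segment.
# Per frequency band (delta, theta, alpha, beta): 6 amplitude + 8 range-EEG
# + 6 spectral features; broadband: 5 inter-burst-interval features and the
# Higuchi fractal dimension. Features are computed on 60 s epochs (50%
# overlap; 119 per hour) and averaged across epochs.

#' Frequency band definitions
#' @return data frame with `band`, `lo`, `hi` (Hz): delta 0.5--4,
#'   theta 4--7, alpha 7--13, beta 13--30.
#' @export
band_defs <- function() {
  data.frame(band = c("delta", "theta", "alpha", "beta"),
             lo = c(0.5, 4, 7, 13), hi = c(4, 7, 13, 30),
             stringsAsFactors = FALSE)
}

#' Cut a signal into sliding epochs
#'
#' @param x numeric vector (one channel).
#' @param fs sampling rate, Hz.
#' @param epoch_s window length in seconds (rectangular).
#' @param overlap fractional overlap between consecutive epochs.
#' @return samples-by-epochs matrix; a one-hour signal at 60 s / 50% gives
#'   119 epochs.
#' @export
epoch_signal <- function(x, fs, epoch_s = 60, overlap = 0.5) {
  len <- round(epoch_s * fs)
  hop <- round(epoch_s * (1 - overlap) * fs)
  if (length(x) < len) {
    stop_value("signal (%d samples) shorter than one %g s epoch", length(x), epoch_s)
  }
  n_ep <- (length(x) - len) %/% hop + 1L
  starts <- (seq_len(n_ep) - 1L) * hop
  out <- matrix(x[outer(seq_len(len), starts, "+")], nrow = len)
  attr(out, "starts") <- starts
  attr(out, "fs") <- fs
  out
}

#' Zero-phase Butterworth band-pass of one signal
#'
#' Applies the squared magnitude response of a Butterworth band-pass (the
#' forward-backward response) in the frequency domain: exactly zero phase.
#'
#' @param x numeric vector.
#' @param fs sampling rate, Hz.
#' @param lo,hi band edges, Hz.
#' @param order filter order.
#' @return the band-limited signal.
#' @export
band_filter <- function(x, fs, lo, hi, order = 5) {
  flt <- butter_bandpass(lo, hi, fs, order)
  zero_phase_filter(x, flt$b, flt$a)
}

# Columnwise moments of an epochs matrix; excess-kurtosis convention.
col_moments <- function(Y) {
  N <- nrow(Y)
  Y2 <- Y * Y
  m1 <- colMeans(Y)
  r2 <- colMeans(Y2); r3 <- colMeans(Y2 * Y); r4 <- colMeans(Y2 * Y2)
  m2 <- pmax(r2 - m1^2, 0)
  m3 <- r3 - 3 * m1 * r2 + 2 * m1^3
  m4 <- r4 - 4 * m1 * r3 + 6 * m1^2 * r2 - 3 * m1^4
  zero <- m2 <= 0
  list(mean = m1, power = r2,
       sd = sqrt(m2 * N / (N - 1)),
       skewness = ifelse(zero, NA_real_, m3 / m2^1.5),
       kurtosis = ifelse(zero, NA_real_, m4 / m2^2 - 3))
}

# mean/sd only (for envelope statistics, where higher moments are unused).
col_mean_sd <- function(Y) {
  N <- nrow(Y)
  m1 <- colMeans(Y)
  m2 <- pmax(colMeans(Y * Y) - m1^2, 0)
  list(mean = m1, sd = sqrt(m2 * N / (N - 1)))
}

#' Amplitude-domain features of one epoch
#'
#' Signal power (mean squared amplitude), sample SD, skewness, excess
#' kurtosis, and the mean and SD of the analytic-signal (Hilbert) envelope.
#' Skewness/kurtosis of a constant signal are recorded as missing.
#'
#' @param y band-filtered epoch.
#' @param envelope optional precomputed envelope `|y + jH{y}|`.
#' @return named numeric vector of 6 features.
#' @export
amplitude_features <- function(y, envelope = NULL) {
  if (is.null(envelope)) envelope <- hilbert_envelope(y)
  m <- col_moments(cbind(y))
  setNames(c(m$power, m$sd, m$skewness, m$kurtosis,
             mean(envelope), sd(envelope)),
           c("power", "sd", "skewness", "kurtosis", "env_mean", "env_sd"))
}

reeg_summary <- function(ranges) {
  mu <- mean(ranges)
  q <- quantile7_sorted(sort(ranges), c(0.05, 0.5, 0.95))
  width <- q[3] - q[1]
  s <- sd(ranges)
  c(mean = mu, median = q[2], lower_margin = q[1], upper_margin = q[3],
    width = width, sd = s,
    cv = if (mu == 0) NA_real_ else s / mu,
    asymmetry = if (width == 0) NA_real_ else ((q[3] - q[2]) - (q[2] - q[1])) / width)
}

#' Range-EEG features of one epoch
#'
#' Peak-to-peak voltage over 2 s half-overlapping sub-segments, summarised
#' by mean, median, 5th/95th percentile margins, width (upper - lower
#' margin), SD, coefficient of variation and a bounded asymmetry index
#' `((upper - median) - (median - lower)) / width`.
#'
#' @param y band-filtered epoch.
#' @param fs sampling rate, Hz.
#' @param seg_s sub-segment length, seconds.
#' @param overlap fractional sub-segment overlap.
#' @return named numeric vector of 8 features.
#' @export
reeg_features <- function(y, fs, seg_s = 2, overlap = 0.5) {
  width <- round(seg_s * fs)
  hop <- round(seg_s * (1 - overlap) * fs)
  reeg_summary(block_ranges(y, width, hop))
}

#' Burst detector parameters
#' @param smooth_s moving-average smoothing of the envelope, seconds.
#' @param rel_thresh burst threshold as a multiple of the epoch median
#'   envelope.
#' @param abs_thresh_uv absolute envelope ceiling for the threshold,
#'   microvolts; the effective threshold is
#'   `min(rel_thresh * median(envelope), abs_thresh_uv)`, so sustained
#'   high-amplitude activity is still classified as burst.
#' @param min_burst_s minimum burst duration, seconds.
#' @param merge_s gaps shorter than this are merged into one burst, seconds.
#' @return a list of class `burst_params`.
#' @export
burst_params <- function(smooth_s = 0.5, rel_thresh = 1.5, abs_thresh_uv = 15,
                         min_burst_s = 1, merge_s = 0.5) {
  structure(as.list(environment()), class = "burst_params")
}

detect_bursts_env <- function(env, fs, params = burst_params()) {
  thr <- min(params$rel_thresh * median(env), params$abs_thresh_uv)
  above <- env > thr
  if (!any(above)) return(cbind(start = numeric(0), end = numeric(0)))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  iv <- cbind((starts[r$values] - 1L) / fs, ends[r$values] / fs)
  # merge short gaps, then enforce the minimum burst duration
  if (nrow(iv) > 1L) {
    keep <- iv[1, , drop = FALSE]
    for (k in 2:nrow(iv)) {
      if (iv[k, 1] - keep[nrow(keep), 2] < params$merge_s) {
        keep[nrow(keep), 2] <- iv[k, 2]
      } else keep <- rbind(keep, iv[k, ])
    }
    iv <- keep
  }
  iv <- iv[iv[, 2] - iv[, 1] >= params$min_burst_s, , drop = FALSE]
  colnames(iv) <- c("start", "end")
  iv
}

#' Detect high-amplitude bursts in a broadband epoch
#'
#' Amplitude-envelope detector: the Hilbert envelope is smoothed by a short
#' moving average and thresholded; supra-threshold intervals of at least
#' `min_burst_s` are bursts, with sub-`merge_s` gaps merged.
#'
#' @param y broadband (0.5--30 Hz) epoch, microvolts.
#' @param fs sampling rate, Hz.
#' @param params a [burst_params()].
#' @return matrix of `[start, end)` burst intervals in seconds (possibly
#'   zero rows).
#' @export
detect_bursts <- function(y, fs, params = burst_params()) {
  env <- moving_average(hilbert_envelope(y), round(params$smooth_s * fs))
  detect_bursts_env(env, fs, params)
}

#' Inter-burst interval features
#'
#' IBIs are the gaps between consecutive bursts. Mean, median, SD
#' (population convention) and CV of the IBIs, plus the burst ratio (total
#' burst time over epoch length). With fewer than two bursts the IBI
#' statistics are missing while the burst ratio stays defined.
#'
#' @param ann burst interval matrix from [detect_bursts()].
#' @param epoch_s epoch length in seconds.
#' @return named numeric vector of 5 features.
#' @export
ibi_features <- function(ann, epoch_s) {
  ratio <- sum(ann[, 2] - ann[, 1]) / epoch_s
  if (nrow(ann) < 2L) {
    return(c(mean = NA_real_, median = NA_real_, sd = NA_real_,
             cv = NA_real_, burst_ratio = ratio))
  }
  ibis <- ann[-1L, 1] - ann[-nrow(ann), 2]
  mu <- mean(ibis)
  s <- sqrt(mean((ibis - mu)^2))
  c(mean = mu, median = median(ibis), sd = s,
    cv = if (mu == 0) NA_real_ else s / mu, burst_ratio = ratio)
}

# One-sided Welch/STFT machinery shared by the standalone and fast paths.
stft_psd <- function(x, fs, win_s = 2, overlap = 0.5) {
  wlen <- round(win_s * fs)
  hop <- round(win_s * (1 - overlap) * fs)
  if (length(x) < wlen) stop_value("signal shorter than one %g s analysis window", win_s)
  nfr <- (length(x) - wlen) %/% hop + 1L
  w <- 0.54 - 0.46 * cos(2 * pi * (seq_len(wlen) - 1L) / wlen)  # periodic hamming
  Fm <- matrix(x[outer(seq_len(wlen), (seq_len(nfr) - 1L) * hop, "+")], nrow = wlen) * w
  S <- Mod(mvfft(Fm))^2 / (fs * sum(w^2))
  nb <- wlen %/% 2L + 1L
  S <- S[seq_len(nb), , drop = FALSE]
  if (wlen %% 2L == 0L) S[2:(nb - 1L), ] <- 2 * S[2:(nb - 1L), ] else
    S[2:nb, ] <- 2 * S[2:nb, ]
  list(S = S, f = (seq_len(nb) - 1L) * fs / wlen, df = fs / wlen, hop_frames = hop)
}

band_mask <- function(f, lo, hi, hi_closed = FALSE) {
  if (hi_closed) f >= lo & f <= hi else f >= lo & f < hi
}

# Spectral summary of per-epoch PSD columns restricted to a band.
spectral_summary <- function(P_band, f_band, df, P_total, diff_mean) {
  power <- colSums(P_band) * df
  total <- colSums(P_total) * df
  rel <- ifelse(total > 0, power / total, NA_real_)
  pos <- power > 0
  logP <- log(pmax(P_band, .Machine$double.xmin))
  wiener <- ifelse(pos, exp(colMeans(logP)) / colMeans(P_band), NA_real_)
  pn <- sweep(P_band, 2L, colSums(P_band), "/")
  plogp <- ifelse(pn > 0, pn * log(pn), 0)
  shannon <- ifelse(pos, -colSums(plogp), NA_real_)
  sef <- rep(NA_real_, ncol(P_band))
  for (j in which(pos)) {
    cum <- cumsum(P_band[, j])
    sef[j] <- f_band[which(cum >= 0.95 * cum[length(cum)])[1]]
  }
  rbind(power = power, rel_power = rel, wiener_entropy = wiener,
        shannon_entropy = shannon, spectral_diff = diff_mean, sef95 = sef)
}

#' Spectral features of one epoch within a band
#'
#' The PSD is estimated by the Welch method (2 s hamming windows, 50%
#' overlap) on the broadband epoch and integrated over the requested band.
#' Band power, relative power (band over total 0.5--30 Hz power), Wiener
#' entropy (spectral flatness: geometric over arithmetic mean of the
#' in-band PSD), Shannon entropy of the unit-sum in-band PSD (natural log),
#' mean squared difference between consecutive unit-sum short-time spectra
#' in band, and the 95% spectral edge frequency within the band.
#'
#' @param y broadband epoch.
#' @param fs sampling rate, Hz.
#' @param band `c(lo, hi)` in Hz.
#' @param total_band band over which total power is taken.
#' @param hi_closed include the upper edge (used for the beta band so the
#'   partition covers 0.5--30 Hz exactly).
#' @return named numeric vector of 6 features.
#' @export
spectral_features <- function(y, fs, band, total_band = c(0.5, 30),
                              hi_closed = band[2] >= total_band[2]) {
  st <- stft_psd(y, fs)
  psd <- rowMeans(st$S)
  bm <- band_mask(st$f, band[1], band[2], hi_closed)
  tm <- band_mask(st$f, total_band[1], total_band[2], TRUE)
  Nrm <- sweep(st$S[bm, , drop = FALSE], 2L, colSums(st$S[bm, , drop = FALSE]), "/")
  d <- if (ncol(Nrm) > 1L) {
    mean(colMeans((Nrm[, -1L, drop = FALSE] - Nrm[, -ncol(Nrm), drop = FALSE])^2))
  } else NA_real_
  out <- spectral_summary(cbind(psd[bm]), st$f[bm], st$df, cbind(psd[tm]), d)
  setNames(out[, 1], rownames(out))
}

#' Higuchi fractal dimension
#'
#' Curve-length estimator over decimation intervals `k = 1..kmax`; the FD is
#' the negative slope of `log L(k)` against `log k`. Approximately 1 for
#' smooth curves and 2 for white noise. The result is clipped to `[1, 2]`.
#'
#' @param y numeric vector (broadband epoch).
#' @param kmax maximum decimation interval.
#' @param warn warn when the raw estimate falls outside `[1, 2]`.
#' @return the fractal dimension.
#' @export
higuchi_fd <- function(y, kmax = 6, warn = TRUE) {
  N <- length(y)
  if (N <= 4 * kmax) stop_value("need more than %d samples for kmax = %d", 4 * kmax, kmax)
  L <- numeric(kmax)
  for (k in seq_len(kmax)) {
    # |y[j+k] - y[j]| grouped by start offset m = ((j-1) mod k) + 1
    d <- abs(y[(k + 1L):N] - y[seq_len(N - k)])
    pad <- (-length(d)) %% k
    sm <- rowSums(matrix(c(d, numeric(pad)), nrow = k))
    m <- seq_len(k)
    nm <- (N - m) %/% k
    L[k] <- mean(sm * (N - 1) / (nm * k) / k)
  }
  if (all(L == 0)) return(1)                       # constant input
  fd <- -coef(stats::lm.fit(cbind(1, log(seq_len(kmax))), log(L)))[2]
  if ((fd < 1 || fd > 2) && warn) {
    warning(sprintf("Higuchi FD %.3f outside [1, 2]; clipped", fd))
  }
  unname(min(max(fd, 1), 2))
}

feature_block_names <- function() {
  b <- band_defs()$band
  amp <- c("power", "sd", "skewness", "kurtosis", "env_mean", "env_sd")
  reeg <- c("mean", "median", "lower_margin", "upper_margin", "width", "sd",
            "cv", "asymmetry")
  spec <- c("power", "rel_power", "wiener_entropy", "shannon_entropy",
            "spectral_diff", "sef95")
  c(paste0(rep(b, each = 6), "__amplitude__", amp),
    paste0(rep(b, each = 8), "__reeg__", reeg),
    paste0(rep(b, each = 6), "__spectral__", spec),
    paste0("broadband__ibi__", c("mean", "median", "sd", "cv", "burst_ratio")),
    "broadband__nonlinear__fd")
}

#' Extract the 86-feature vector of one channel
#'
#' Computes every per-epoch feature over the 60 s / 50%-overlap epoch grid
#' and averages across epochs, skipping missing per-epoch values; a feature
#' is missing only when it is missing in every epoch. Band filtering and
#' envelopes are computed once on the full signal (linear, time-invariant
#' operations commute with epoch windowing up to boundary transients) for
#' speed.
#'
#' @param x one-hour preprocessed single-channel signal (microvolts).
#' @param fs sampling rate, Hz (64 after preprocessing).
#' @param bands band definition table, see [band_defs()].
#' @param burst a [burst_params()].
#' @param kmax Higuchi decimation bound.
#' @return named numeric vector with 86 entries (`band__domain__feature`).
#' @export
extract_channel <- function(x, fs, bands = band_defs(), burst = burst_params(),
                            kmax = 6) {
  ep <- epoch_signal(x, fs)
  starts <- attr(ep, "starts")
  n_ep <- ncol(ep)
  len <- nrow(ep)
  idx <- outer(seq_len(len), starts, "+")
  out <- list()

  # spectral machinery shared across bands: global STFT of the broadband
  # signal on the 2 s / 50% grid, then per-epoch Welch means via running sums
  st <- stft_psd(x, fs)
  fr_per_ep <- (len - round(2 * fs)) %/% round(fs) + 1L        # 59 frames/epoch
  offs <- round(starts / fs)                                   # frame offset of each epoch
  CS0 <- cbind(0, t(apply(st$S, 1L, cumsum)))
  P_ep <- (CS0[, offs + fr_per_ep + 1L, drop = FALSE] - CS0[, offs + 1L, drop = FALSE]) / fr_per_ep
  tm <- band_mask(st$f, 0.5, 30, TRUE)

  Xf <- fft(x)                 # shared spectrum: band filtering + envelopes
  for (i in seq_len(nrow(bands))) {
    b <- bands$band[i]
    flt <- butter_bandpass(bands$lo[i], bands$hi[i], fs, 5)
    Xb <- Xf * filter_response_sq(flt$b, flt$a, length(x))
    yb <- Re(fft(Xb, inverse = TRUE)) / length(x)
    env <- envelope_from_fft(Xb)
    Y <- matrix(yb[idx], nrow = len)
    E <- matrix(env[idx], nrow = len)
    m <- col_moments(Y)
    em <- col_mean_sd(E)
    out[[paste0(b, "__amplitude")]] <- rbind(
      power = m$power, sd = m$sd, skewness = m$skewness, kurtosis = m$kurtosis,
      env_mean = em$mean, env_sd = em$sd)

    rng <- block_ranges(yb, round(2 * fs), round(fs))
    seg_per_ep <- fr_per_ep
    reeg <- vapply(seq_len(n_ep), function(e) {
      reeg_summary(rng[offs[e] + seq_len(seg_per_ep)])
    }, numeric(8))
    out[[paste0(b, "__reeg")]] <- reeg

    bm <- band_mask(st$f, bands$lo[i], bands$hi[i], hi_closed = bands$hi[i] >= 30)
    Nrm <- sweep(st$S[bm, , drop = FALSE], 2L,
                 colSums(st$S[bm, , drop = FALSE]), "/")
    Dfr <- colMeans((Nrm[, -1L, drop = FALSE] - Nrm[, -ncol(Nrm), drop = FALSE])^2)
    CD0 <- c(0, cumsum(ifelse(is.finite(Dfr), Dfr, 0)))
    dmean <- (CD0[offs + fr_per_ep] - CD0[offs + 1L]) / (fr_per_ep - 1L)
    out[[paste0(b, "__spectral")]] <- spectral_summary(
      P_ep[bm, , drop = FALSE], st$f[bm], st$df, P_ep[tm, , drop = FALSE], dmean)
  }

  env_b <- moving_average(envelope_from_fft(Xf), round(burst$smooth_s * fs))
  Eb <- matrix(env_b[idx], nrow = len)
  ib <- vapply(seq_len(n_ep), function(e) {
    ibi_features(detect_bursts_env(Eb[, e], fs, burst), epoch_s = len / fs)
  }, numeric(5))
  fd <- vapply(seq_len(n_ep), function(e) higuchi_fd(x[idx[, e]], kmax, warn = FALSE),
               numeric(1))

  per_epoch <- rbind(do.call(rbind, out[paste0(bands$band, "__amplitude")]),
                     do.call(rbind, out[paste0(bands$band, "__reeg")]),
                     do.call(rbind, out[paste0(bands$band, "__spectral")]),
                     ib, rbind(fd))
  vals <- rowMeans(per_epoch, na.rm = TRUE)
  vals[is.nan(vals)] <- NA_real_
  setNames(vals, feature_block_names())
}

#' Extract features for every channel of a segment
#'
#' @param rec a (typically 16-channel bipolar) one-hour [recording].
#' @param ... passed to [extract_channel()].
#' @return channels-by-86 matrix with channel row names; flattening gives
#'   `86 * n_channels` named features (1376 for the full montage).
#' @export
extract_recording <- function(rec, ...) {
  out <- t(vapply(seq_len(nrow(rec$data)),
                  function(ch) extract_channel(rec$data[ch, ], rec$fs, ...),
                  numeric(86)))
  rownames(out) <- rec$labels
  out
}

flatten_features <- function(mat) {
  v <- as.vector(t(mat))
  names(v) <- as.vector(vapply(rownames(mat), function(ch)
    paste(ch, colnames(mat), sep = "__"), character(ncol(mat))))
  v
}

# One feature-table row from an extracted segment.
segment_row <- function(rec, mat) {
  meta <- data.frame(subject_id = rec$subject_id,
                     segment_index = attr(rec, "segment_index") %||% 1L,
                     pma_weeks = rec$pma_weeks, stringsAsFactors = FALSE)
  list(meta = meta, values = flatten_features(mat))
}

assemble_table <- function(rows) {
  meta <- do.call(rbind, lapply(rows, `[[`, "meta"))
  values <- do.call(rbind, lapply(rows, `[[`, "values"))
  feature_table(meta, values)
}

#' Stream a synthetic cohort into a feature table
#'
#' Generates, preprocesses and extracts one subject at a time so only one
#' raw recording is ever held in memory. One row per one-hour segment.
#'
#' @param cfg a [synth_config()].
#' @param preproc a [preproc_config()].
#' @param montage montage table.
#' @param verbose print per-subject progress.
#' @param ... passed to [extract_channel()].
#' @return an `fba_features` table.
#' @export
extract_cohort <- function(cfg = synth_config(), preproc = preproc_config(),
                           montage = neonatal_montage(), verbose = FALSE, ...) {
  labels <- synth_pma_labels(cfg)
  rows <- list()
  for (i in seq_len(cfg$n_subjects)) {
    g <- generate_recording(labels$pma_weeks[i], cfg, seed = derive_seed(cfg$seed, i),
                            subject_id = labels$subject_id[i])
    pp <- preprocess_recording(g$recording, preproc)
    for (seg in pp$segments) {
      bip <- build_bipolar(seg, montage)
      attr(bip, "segment_index") <- attr(seg, "segment_index")
      rows[[length(rows) + 1L]] <- segment_row(bip, extract_recording(bip, ...))
    }
    if (verbose) message(sprintf("extracted %s (%d/%d)", labels$subject_id[i], i, cfg$n_subjects))
  }
  assemble_table(rows)
}

#' Extract a feature table from a directory of EDF recordings
#'
#' Expects `<subject>.edf` files with matching `<subject>.json` sidecars
#' carrying `subject_id` and `pma_weeks`.
#'
#' @param dir directory of EDF + sidecar files.
#' @param preproc a [preproc_config()].
#' @param montage montage table.
#' @param ... passed to [extract_channel()].
#' @return an `fba_features` table.
#' @export
extract_dir <- function(dir, preproc = preproc_config(),
                        montage = neonatal_montage(), ...) {
  paths <- sort(list.files(dir, pattern = "\\.edf$", full.names = TRUE))
  if (!length(paths)) stop_value("no EDF files in %s", dir)
  rows <- list()
  for (p in paths) {
    sc <- sub("\\.edf$", ".json", p)
    rec <- read_edf(p, sidecar = if (file.exists(sc)) sc else NULL)
    pp <- preprocess_recording(rec, preproc)
    for (seg in pp$segments) {
      bip <- build_bipolar(seg, montage)
      attr(bip, "segment_index") <- attr(seg, "segment_index")
      rows[[length(rows) + 1L]] <- segment_row(bip, extract_recording(bip, ...))
    }
  }
  assemble_table(rows)
}
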