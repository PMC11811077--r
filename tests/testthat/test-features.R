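# Feature extractor: epoch grid, band filtering, and the five feature
# domains, checked against closed-form values on sines, constants and
# seeded noise.

test_that("epoching yields 119 epochs per hour and errors on short input", {
  ep <- epoch_signal(rnorm(3600 * 64), 64)
  expect_equal(dim(ep), c(3840, 119))
  expect_equal(ncol(epoch_signal(rnorm(90 * 64), 64)), 2)
  expect_error(epoch_signal(rnorm(59 * 64), 64), class = "neofba_value_error")
})

test_that("band filters separate tones into their bands", {
  fs <- 64
  t <- (seq_len(60 * fs) - 1) / fs
  s5 <- sin(2 * pi * 5 * t)
  expect_gt(sd(band_filter(s5, fs, 4, 7)) / sd(s5), 0.9)     # theta keeps 5 Hz
  expect_lt(sd(band_filter(s5, fs, 13, 30)) / sd(s5), 0.1)   # beta rejects it
  expect_equal(band_filter(numeric(640), fs, 4, 7), numeric(640))
  mix <- sin(2 * pi * 2 * t) + sin(2 * pi * 20 * t)
  expect_gt(cor(band_filter(mix, fs, 0.5, 4), sin(2 * pi * 2 * t)), 0.99)
})

test_that("amplitude features match closed forms on sines and noise", {
  fs <- 64
  t <- (seq_len(60 * fs) - 1) / fs
  s <- 2 * sin(2 * pi * 5 * t)
  a <- amplitude_features(s)
  expect_equal(unname(a["power"]), 2, tolerance = 0.01)      # A^2 / 2
  expect_equal(unname(a["env_mean"]), 2, tolerance = 0.02)   # |A|
  z <- amplitude_features(numeric(3840))
  expect_equal(unname(z[c("power", "env_mean")]), c(0, 0))
  expect_true(all(is.na(z[c("skewness", "kurtosis")])))
  set.seed(42)
  g <- amplitude_features(rnorm(3840))
  expect_lt(abs(g[["skewness"]]), 0.15)
  expect_lt(abs(g[["kurtosis"]]), 0.3)                       # excess convention
})

test_that("range-EEG features summarise per-segment peak-to-peak voltages", {
  fs <- 64
  r0 <- reeg_features(rep(3, 60 * fs), fs)
  expect_equal(unname(r0[c("mean", "median", "width")]), c(0, 0, 0))
  expect_true(is.na(r0[["cv"]]))                             # mean range 0
  t <- (seq_len(60 * fs) - 1) / fs
  rs <- reeg_features(3 * sin(2 * pi * 1 * t), fs)           # every 2 s segment = full cycles
  expect_equal(unname(rs["mean"]), 6, tolerance = 0.01)
  expect_equal(unname(rs["median"]), unname(rs["mean"]))
  expect_equal(unname(rs[c("width", "sd", "cv")]), c(0, 0, 0), tolerance = 1e-9)
  set.seed(7)
  rn <- reeg_features(rnorm(60 * fs), fs)
  # Monte-Carlo: E[max - min] of 128 iid N(0,1) is 5.17 (SD 0.59)
  expect_gt(rn[["mean"]], 4.5)
  expect_lt(rn[["mean"]], 5.9)
})

test_that("burst detection recovers constructed burst trains", {
  fs <- 64
  set.seed(3)
  quiet <- rnorm(3 * fs, sd = 3)
  burst <- rnorm(2 * fs, sd = 30)
  y <- c(rep(c(quiet, burst), 12))[1:(60 * fs)]              # bursts every 5 s
  ann <- detect_bursts(y, fs)
  expect_lte(abs(nrow(ann) - 12), 1)
  starts_true <- 3 + 5 * (0:11)
  matched <- vapply(seq_len(nrow(ann)), function(k)
    min(abs(ann[k, "start"] - starts_true)), numeric(1))
  expect_lt(max(matched), 0.25)
  expect_equal(nrow(detect_bursts(numeric(60 * fs), fs)), 0)
  solid <- detect_bursts(rep(30, 60 * fs), fs)               # sustained high amplitude
  expect_equal(nrow(solid), 1)
  expect_equal(unname(solid[1, ]), c(0, 60), tolerance = 0.02)
})

test_that("inter-burst interval arithmetic follows the definitions", {
  ann <- cbind(start = c(0, 5), end = c(2, 7))
  v <- ibi_features(ann, 10)
  expect_equal(unname(v[c("mean", "median", "sd", "burst_ratio")]), c(3, 3, 0, 0.4))
  none <- ibi_features(cbind(start = numeric(0), end = numeric(0)), 10)
  expect_equal(unname(none["burst_ratio"]), 0)
  expect_true(all(is.na(none[c("mean", "median", "sd", "cv")])))
  ann3 <- cbind(start = c(0, 4, 9), end = c(2, 6, 10))
  v3 <- ibi_features(ann3, 10)
  expect_equal(unname(v3[c("mean", "median", "burst_ratio")]), c(2.5, 2.5, 0.5))
})

test_that("spectral features distinguish white noise from tones", {
  fs <- 64
  set.seed(11)
  noise <- rnorm(60 * fs)
  bands <- band_defs()
  for (i in 1:4) {
    sf <- spectral_features(noise, fs, c(bands$lo[i], bands$hi[i]))
    expect_gt(sf[["wiener_entropy"]], 0.8)
  }
  tone <- sin(2 * pi * 10 * (seq_len(60 * fs) - 1) / fs)
  expect_lt(spectral_features(tone, fs, c(7, 13))[["wiener_entropy"]], 0.2)
  rel <- vapply(1:4, function(i)
    spectral_features(noise, fs, c(bands$lo[i], bands$hi[i]))[["rel_power"]],
    numeric(1))
  expect_equal(sum(rel), 1, tolerance = 0.05)
  zero <- spectral_features(numeric(60 * fs), fs, c(4, 7))
  expect_true(all(is.na(zero[c("wiener_entropy", "shannon_entropy", "sef95")])))
  # SEF95 of an in-band tone is (just above) the tone frequency
  expect_lt(abs(spectral_features(tone, fs, c(7, 13))[["sef95"]] - 10), 1)
})

test_that("Higuchi fractal dimension spans its smooth-to-noise range", {
  expect_equal(higuchi_fd(seq_len(3840)), 1, tolerance = 0.05)
  set.seed(5)
  expect_equal(higuchi_fd(rnorm(3840), warn = FALSE), 2, tolerance = 0.1)
  sine <- sin(2 * pi * 2 * (seq_len(3840) - 1) / 64)
  expect_lt(higuchi_fd(sine), 1.2)
  expect_equal(higuchi_fd(rep(4, 100)), 1)
  expect_error(higuchi_fd(rnorm(10), kmax = 6), class = "neofba_value_error")
})

test_that("the channel extractor produces the 86 named epoch-averaged features", {
  fs <- 64
  set.seed(20)
  x <- rnorm(3600 * fs, sd = 20)
  v <- extract_channel(x, fs)
  expect_length(v, 86)
  expect_false(any(duplicated(names(v))))
  info <- parse_feature_name(paste0("ch__", names(v)))
  expect_equal(sum(info$domain == "amplitude"), 24)
  expect_equal(sum(info$domain == "reeg"), 32)
  expect_equal(sum(info$domain == "spectral"), 24)
  expect_equal(sum(info$domain == "ibi"), 5)
  expect_equal(sum(info$domain == "nonlinear"), 1)
  # a 30 s periodic signal makes every epoch identical: the epoch average
  # equals the single-epoch value
  tile <- rep(x[1:(30 * fs)], 120)
  vt <- extract_channel(tile, fs)
  ep1 <- tile[1:(60 * fs)]
  expect_equal(vt[["delta__amplitude__power"]],
               unname(amplitude_features(band_filter(ep1, fs, 0.5, 4))["power"]),
               tolerance = 0.02)
  expect_equal(vt[["broadband__nonlinear__fd"]], higuchi_fd(ep1, warn = FALSE),
               tolerance = 0.02)
})

test_that("feature scale behaviour: homogeneity and scale invariants", {
  fs <- 64
  set.seed(31)
  cfg <- synth_config(fs = fs, duration_s = 3600, seed = 31)
  x <- generate_recording(34, cfg, seed = 31)$recording$data[1, ]
  v1 <- extract_channel(x, fs)
  v2 <- extract_channel(2 * x, fs)
  expect_equal(v2[["delta__amplitude__power"]], 4 * v1[["delta__amplitude__power"]],
               tolerance = 1e-6)
  expect_equal(v2[["theta__amplitude__env_mean"]], 2 * v1[["theta__amplitude__env_mean"]],
               tolerance = 1e-6)
  invariant <- c("delta__amplitude__skewness", "delta__amplitude__kurtosis",
                 "alpha__spectral__wiener_entropy", "beta__spectral__rel_power",
                 "theta__reeg__cv", "theta__reeg__asymmetry",
                 "broadband__nonlinear__fd")
  for (nm in invariant) {
    expect_equal(v2[[nm]], v1[[nm]], tolerance = 1e-6, label = nm)
  }
})

test_that("recording-level extraction flattens to 86 features per channel", {
  rec <- noise_recording(fs = 64, dur = 3600, seed = 14,
                         labels = c("Fp1-Fp2", "Fp1-T3", "Fp2-T4"))
  m <- extract_recording(rec)
  expect_equal(dim(m), c(3, 86))
  flat <- getFromNamespace("flatten_features", "neofba")(m)
  expect_length(flat, 258)
  expect_identical(parse_feature_name(names(flat))$channel,
                   rep(c("Fp1-Fp2", "Fp1-T3", "Fp2-T4"), each = 86))
})
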