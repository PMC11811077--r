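tone_rec <- function(freq, fs = 500, dur = 60, amp = 1) {
  t <- (seq_len(fs * dur) - 1) / fs
  recording(rbind(amp * sin(2 * pi * freq * t)), fs, "Fp1")
}

test_that("notch removes the mains tone and leaves the passband alone", {
  cfg <- preproc_config()
  out50 <- notch_filter(tone_rec(50), cfg)
  expect_lt(sd(out50$data[1, ]), 0.1 * sd(tone_rec(50)$data[1, ]))
  out10 <- notch_filter(tone_rec(10), cfg)
  expect_equal(sd(out10$data[1, ]) / sd(tone_rec(10)$data[1, ]), 1, tolerance = 0.1)
  z <- recording(rbind(numeric(1000)), 500, "Fp1")
  expect_equal(notch_filter(z, cfg)$data, z$data)
  lowfs <- recording(rbind(numeric(1000)), 64, "Fp1")
  expect_error(notch_filter(lowfs, cfg), class = "neofba_value_error")
})

test_that("resampling hits the exact sample count and preserves tones", {
  cfg <- preproc_config()
  rec <- tone_rec(5, fs = 500, dur = 60)
  out <- resample_to(rec, cfg)
  expect_equal(out$fs, 64)
  expect_equal(ncol(out$data), 60 * 64)
  ref <- sin(2 * pi * 5 * (seq_len(60 * 64) - 1) / 64)
  expect_gt(cor(out$data[1, ], ref), 0.999)
  # identity when already at the target rate
  at64 <- tone_rec(5, fs = 64, dur = 60)
  expect_identical(resample_to(at64, cfg)$data, at64$data)
  expect_error(resample_to(tone_rec(5, fs = 32), cfg), class = "neofba_value_error")
})

test_that("band-pass removes DC, keeps 10 Hz, attenuates 31 Hz", {
  cfg <- preproc_config()
  const <- recording(rbind(rep(5, 64 * 60)), 64, "Fp1")
  filtered <- bandpass_filter(const, cfg)
  expect_lt(max(abs(filtered$data)), 1e-6 * 5)
  g10 <- sd(bandpass_filter(tone_rec(10, 64), cfg)$data[1, ]) /
    sd(tone_rec(10, 64)$data[1, ])
  g31 <- sd(bandpass_filter(tone_rec(31, 64), cfg)$data[1, ]) /
    sd(tone_rec(31, 64)$data[1, ])
  expect_equal(g10, 1, tolerance = 0.05)
  expect_lt(g31, 0.5 * g10)
  # band edge at or above the recording's Nyquist frequency
  expect_error(bandpass_filter(tone_rec(10, fs = 50), cfg),
               class = "neofba_value_error")
})

test_that("filtering stages are idempotent on passband content", {
  cfg <- preproc_config()
  t <- (seq_len(64 * 120) - 1) / 64
  rec <- recording(rbind(sin(2 * pi * 2 * t) + sin(2 * pi * 10 * t) +
                           0.5 * sin(2 * pi * 20 * t)), 64, "Fp1")
  once <- bandpass_filter(rec, cfg)
  twice <- bandpass_filter(once, cfg)
  expect_lt(sqrt(mean((twice$data - once$data)^2)), 0.01 * sqrt(mean(once$data^2)))
  n1 <- notch_filter(tone_rec(10), cfg)
  n2 <- notch_filter(n1, cfg)
  expect_lt(sqrt(mean((n2$data - n1$data)^2)), 0.01 * sqrt(mean(n1$data^2)))
})

test_that("artifact suppression repairs spikes and passes clean data through", {
  cfg <- preproc_config()
  clean <- noise_recording(fs = 64, dur = 120, sd_uv = 10, seed = 12, labels = "Fp1")
  out <- suppress_artifacts(clean, cfg)
  expect_equal(nrow(out$mask), 0)
  expect_identical(out$recording$data, clean$data)

  spiky <- clean
  span <- 3200:3232                       # 0.5 s at 64 Hz
  spiky$data[1, span] <- spiky$data[1, span] + 500
  rep_out <- suppress_artifacts(spiky, cfg)
  expect_gt(nrow(rep_out$mask), 0)
  expect_true(any(rep_out$mask$start_s <= span[1] / 64 &
                    rep_out$mask$end_s >= span[length(span)] / 64))
  expect_lt(max(abs(rep_out$recording$data[1, span])), 5 * 10)

  zero <- recording(rbind(numeric(64 * 120)), 64, "Fp1")
  zout <- suppress_artifacts(zero, cfg)
  expect_identical(zout$recording$data, zero$data)
  expect_equal(nrow(zout$mask), 0)
})

test_that("segmentation cuts exact non-overlapping hours", {
  cfg <- preproc_config()
  long <- recording(matrix(rnorm(2 * 64 * 5.5 * 3600), nrow = 2), 64,
                    c("Fp1", "Fp2"))
  segs <- segment_hours(long, cfg)
  expect_length(segs, 5)
  for (s in segs) expect_equal(ncol(s$data), 64 * 3600)
  expect_equal(vapply(segs, attr, 0L, "segment_index"), 1:5)
  one <- recording(rbind(rnorm(64 * 3600)), 64, "Fp1")
  expect_length(segment_hours(one, cfg), 1)
  short <- recording(rbind(rnorm(64 * 3599)), 64, "Fp1")
  expect_warning(segs0 <- segment_hours(short, cfg), "shorter")
  expect_length(segs0, 0)
})

test_that("the fused pipeline equals the stage-by-stage path and keeps channel order", {
  rec <- noise_recording(fs = 250, dur = 120, seed = 13)
  cfg <- preproc_config(segment_s = 60)
  fused <- preprocess_recording(rec, cfg)
  staged <- bandpass_filter(resample_to(notch_filter(rec, cfg), cfg), cfg)
  expect_equal(fused$segments[[1]]$data, staged$data[, 1:(64 * 60)],
               tolerance = 1e-10)
  expect_identical(fused$segments[[1]]$labels, rec$labels)
  expect_length(fused$segments, 2)
})
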