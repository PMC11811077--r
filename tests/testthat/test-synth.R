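# The generator's maturation model: same seed => identical data; IBIs
# shorten, burst ratio rises and only designated electrodes carry the age
# signal.

short_cfg <- function(...) {
  synth_config(fs = 64, duration_s = 600, n_subjects = 30, seed = 21, ...)
}

test_that("generation is deterministic and dimensioned by fs * duration", {
  cfg <- short_cfg()
  a <- generate_recording(30, cfg, seed = 5)
  b <- generate_recording(30, cfg, seed = 5)
  expect_identical(a, b)
  expect_equal(ncol(a$recording$data), 64 * 600)
  expect_equal(nrow(a$recording$data), 12)
  c <- generate_recording(30, cfg, seed = 6)
  expect_false(identical(a$recording$data, c$recording$data))
  expect_error(generate_recording(20, cfg), class = "neofba_value_error")
})

test_that("cohort PMA labels cover every week of the range", {
  cfg <- synth_config(n_subjects = 14, fs = 64, duration_s = 2, seed = 3)
  co <- generate_cohort(cfg)
  expect_length(co$recordings, 14)
  expect_true(all(co$labels$pma_weeks >= 28 & co$labels$pma_weeks <= 40))
  expect_setequal(floor(co$labels$pma_weeks), 28:40)
  co2 <- generate_cohort(cfg)
  expect_identical(co$labels, co2$labels)
})

test_that("mean inter-burst interval shortens with PMA as configured", {
  cfg <- short_cfg()
  mean_ibi <- function(pma, seed) {
    tr <- generate_recording(pma, cfg, seed = seed)$truth
    iv <- tr$bursts[[1]]
    mean(iv[-1, 1] - iv[-nrow(iv), 2])
  }
  n <- 20
  at28 <- vapply(seq_len(n), function(i) mean_ibi(28, 100 + i), numeric(1))
  at40 <- vapply(seq_len(n), function(i) mean_ibi(40, 200 + i), numeric(1))
  expect_gt(mean(at28), mean(at40))
  gap <- mean(at28) - mean(at40)
  expected <- 12 * abs(cfg$ibi_slope)
  se <- sqrt(var(at28) / n + var(at40) / n)
  expect_lt(abs(gap - expected), 2 * se + 0.2)
})

test_that("ground-truth burst ratio rises with PMA (permutation test)", {
  cfg <- short_cfg()
  co <- generate_cohort(cfg)
  ratio <- vapply(co$truth, function(tr) {
    iv <- tr$bursts[[1]]
    sum(iv[, 2] - iv[, 1]) / cfg$duration_s
  }, numeric(1))
  pma <- co$labels$pma_weeks
  slope <- coef(lm(ratio ~ pma))[2]
  expect_gt(slope, 0)
  set.seed(1)
  perm <- replicate(999, abs(coef(lm(sample(ratio) ~ pma))[2]))
  expect_lt(mean(perm >= abs(slope)), 0.01)
})

test_that("only channels fed by informative electrodes share information with PMA", {
  cfg <- short_cfg()
  co <- generate_cohort(cfg)
  carriers <- co$truth[[1]]$carrier_channels
  pow <- t(vapply(co$recordings, function(r) {
    apply(build_bipolar(r)$data, 1L, var)
  }, numeric(16)))
  pma <- co$labels$pma_weeks
  mi_binned <- function(x, y, nb = 3) {
    bx <- cut(x, quantile(x, seq(0, 1, length.out = nb + 1)), include.lowest = TRUE)
    by <- cut(y, quantile(y, seq(0, 1, length.out = nb + 1)), include.lowest = TRUE)
    p <- table(bx, by) / length(x)
    px <- rowSums(p); py <- colSums(p)
    sum(p * log(p / outer(px, py)), na.rm = TRUE)
  }
  mi <- vapply(1:16, function(ch) mi_binned(pma, log(pow[, ch])), numeric(1))
  expect_gt(mean(mi[carriers]), mean(mi[-carriers]))
})

test_that("writing a cohort yields readable EDF + sidecar pairs", {
  cfg <- synth_config(n_subjects = 2, fs = 64, duration_s = 10, seed = 9)
  co <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  paths <- write_cohort_edf(co, dir)
  expect_length(list.files(dir, pattern = "\\.edf$"), 2)
  back <- read_edf(paths[1], sidecar = sub("\\.edf$", ".json", paths[1]))
  expect_equal(back$pma_weeks, co$labels$pma_weeks[1])
  expect_lt(max(abs(back$data - co$recordings[[1]]$data)),
            1e-4 * max(abs(co$recordings[[1]]$data)))
})

test_that("feature-level generator confines signal to designated channels", {
  tbl <- synth_feature_table(n_subjects = 200, channels = c(1, 2, 6),
                             informative_channels = 6, n_features = 3,
                             n_informative = 2, effect = 2, seed = 4)
  expect_equal(nrow(tbl), 200)
  expect_equal(length(setdiff(names(tbl), c("subject_id", "segment_index", "pma_weeks"))), 9)
  r2 <- r2_table(as.matrix(tbl[, -(1:3)]), tbl$pma_weeks)
  info <- parse_feature_name(r2$feature)
  # the two top-correlated features sit on the informative channel
  expect_true(all(info$channel[1:2] == "Fp1-Fp2"))
  expect_true(all(r2$r2[1:2] > 0.5))
  expect_true(all(r2$r2[info$channel != "Fp1-Fp2"] < 0.15))
})
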