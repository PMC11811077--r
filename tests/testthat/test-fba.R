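# The fba() fit object: end-to-end behaviour on feature-level cohorts and
# the disk-artifact pipeline.

fast_control <- function() {
  fba_control(swarm = swarm_config(particles = 8, iterations = 6),
              search_grid = tiny_grid(), final_grid = tiny_grid())
}

test_that("fba() selects informative channels and predicts held-out subjects", {
  tbl <- synth_feature_table(n_subjects = 60, channels = c(1, 2, 6, 7, 10),
                             informative_channels = c(6, 7), effect = 1.5,
                             seed = 2)
  fit <- fba(tbl, channel_method = "bpso_fa_be", feature_method = "pcc_rfe_svr",
             seed = 11, control = fast_control())
  expect_s3_class(fit, "fba")
  expect_true(all(c(6, 7) %in% fit$channels))
  expect_lt(fit$test$mae, 0.5 * sd(tbl$pma_weeks[tbl$subject_id %in% fit$split$test]))
  # segment- and subject-level prediction
  te <- tbl[tbl$subject_id %in% fit$split$test, ]
  class(te) <- class(tbl)
  p <- predict(fit, te)
  expect_length(p, nrow(te))
  ps <- predict(fit, te, aggregate = "subject")
  expect_length(ps, length(unique(te$subject_id)))
  # methods run
  expect_output(print(fit), "Functional brain age")
  expect_output(summary(fit), "Channel search")
  expect_length(residuals(fit), nrow(te))
  grDevices::pdf(NULL); on.exit(grDevices::dev.off())
  expect_silent(plot(fit))
})

test_that("fba() is reproducible from its seed", {
  tbl <- synth_feature_table(n_subjects = 40, channels = c(2, 6, 9),
                             informative_channels = 6, seed = 5)
  f1 <- fba(tbl, channel_method = "fa", feature_method = "pcc_svr",
            seed = 3, control = fast_control())
  f2 <- fba(tbl, channel_method = "fa", feature_method = "pcc_svr",
            seed = 3, control = fast_control())
  expect_identical(f1$split, f2$split)
  expect_identical(f1$channels, f2$channels)
  expect_identical(f1$features, f2$features)
  expect_equal(f1$test$mae, f2$test$mae)
})

test_that("coef() exposes weights only for linear-kernel SVR fits", {
  tbl <- synth_feature_table(n_subjects = 40, channels = 6,
                             informative_channels = 6, seed = 8)
  fit <- fba(tbl, channel_method = "none", feature_method = "none",
             seed = 2, control = fba_control(
               search_grid = tiny_grid(),
               final_grid = data.frame(C = 1, gamma = "scale", kernel = "linear")))
  w <- coef(fit)
  expect_length(w, length(fit$features))
  expect_named(w)
})

test_that("the pipeline writes artifacts, reruns identically and regenerates", {
  out <- file.path(withr::local_tempdir(), "run")
  cfg <- list(seed = 5, out_dir = out,
              synth = list(n_subjects = 6, fs = 128, duration_s = 3600,
                           informative_channels = c(6, 7, 9)),
              fba = list(channel_method = "fa", feature_method = "none"))
  ctl <- fast_control()
  ctl$folds <- 3                      # six-subject smoke cohort
  fit <- run_pipeline(cfg, control = ctl)
  arts <- attr(fit, "artifacts")
  expect_true(all(file.exists(arts)))
  report1 <- readBin(file.path(out, "report.json"), "raw",
                     file.size(file.path(out, "report.json")))
  tbl <- read_feature_table(file.path(out, "features.csv"))
  expect_equal(nrow(tbl), 6)
  expect_equal(length(setdiff(names(tbl), c("subject_id", "segment_index",
                                            "pma_weeks"))), 1376)
  # unchanged config: cached features, byte-identical report
  run_pipeline(cfg, control = ctl)
  report2 <- readBin(file.path(out, "report.json"), "raw", length(report1))
  expect_identical(report1, report2)
  # deleting the feature table forces regeneration to the identical state
  file.remove(file.path(out, "features.csv"), file.path(out, "config.json"))
  run_pipeline(cfg, control = ctl)
  tbl2 <- read_feature_table(file.path(out, "features.csv"))
  expect_equal(as.matrix(tbl2[, -(1:3)]), as.matrix(tbl[, -(1:3)]),
               tolerance = 1e-12)
  report3 <- readBin(file.path(out, "report.json"), "raw", length(report1))
  expect_identical(report1, report3)
})
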