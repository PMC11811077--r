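test_that("MAE is the mean absolute error in weeks", {
  expect_equal(mae(c(30, 34), c(30, 34)), 0)
  expect_equal(mae(c(30, 34), c(31, 33)), 1)
  expect_equal(mae(28, 40), 12)
  expect_error(mae(1:3, 1:2), class = "neofba_value_error")
})

test_that("the full SVR grid enumerates 198 candidates in canonical order", {
  g <- svr_grid()
  expect_equal(nrow(g), 198)
  expect_equal(length(unique(g$C)), 11)
  expect_equal(min(g$C), 0.01)
  expect_equal(max(g$C), 1.01)
  expect_setequal(unique(g$gamma), c("scale", "auto", "0.01", "0.1", "0.5", "1"))
  expect_setequal(unique(g$kernel), c("linear", "rbf", "poly"))
  expect_equal(g$C[1], 0.01)                 # ties resolve toward smallest C
  expect_equal(g$kernel[1], "linear")
})

test_that("grouped folds never split a subject and stay PMA-balanced", {
  subj <- rep(sprintf("s%02d", 1:20), each = 3)
  y <- rep(seq(28, 40, length.out = 20), each = 3)
  f <- make_folds(subj, y, k = 5, seed = 2)
  expect_length(f, 60)
  per_subj <- tapply(f, subj, function(v) length(unique(v)))
  expect_true(all(per_subj == 1))
  expect_equal(sort(unique(f)), 1:5)
  spread <- tapply(y, f, mean)
  expect_lt(max(spread) - min(spread), 3)
  expect_identical(f, make_folds(subj, y, k = 5, seed = 2))
})

test_that("grid-searched SVR finds a near-perfect linear relationship", {
  set.seed(8)
  X <- matrix(rnorm(60 * 5), 60)
  colnames(X) <- paste0("f", 1:5)
  y <- 34 + 3 * X[, 2] + rnorm(60, sd = 0.05)
  fit <- fit_svr_grid(X, y, grid = tiny_grid(), seed = 1)
  expect_s3_class(fit, "fba_svr")
  expect_lt(fit$cv_mae, 0.1 * sd(y))
  expect_equal(length(predict(fit, X[1:4, ])), 4)
  # determinism
  fit2 <- fit_svr_grid(X, y, grid = tiny_grid(), seed = 1)
  expect_identical(fit$grid_row, fit2$grid_row)
  expect_equal(fit$cv_mae, fit2$cv_mae)
  # constant labels degrade to a constant predictor with a warning
  expect_warning(cfit <- fit_svr_grid(X, rep(34, 60), grid = tiny_grid()), "constant")
  expect_equal(unique(predict(cfit, X)), 34)
})

test_that("every supported model beats the mean predictor on easy data", {
  tbl <- synth_feature_table(n_subjects = 60, channels = c(6, 7),
                             informative_channels = c(6, 7), effect = 2, seed = 9)
  X <- as.matrix(tbl[, -(1:3)])
  y <- tbl$pma_weeks
  tr <- 1:42
  base <- mae(y[-tr], rep(mean(y[tr]), length(y) - length(tr)))
  for (nm in c("svr", "rf", "gbdt")) {
    args <- list(nm, X[tr, ], y[tr], groups = tbl$subject_id[tr], seed = 3)
    if (nm == "svr") args$grid <- tiny_grid()
    fit <- do.call(fit_model, args)
    expect_lt(mae(y[-tr], predict(fit, X[-tr, ])), base, label = nm)
  }
  rf1 <- fit_model("rf", X[tr, ], y[tr], seed = 5)
  rf2 <- fit_model("rf", X[tr, ], y[tr], seed = 5)
  expect_identical(predict(rf1, X[-tr, ]), predict(rf2, X[-tr, ]))
  expect_error(fit_model("lgbm", X[tr, ], y[tr]), class = "neofba_value_error")
})

test_that("error reports bin, score and flag outliers as defined", {
  y <- c(30, 30, 30, 30, 30)
  pred <- y + c(-3, -1.5, 0, 1.5, 3)
  rep1 <- error_report(y, pred)
  expect_equal(unname(rep1$bins), c(1, 1, 1, 1, 1))
  expect_equal(rep1$accuracy_2wk, 60)
  expect_equal(rep1$accuracy_1wk, 20)
  expect_equal(sum(rep1$bins), rep1$n)

  rep0 <- error_report(c(30, 38), c(30, 38))
  expect_equal(rep0$accuracy_1wk, 100)
  expect_equal(rep0$accuracy_2wk, 100)
  expect_equal(rep0$mae, 0)

  # boundary errors are assigned inward
  repb <- error_report(rep(30, 4), rep(30, 4) + c(-2, -1, 1, 2))
  expect_equal(unname(repb$bins), c(0, 1, 2, 1, 0))

  # a gross error within one PMA group trips the 1.5 IQR rule
  y2 <- rep(29, 5)
  rep2 <- error_report(y2, y2 + c(0.1, 0, -0.1, 0.05, 10))
  expect_equal(unname(rep2$per_group[["28-30"]]$outliers), 10)

  set.seed(1)
  for (i in 1:20) {
    e <- rnorm(50, sd = 2)
    r <- error_report(rep(34, 50), 34 + e)
    expect_lte(r$accuracy_1wk, r$accuracy_2wk)
  }
  expect_error(error_report(1:3, 1:2), class = "neofba_value_error")
})
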