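# The one-call model: subject-wise split, wrapper channel selection,
# PCC-RFE-SVR feature selection and a grid-searched regression model,
# returned as a classed fit with the usual methods.

#' Control parameters for [fba()]
#'
#' @param swarm,anneal,genetic search configurations (see [swarm_config()],
#'   [anneal_config()], [genetic_config()]). The swarm default here is a
#'   compact search (16 particles, 12 iterations) sized for cohorts of tens
#'   of subjects; pass the full-scale configuration for larger studies.
#' @param search_grid SVR grid used inside subset/feature search loops.
#' @param final_grid SVR grid for the final model fit (the full 198-candidate
#'   grid).
#' @param folds CV folds.
#' @param pcc_threshold redundancy-filter threshold.
#' @param train_fraction subject-wise training fraction.
#' @return a list of class `fba_control`.
#' @export
fba_control <- function(swarm = swarm_config(particles = 16, iterations = 12),
                        anneal = anneal_config(), genetic = genetic_config(),
                        search_grid = wrapper_grid(), final_grid = svr_grid(),
                        folds = 5, pcc_threshold = 0.9, train_fraction = 0.7) {
  structure(as.list(environment()), class = "fba_control")
}

#' Fit a functional brain age model
#'
#' End-to-end fit on a feature table: subjects are split 7:3 within integer
#' PMA-week strata (segments of one subject never straddle the split),
#' channels are selected by a wrapper search scored with grouped 5-fold CV
#' MAE on the training partition, features of the selected channels are
#' selected by PCC filtering plus SVR-based recursive feature elimination,
#' and the final regression model is trained with a full hyperparameter
#' grid search. The held-out test partition is scored once, at the end.
#'
#' @param tbl an `fba_features` table (rows = one-hour segments).
#' @param channel_method `"bpso_fa_be"` (default), `"fa"`, `"be"`,
#'   `"ga_fa_be"`, `"sa_fa_be"` or `"none"` (keep all channels).
#' @param feature_method `"pcc_rfe_svr"` (default), `"pcc_svr"`,
#'   `"rfe_svr"` or `"none"`.
#' @param cross_channel_mode how multi-channel features enter the model:
#'   `"concat"` (default), `"median"` or `"mean"`.
#' @param model final regression model (`"svr"`, `"rf"`, `"gbdt"`).
#' @param seed master seed: split, folds and searches all derive from it.
#' @param split optional precomputed list with `train`/`test` subject ids.
#' @param control an [fba_control()].
#' @return an object of class `fba`; see [predict.fba()],
#'   [summary.fba()], [plot.fba()].
#' @examples
#' tbl <- synth_feature_table(n_subjects = 30, channels = 1:4,
#'                            informative_channels = 2, seed = 1)
#' fit <- fba(tbl, channel_method = "fa", feature_method = "none", seed = 1)
#' print(fit)
#' @export
fba <- function(tbl,
                channel_method = c("bpso_fa_be", "fa", "be", "ga_fa_be",
                                   "sa_fa_be", "none"),
                feature_method = c("pcc_rfe_svr", "pcc_svr", "rfe_svr", "none"),
                cross_channel_mode = c("concat", "median", "mean"),
                model = "svr", seed = 7, split = NULL,
                control = fba_control()) {
  channel_method <- match.arg(channel_method)
  feature_method <- match.arg(feature_method)
  cross_channel_mode <- match.arg(cross_channel_mode)
  stopifnot(inherits(tbl, "fba_features"))
  cl <- match.call()

  labels <- unique(tbl[c("subject_id", "pma_weeks")])
  if (is.null(split)) {
    split <- split_subjects(labels, control$train_fraction, seed = derive_seed(seed, 1))
  }
  tr_tbl <- tbl[tbl$subject_id %in% split$train, ]
  te_tbl <- tbl[tbl$subject_id %in% split$test, ]
  class(tr_tbl) <- class(te_tbl) <- class(tbl)

  cv_seed <- derive_seed(seed, 2)
  cache <- subset_cache()
  channels_res <- switch(
    channel_method,
    none = NULL,
    fa = forward_addition(tr_tbl, cv_seed = cv_seed, grid = control$search_grid,
                          folds = control$folds, cache = cache),
    be = backward_elimination(tr_tbl, cv_seed = cv_seed, grid = control$search_grid,
                              folds = control$folds, cache = cache),
    bpso_fa_be = {
      cfg <- control$swarm; cfg$seed <- derive_seed(seed, 3)
      bpso_fa_be(tr_tbl, cfg, cv_seed = cv_seed, grid = control$search_grid,
                 folds = control$folds, cache = cache)
    },
    ga_fa_be = {
      cfg <- control$genetic; cfg$seed <- derive_seed(seed, 3)
      ga_select(tr_tbl, cfg, cv_seed = cv_seed, grid = control$search_grid,
                folds = control$folds, cache = cache)
    },
    sa_fa_be = {
      cfg <- control$anneal; cfg$seed <- derive_seed(seed, 3)
      sa_select(tr_tbl, cfg, cv_seed = cv_seed, grid = control$search_grid,
                folds = control$folds, cache = cache)
    })
  channels <- if (is.null(channels_res)) table_channels(tbl) else
    channels_res$best$channels

  tr_x <- cross_channel(tr_tbl, cross_channel_mode, channels)
  Xtr <- feature_matrix(tr_x)
  ytr <- tr_x$pma_weeks
  gtr <- tr_x$subject_id

  features_res <- NULL
  if (feature_method != "none" && ncol(Xtr) >= 2L) {
    features_res <- select_features(Xtr, ytr, method = feature_method,
                                    groups = gtr, threshold = control$pcc_threshold,
                                    cv_seed = cv_seed, grid = control$search_grid,
                                    folds = control$folds)
    Xtr <- Xtr[, features_res$selected, drop = FALSE]
  }

  fit <- if (model == "svr") {
    fit_model("svr", Xtr, ytr, gtr, seed = cv_seed, grid = control$final_grid,
              folds = control$folds)
  } else fit_model(model, Xtr, ytr, gtr, seed = cv_seed)

  train_cv_mae <- if (!is.null(features_res)) min(features_res$curve$mae) else
    if (model == "svr") fit$fit$cv_mae else NA_real_

  obj <- structure(list(
    call = cl, seed = seed, split = split,
    channel_method = channel_method, feature_method = feature_method,
    cross_channel_mode = cross_channel_mode, model_name = model,
    channels = channels, channels_result = channels_res,
    features = colnames(Xtr), features_result = features_res,
    fit = fit, train_cv_mae = train_cv_mae,
    train_fitted = predict(fit, Xtr), train_y = ytr), class = "fba")

  if (nrow(te_tbl)) {
    pred <- predict(obj, te_tbl)
    obj$test <- error_report(te_tbl$pma_weeks, pred)
    obj$test_predictions <- data.frame(subject_id = te_tbl$subject_id,
                                       segment_index = te_tbl$segment_index,
                                       pma_weeks = te_tbl$pma_weeks,
                                       fba_weeks = pred)
  }
  obj
}

#' Predict functional brain age for new segments
#'
#' Applies the fitted channel subset, cross-channel processing, selected
#' features and regression model to a new feature table.
#'
#' @param object an [fba()] fit.
#' @param newdata an `fba_features` table with the fitted channels present.
#' @param aggregate `"segment"` (default: one prediction per row) or
#'   `"subject"` (median of a subject's segment predictions).
#' @param ... unused.
#' @return numeric vector of predicted FBA in weeks (named by subject when
#'   aggregating).
#' @export
predict.fba <- function(object, newdata, aggregate = c("segment", "subject"), ...) {
  aggregate <- match.arg(aggregate)
  x <- cross_channel(newdata, object$cross_channel_mode, object$channels)
  X <- feature_matrix(x)[, object$features, drop = FALSE]
  p <- predict(object$fit, X)
  if (aggregate == "subject") {
    p <- tapply(p, newdata$subject_id, median)
    return(p[unique(newdata$subject_id)])
  }
  p
}

#' @export
print.fba <- function(x, ...) {
  cat("Functional brain age model (", x$model_name, ")\n", sep = "")
  cat(sprintf("  subjects: %d train / %d test | channel search: %s | feature search: %s\n",
              length(x$split$train), length(x$split$test),
              x$channel_method, x$feature_method))
  cat(sprintf("  channels selected: {%s} | features: %d\n",
              paste(x$channels, collapse = ","), length(x$features)))
  if (!is.na(x$train_cv_mae)) {
    cat(sprintf("  training CV MAE: %.3f wk\n", x$train_cv_mae))
  }
  if (!is.null(x$test)) {
    cat(sprintf("  test MAE: %.3f wk | within 1 wk: %.2f%% | within 2 wk: %.2f%%\n",
                x$test$mae, x$test$accuracy_1wk, x$test$accuracy_2wk))
  }
  invisible(x)
}

#' Summarise an FBA fit
#' @param object an [fba()] fit.
#' @param ... unused.
#' @return `object`, invisibly; prints the per-cardinality channel table,
#'   the selection curve optimum, chosen hyperparameters and the test
#'   error report.
#' @export
summary.fba <- function(object, ...) {
  print(object)
  if (!is.null(object$channels_result)) {
    cat("\nChannel search (per-cardinality best):\n")
    print(object$channels_result)
  }
  if (!is.null(object$features_result)) {
    cat("\nFeature selection:\n")
    print(object$features_result)
  }
  if (object$model_name == "svr" && !is.null(object$fit$fit$grid_row)) {
    gr <- object$fit$fit$grid_row
    cat(sprintf("\nSVR hyperparameters: kernel=%s C=%.2f gamma=%s\n",
                gr$kernel, gr$C, gr$gamma))
  }
  if (!is.null(object$test)) { cat("\nTest set:\n"); print(object$test) }
  invisible(object)
}

#' @export
coef.fba <- function(object, ...) {
  if (object$model_name != "svr" || is.null(object$fit$fit$model) ||
      object$fit$fit$grid_row$kernel != "linear") {
    message("coefficients are only available for a linear-kernel SVR fit")
    return(invisible(NULL))
  }
  m <- object$fit$fit$model
  setNames(as.vector(t(m$coefs) %*% m$SV), object$features)
}

#' @export
residuals.fba <- function(object, ...) {
  if (is.null(object$test)) return(object$train_fitted - object$train_y)
  object$test$errors
}

#' Plot an FBA fit
#'
#' Left: cross-validated MAE of the best channel subset at each
#' cardinality; right: the feature-selection curve (CV MAE against number
#' of features) with the chosen optimum.
#'
#' @param x an [fba()] fit.
#' @param ... unused.
#' @export
plot.fba <- function(x, ...) {
  has_ch <- !is.null(x$channels_result)
  has_fs <- !is.null(x$features_result)
  if (has_ch && has_fs) {
    op <- par(mfrow = c(1, 2)); on.exit(par(op))
  }
  if (has_ch) {
    df <- x$channels_result$per_cardinality
    plot(df$m, df$mae, type = "b", xlab = "number of channels",
         ylab = "CV MAE (weeks)", main = "channel selection")
  }
  if (has_fs) plot(x$features_result, main = "feature selection")
  if (!has_ch && !has_fs) message("nothing to plot: no search results stored")
  invisible(x)
}
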