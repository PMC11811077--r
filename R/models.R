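# Regression models and evaluation: MAE, grouped stratified CV folds, the
# grid-searched SVR, alternative tree ensembles, error-distribution report.

#' Mean absolute error in weeks
#' @param y_true,y_pred actual and predicted FBA (weeks).
#' @return mean of `|y_true - y_pred|`.
#' @export
mae <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop_value("length mismatch: %d vs %d", length(y_true), length(y_pred))
  }
  if (!length(y_true)) stop_value("empty input")
  mean(abs(y_true - y_pred))
}

#' SVR hyperparameter grids
#'
#' `svr_grid()` is the full search grid: cost C from 0.01 in steps of 0.1
#' up to 1.01 (11 values), gamma in {scale, auto, 0.01, 0.1, 0.5, 1} and
#' kernels {linear, rbf, poly} -- 198 candidates, enumerated C-major so
#' ties resolve to the smallest C first. `wrapper_grid()` is the compact
#' grid used inside subset-search loops, where the SVR is refit thousands
#' of times; it spans the same C range coarsely with linear and RBF
#' kernels.
#'
#' @return data frame with columns `C`, `gamma` (character), `kernel`.
#' @export
svr_grid <- function() {
  g <- expand.grid(kernel = c("linear", "rbf", "poly"),
                   gamma = c("scale", "auto", "0.01", "0.1", "0.5", "1"),
                   C = seq(0.01, 1.09, by = 0.1),
                   stringsAsFactors = FALSE)
  g <- g[order(g$C, match(g$gamma, c("scale", "auto", "0.01", "0.1", "0.5", "1")),
               match(g$kernel, c("linear", "rbf", "poly"))), ]
  rownames(g) <- NULL
  g[, c("C", "gamma", "kernel")]
}

#' @rdname svr_grid
#' @export
wrapper_grid <- function() {
  data.frame(C = c(0.11, 1.01, 0.11, 0.51, 1.01),
             gamma = "scale",
             kernel = c("linear", "linear", "rbf", "rbf", "rbf"),
             stringsAsFactors = FALSE)
}

# gamma heuristics as used by scikit-learn: "scale" = 1/(d * Var(X)) with
# the population variance of all matrix entries; "auto" = 1/d.
resolve_gamma <- function(gamma, X) {
  if (gamma == "scale") {
    v <- mean(X^2) - mean(X)^2
    return(1 / (ncol(X) * max(v, 1e-12)))
  }
  if (gamma == "auto") return(1 / ncol(X))
  as.numeric(gamma)
}

svm_kernel_name <- function(k) {
  switch(k, linear = "linear", rbf = "radial", poly = "polynomial",
         stop_value("unknown kernel: %s", k))
}

fit_svm_row <- function(X, y, row) {
  e1071::svm(X, y, type = "eps-regression",
             kernel = svm_kernel_name(row$kernel),
             cost = row$C, gamma = resolve_gamma(row$gamma, X),
             scale = FALSE)
}

#' Grouped, PMA-stratified cross-validation folds
#'
#' Assigns each *subject* to one of `k` folds: subjects are ordered by
#' label, shuffled within the ordering, and dealt round-robin, giving folds
#' balanced in PMA with no subject split across folds.
#'
#' @param groups subject identifier per row.
#' @param y label per row (weeks).
#' @param k number of folds.
#' @param seed RNG seed.
#' @return integer fold id per row.
#' @export
make_folds <- function(groups, y, k = 5, seed = 1) {
  subj <- unique(groups)
  ylab <- vapply(subj, function(s) mean(y[groups == s]), numeric(1))
  with_seed(seed, {
    ord <- order(ylab + runif(length(subj)) * 1e-9)
    fold_of <- integer(length(subj))
    fold_of[ord] <- rep(seq_len(k), length.out = length(subj))
    fold_of[match(groups, subj)]
  })
}

# Median imputation parameters from a training matrix. A complete matrix
# yields NULL so the (common) no-missing-data case costs nothing.
impute_fit <- function(X) {
  if (!anyNA(X)) return(NULL)
  med <- apply(X, 2L, median, na.rm = TRUE)
  med[!is.finite(med)] <- 0
  med
}

impute_apply <- function(X, med) {
  if (!anyNA(X)) return(X)
  if (is.null(med)) {
    # training data were complete; impute new-data gaps from its own columns
    med <- apply(X, 2L, median, na.rm = TRUE)
    med[!is.finite(med)] <- 0
  }
  for (j in which(colSums(is.na(X)) > 0L)) X[is.na(X[, j]), j] <- med[j]
  X
}

# Candidate-wise CV MAE over grouped folds. Standardisation and imputation
# are refit inside every training fold so no test-fold information leaks.
cv_candidate_mae <- function(X, y, groups, grid, folds = 5, seed = 1) {
  fid <- make_folds(groups, y, k = folds, seed = seed)
  err <- matrix(NA_real_, nrow = nrow(grid), ncol = folds)
  for (f in sort(unique(fid))) {
    tr <- fid != f
    med <- impute_fit(X[tr, , drop = FALSE])
    Xtr <- impute_apply(X[tr, , drop = FALSE], med)
    Xte <- impute_apply(X[!tr, , drop = FALSE], med)
    zs <- suppressWarnings(zscore_fit(Xtr))
    Xtr <- zscore_apply(Xtr, zs)
    Xte <- zscore_apply(Xte, zs)
    for (g in seq_len(nrow(grid))) {
      m <- fit_svm_row(Xtr, y[tr], grid[g, ])
      err[g, f] <- mae(y[!tr], predict(m, Xte))
    }
  }
  rowMeans(err, na.rm = TRUE)
}

#' Grid-searched support vector regression
#'
#' Exhaustively evaluates every grid candidate by grouped 5-fold
#' cross-validated MAE (ties break to the first candidate in grid order),
#' then refits the winner on the full training data. Imputation and
#' z-scoring are part of the fitted object and are applied to new data at
#' prediction time.
#'
#' @param X training feature matrix.
#' @param y training labels (weeks).
#' @param groups subject id per row (for grouped folds); defaults to one
#'   group per row.
#' @param grid candidate grid, see [svr_grid()].
#' @param folds number of CV folds.
#' @param seed fold seed.
#' @return an object of class `fba_svr` with elements `model`, `grid_row`,
#'   `cv_mae` (winner's CV MAE), `candidates` (per-candidate CV MAE).
#' @export
fit_svr_grid <- function(X, y, groups = seq_along(y), grid = svr_grid(),
                         folds = 5, seed = 1) {
  X <- as.matrix(X)
  if (nrow(X) < folds) stop_value("need at least %d rows for %d-fold CV", folds, folds)
  if (var(y) == 0) {
    warning("constant labels: returning a constant predictor")
    return(structure(list(constant = y[1], cv_mae = 0, grid_row = NULL,
                          candidates = NULL), class = "fba_svr"))
  }
  cand <- cv_candidate_mae(X, y, groups, grid, folds, seed)
  best <- which.min(cand)          # first minimum in canonical grid order
  med <- impute_fit(X)
  Xi <- impute_apply(X, med)
  zs <- suppressWarnings(zscore_fit(Xi))
  model <- fit_svm_row(zscore_apply(Xi, zs), y, grid[best, ])
  structure(list(model = model, zscore = zs, impute = med,
                 grid_row = grid[best, ], cv_mae = cand[best],
                 candidates = cbind(grid, cv_mae = cand)),
            class = "fba_svr")
}

#' @export
predict.fba_svr <- function(object, newdata, ...) {
  if (!is.null(object$constant)) return(rep(object$constant, nrow(as.matrix(newdata))))
  X <- impute_apply(as.matrix(newdata), object$impute)
  unname(predict(object$model, zscore_apply(X, object$zscore)))
}

#' @export
print.fba_svr <- function(x, ...) {
  if (!is.null(x$constant)) {
    cat(sprintf("<fba_svr> constant predictor (%.3f)\n", x$constant))
  } else {
    cat(sprintf("<fba_svr> kernel=%s C=%.2f gamma=%s | CV MAE %.3f wk\n",
                x$grid_row$kernel, x$grid_row$C, x$grid_row$gamma, x$cv_mae))
  }
  invisible(x)
}

#' Fit one of the supported regression models
#'
#' `"svr"` delegates to [fit_svr_grid()]; `"rf"` (random forest) and
#' `"gbdt"` (gradient-boosted trees via xgboost) use fixed, documented
#' defaults with a seed. All returned objects predict FBA in weeks via
#' `predict(fit, newdata)`.
#'
#' @param name one of `"svr"`, `"rf"`, `"gbdt"`.
#' @param X training matrix.
#' @param y training labels (weeks).
#' @param groups subject ids (SVR fold grouping).
#' @param seed RNG / fold seed.
#' @param ... extra arguments passed to the underlying fitter.
#' @return a fitted model of class `fba_model`.
#' @export
fit_model <- function(name, X, y, groups = seq_along(y), seed = 1, ...) {
  X <- as.matrix(X)
  med <- impute_fit(X)
  Xi <- impute_apply(X, med)
  fit <- switch(
    name,
    svr = fit_svr_grid(Xi, y, groups, seed = seed, ...),
    rf = with_seed(seed, randomForest::randomForest(Xi, y, ntree = 500, ...)),
    gbdt = with_seed(seed, xgboost::xgboost(
      Xi, y, nrounds = 150, learning_rate = 0.1, max_depth = 3,
      subsample = 0.8, nthreads = 1, verbosity = 0, seed = seed, ...)),
    stop_value("unknown model '%s' (supported: svr, rf, gbdt)", name))
  structure(list(name = name, fit = fit, impute = med), class = "fba_model")
}

#' @export
predict.fba_model <- function(object, newdata, ...) {
  X <- impute_apply(as.matrix(newdata), object$impute)
  if (object$name == "gbdt") return(unname(predict(object$fit, X)))
  unname(predict(object$fit, X))
}

#' Prediction-error distribution report
#'
#' Errors are predicted minus actual FBA. Errors are binned into
#' `(-Inf, -2)`, `[-2, -1)`, `[-1, 1]`, `(1, 2]`, `(2, Inf)` weeks (ties at
#' the +/-1 and +/-2 boundaries assigned inward), accuracies within +/-1
#' and +/-2 weeks are percentages, and per-PMA-group (28--30, 31--33,
#' 34--37, 38--40 weeks) five-number summaries with 1.5 IQR outliers are
#' attached when PMA labels are supplied.
#'
#' @param y_true,y_pred actual and predicted FBA (weeks).
#' @param pma PMA per sample for grouping (defaults to `y_true`).
#' @return a list of class `fba_error_report`.
#' @export
error_report <- function(y_true, y_pred, pma = y_true) {
  if (length(y_true) != length(y_pred)) {
    stop_value("length mismatch: %d vs %d", length(y_true), length(y_pred))
  }
  e <- y_pred - y_true
  bins <- c(`<-2` = sum(e < -2), `[-2,-1)` = sum(e >= -2 & e < -1),
            `[-1,1]` = sum(e >= -1 & e <= 1), `(1,2]` = sum(e > 1 & e <= 2),
            `>2` = sum(e > 2))
  groups <- list(`28-30` = c(28, 30), `31-33` = c(31, 33),
                 `34-37` = c(34, 37), `38-40` = c(38, 40))
  per_group <- list()
  for (gname in names(groups)) {
    gr <- groups[[gname]]
    inb <- !is.na(pma) & floor(pma) >= gr[1] & floor(pma) <= gr[2]
    if (!any(inb)) next
    ge <- e[inb]
    q <- unname(quantile(ge, c(0, 0.25, 0.5, 0.75, 1)))
    iqr <- q[4] - q[2]
    out_lo <- q[2] - 1.5 * iqr; out_hi <- q[4] + 1.5 * iqr
    per_group[[gname]] <- list(n = sum(inb),
                               min = q[1], q1 = q[2], median = q[3],
                               q3 = q[4], max = q[5],
                               outliers = ge[ge < out_lo | ge > out_hi])
  }
  structure(list(n = length(e), errors = e, mae = mean(abs(e)), bins = bins,
                 accuracy_1wk = 100 * mean(abs(e) <= 1),
                 accuracy_2wk = 100 * mean(abs(e) <= 2),
                 per_group = per_group),
            class = "fba_error_report")
}

#' @export
print.fba_error_report <- function(x, ...) {
  cat(sprintf("<fba_error_report> n=%d | MAE %.3f wk | within 1 wk %.2f%% | within 2 wk %.2f%%\n",
              x$n, x$mae, x$accuracy_1wk, x$accuracy_2wk))
  cat("  error bins:", paste(sprintf("%s:%d", names(x$bins), x$bins), collapse = "  "), "\n")
  for (g in names(x$per_group)) {
    pg <- x$per_group[[g]]
    cat(sprintf("  PMA %s wk (n=%d): median %.2f [Q1 %.2f, Q3 %.2f], %d outlier(s)\n",
                g, pg$n, pg$median, pg$q1, pg$q3, length(pg$outliers)))
  }
  invisible(x)
}
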