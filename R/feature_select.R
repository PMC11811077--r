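# Feature selection on the selected channels' features: Pearson-correlation
# redundancy filtering, recursive feature elimination with a linear-kernel
# SVR, and the combined PCC-RFE-SVR / PCC-SVR / RFE-SVR variants.

#' Pearson correlation coefficient
#'
#' @param x,z numeric vectors of equal length (at least 3), non-constant.
#' @return the correlation in `[-1, 1]`; `NA` with a warning when either
#'   input is constant (undefined correlation).
#' @export
pcc <- function(x, z) {
  if (length(x) != length(z)) stop_value("length mismatch: %d vs %d", length(x), length(z))
  if (length(x) < 3L) stop_value("need at least 3 observations")
  if (sd(x) == 0 || sd(z) == 0) {
    warning("correlation undefined for constant input")
    return(NA_real_)
  }
  cor(x, z)
}

#' Redundancy filtering by pairwise correlation
#'
#' Feature pairs with `|r|` above `threshold` are redundant; pairs are
#' visited in canonical column order and the *later* column of each
#' still-kept redundant pair is dropped, so the result is deterministic.
#' The label is never consulted: the filter is unsupervised (feature-to-
#' feature only), which keeps the step leakage-free; when `y` is supplied
#' it is used only to annotate the report with per-feature R².
#'
#' @param X numeric matrix with named columns (missing values are
#'   median-imputed for the correlation computation).
#' @param threshold absolute-correlation threshold.
#' @param y optional label vector (report annotation only).
#' @return list with `keep` (kept column names) and `report` (class
#'   `fba_corr_report`): high-correlation pairs, dropped names, optional
#'   per-feature R².
#' @export
pcc_filter <- function(X, threshold = 0.9, y = NULL) {
  X <- as.matrix(X)
  if (ncol(X) < 2L) stop_value("need at least 2 features")
  Xi <- impute_apply(X, impute_fit(X))
  r <- suppressWarnings(cor(Xi))
  r[!is.finite(r)] <- 0
  nm <- colnames(Xi)
  keep <- rep(TRUE, ncol(Xi))
  pairs <- list()
  for (i in seq_len(ncol(Xi) - 1L)) {
    if (!keep[i]) next
    hits <- which(keep & abs(r[i, ]) > threshold)
    hits <- hits[hits > i]
    for (j in hits) {
      keep[j] <- FALSE
      pairs[[length(pairs) + 1L]] <- data.frame(
        kept = nm[i], dropped = nm[j], r = r[i, j], stringsAsFactors = FALSE)
    }
  }
  report <- structure(list(
    pairs = if (length(pairs)) do.call(rbind, pairs) else
      data.frame(kept = character(), dropped = character(), r = numeric()),
    dropped = nm[!keep],
    r2 = if (!is.null(y)) r2_table(Xi[, keep, drop = FALSE], y) else NULL),
    class = "fba_corr_report")
  list(keep = nm[keep], report = report)
}

#' Per-feature coefficients of determination against the label
#'
#' R² is the squared Pearson correlation between each feature and the
#' label, sorted descending (ties broken by feature name).
#'
#' @param X feature matrix with named columns.
#' @param y label vector.
#' @return data frame (`feature`, `r2`) in descending R² order.
#' @export
r2_table <- function(X, y) {
  X <- as.matrix(X)
  r2 <- vapply(seq_len(ncol(X)), function(j) {
    x <- X[, j]
    ok <- is.finite(x)
    if (sd(x[ok]) == 0) return(0)
    cor(x[ok], y[ok])^2
  }, numeric(1))
  out <- data.frame(feature = colnames(X), r2 = r2, stringsAsFactors = FALSE)
  out <- out[order(-out$r2, out$feature), ]
  rownames(out) <- NULL
  out
}

selection_curve <- function(curve, order_removed, method) {
  k_star <- curve$k[which.min(curve$mae)]      # ties resolve to smaller k
  structure(list(curve = curve, k_star = k_star,
                 selected = curve$features[[which.min(curve$mae)]],
                 order_removed = order_removed, method = method),
            class = "selection_curve")
}

#' @export
print.selection_curve <- function(x, ...) {
  cat(sprintf("<selection_curve> method=%s | k* = %d features, CV MAE %.3f wk\n",
              x$method, x$k_star, min(x$curve$mae)))
  invisible(x)
}

#' @export
plot.selection_curve <- function(x, ...) {
  plot(x$curve$k, x$curve$mae, type = "l", xlab = "number of features",
       ylab = "CV MAE (weeks)", ...)
  points(x$k_star, min(x$curve$mae), pch = 19)
  invisible(x)
}

# Linear-SVR feature weights |w| = |t(coefs) %*% SV| on standardised data.
linear_svr_weights <- function(X, y, C = 1) {
  zs <- suppressWarnings(zscore_fit(X))
  m <- e1071::svm(zscore_apply(X, zs), y, type = "eps-regression",
                  kernel = "linear", cost = C, scale = FALSE)
  w <- as.vector(t(m$coefs) %*% m$SV)
  abs(w)
}

#' Recursive feature elimination with an SVR estimator
#'
#' At each step a linear-kernel SVR is fitted on the current features
#' (linearity is what makes the coefficient magnitudes a usable importance
#' ranking), the grouped 5-fold CV MAE of the current set is recorded, and
#' the single feature with the smallest `|coefficient|` is removed, down to
#' one feature.
#'
#' @param X feature matrix with named columns (>= 2 features, >= 10 rows).
#' @param y labels (weeks).
#' @param groups subject ids for grouped folds.
#' @param cv_seed fold seed.
#' @param grid SVR grid for the CV scoring of each feature count.
#' @param folds CV folds.
#' @param rfe_C cost of the linear ranking SVR.
#' @return a `selection_curve`: CV MAE at every feature count `k` from the
#'   full dimension down to 1, the removal order, the optimal `k*`
#'   (smallest k among ties) and the selected feature names.
#' @export
rfe_svr <- function(X, y, groups = seq_along(y), cv_seed = 1,
                    grid = wrapper_grid(), folds = 5, rfe_C = 1) {
  X <- as.matrix(X)
  if (ncol(X) < 2L) stop_value("need at least 2 features for RFE")
  if (nrow(X) < 10L) stop_value("need at least 10 rows for RFE")
  Xi <- impute_apply(X, impute_fit(X))
  current <- colnames(Xi)
  removed <- character()
  rows <- list()
  while (length(current) >= 1L) {
    cm <- min(cv_candidate_mae(Xi[, current, drop = FALSE], y, groups, grid,
                               folds = folds, seed = cv_seed))
    rows[[length(rows) + 1L]] <- list(k = length(current), mae = cm,
                                      features = current)
    if (length(current) == 1L) break
    w <- linear_svr_weights(Xi[, current, drop = FALSE], y, C = rfe_C)
    drop_i <- which(w == min(w))
    drop_i <- drop_i[length(drop_i)]           # ties: drop the later column
    removed <- c(removed, current[drop_i])
    current <- current[-drop_i]
  }
  curve <- data.frame(k = vapply(rows, `[[`, 0, "k"),
                      mae = vapply(rows, `[[`, 0, "mae"))
  curve$features <- lapply(rows, `[[`, "features")
  curve <- curve[order(curve$k), ]
  selection_curve(curve, c(removed, current), "rfe_svr")
}

# Nested curve over a fixed importance ordering (used by pcc_svr).
ordered_curve <- function(Xi, y, groups, ordering, cv_seed, grid, folds, method) {
  rows <- lapply(seq_along(ordering), function(k) {
    feats <- ordering[seq_len(k)]
    list(k = k,
         mae = min(cv_candidate_mae(Xi[, feats, drop = FALSE], y, groups, grid,
                                    folds = folds, seed = cv_seed)),
         features = feats)
  })
  curve <- data.frame(k = vapply(rows, `[[`, 0, "k"),
                      mae = vapply(rows, `[[`, 0, "mae"))
  curve$features <- lapply(rows, `[[`, "features")
  selection_curve(curve, rev(ordering), method)
}

#' Feature selection: PCC-RFE-SVR and its ablations
#'
#' `pcc_rfe_svr` filters redundant features by pairwise correlation and
#' runs [rfe_svr()] on the survivors; `pcc_svr` ranks the filtered
#' features by univariate R² and scores nested feature counts; `rfe_svr`
#' skips the filter and runs RFE on the full matrix.
#'
#' @param X feature matrix with named columns.
#' @param y labels (weeks).
#' @param method one of `"pcc_rfe_svr"`, `"pcc_svr"`, `"rfe_svr"`.
#' @param groups subject ids for grouped folds.
#' @param threshold PCC redundancy threshold.
#' @param cv_seed,grid,folds CV scoring controls.
#' @param ... passed to [rfe_svr()].
#' @return a `selection_curve`; for the PCC variants the correlation report
#'   is attached as attribute `"pcc_report"`.
#' @export
select_features <- function(X, y, method = c("pcc_rfe_svr", "pcc_svr", "rfe_svr"),
                            groups = seq_along(y), threshold = 0.9, cv_seed = 1,
                            grid = wrapper_grid(), folds = 5, ...) {
  if (!is.character(method) || !all(method %in% c("pcc_rfe_svr", "pcc_svr", "rfe_svr"))) {
    stop_value("unknown feature-selection method: %s", paste(method, collapse = "/"))
  }
  method <- match.arg(method)
  X <- as.matrix(X)
  if (method == "rfe_svr") {
    return(rfe_svr(X, y, groups, cv_seed, grid, folds, ...))
  }
  flt <- pcc_filter(X, threshold, y = y)
  Xk <- X[, flt$keep, drop = FALSE]
  out <- if (method == "pcc_rfe_svr") {
    res <- rfe_svr(Xk, y, groups, cv_seed, grid, folds, ...)
    res$method <- "pcc_rfe_svr"
    res
  } else {
    Xi <- impute_apply(Xk, impute_fit(Xk))
    ordering <- r2_table(Xi, y)$feature
    ordered_curve(Xi, y, groups, ordering, cv_seed, grid, folds, "pcc_svr")
  }
  attr(out, "pcc_report") <- flt$report
  out
}
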