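# Model-ready assembly: subject-wise stratified train/test split, z-score
# normalisation with training-only parameters, cross-channel processing.

#' Subject-wise stratified train/test split
#'
#' Splits *subjects* (never individual segments) into train and test sets
#' within integer-PMA-week strata, so all of a subject's one-hour segments
#' land on the same side. Strata with fewer than two subjects are merged
#' with the nearest neighbouring stratum.
#'
#' @param labels data frame with `subject_id` and `pma_weeks` (one row per
#'   subject, or a feature table whose rows are deduplicated by subject).
#' @param train_fraction fraction of each stratum assigned to training.
#' @param seed RNG seed.
#' @return list with character vectors `train` and `test`.
#' @export
split_subjects <- function(labels, train_fraction = 0.7, seed = 1) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  labels <- unique(data.frame(subject_id = labels$subject_id,
                              pma_weeks = labels$pma_weeks,
                              stringsAsFactors = FALSE))
  if (nrow(labels) < 2L) stop_value("need at least two subjects to split")
  strata <- floor(labels$pma_weeks)
  lev <- sort(unique(strata))
  counts <- table(factor(strata, levels = lev))
  # merge singleton strata into the nearest neighbour
  grp <- setNames(lev, lev)
  for (l in lev[counts < 2]) {
    others <- lev[lev != l & counts[as.character(lev)] >= 2]
    if (!length(others)) others <- lev[lev != l]
    tgt <- others[which.min(abs(others - l))]
    grp[as.character(l)] <- grp[as.character(tgt)]
    message(sprintf("merging PMA stratum %s (n=%d) into %s", l, counts[as.character(l)], tgt))
  }
  g <- grp[as.character(strata)]
  with_seed(seed, {
    train <- character()
    for (s in unique(g)) {
      ids <- labels$subject_id[g == s]
      ids <- ids[sample.int(length(ids))]
      n_tr <- min(max(round(train_fraction * length(ids)), 1L), length(ids) - 1L)
      train <- c(train, ids[seq_len(n_tr)])
    }
    list(train = sort(train), test = sort(setdiff(labels$subject_id, train)))
  })
}

#' Fit / apply z-score normalisation
#'
#' `zscore_fit()` computes per-column mean and population SD from training
#' rows only; `zscore_apply()` standardises any matrix with those training
#' parameters, so test data never leak into the normalisation. Columns with
#' zero SD map to zero (with a warning at fit time). Missing entries are
#' ignored when fitting and propagate through application.
#'
#' @param X numeric training matrix (rows = segments).
#' @return `zscore_fit()`: an object of class `fba_zscore` with `mu` and
#'   `sigma`; `zscore_apply()`: the standardised matrix.
#' @export
zscore_fit <- function(X) {
  X <- as.matrix(X)
  if (!nrow(X)) stop_value("cannot fit normalisation on an empty matrix")
  mu <- colMeans(X, na.rm = TRUE)
  sigma <- sqrt(colMeans(sweep(X, 2L, mu)^2, na.rm = TRUE))
  if (any(zero <- (sigma == 0 | !is.finite(sigma)))) {
    warning(sprintf("%d constant feature column(s) map to zero", sum(zero)))
  }
  structure(list(mu = mu, sigma = sigma), class = "fba_zscore")
}

#' @rdname zscore_fit
#' @param params an `fba_zscore` object fitted on training rows.
#' @export
zscore_apply <- function(X, params) {
  X <- as.matrix(X)
  s <- params$sigma
  s[s == 0 | !is.finite(s)] <- Inf     # constant columns -> 0
  sweep(sweep(X, 2L, params$mu), 2L, s, "/")
}

#' Cross-channel feature processing
#'
#' Collapses (median/mean) or concatenates the per-channel feature blocks of
#' a subset of montage channels. Median and mean act per underlying feature
#' across the subset's channels and yield 86 columns named
#' `<mode>__band__domain__feature`; concatenation keeps all
#' `86 * |subset|` channel-tagged columns.
#'
#' @param tbl an `fba_features` table.
#' @param mode `"concat"`, `"median"` or `"mean"`.
#' @param channels montage channel IDs to process (default: all present).
#' @return an `fba_features` table with the processed columns.
#' @export
cross_channel <- function(tbl, mode = c("concat", "median", "mean"),
                          channels = table_channels(tbl)) {
  if (!is.character(mode) || !all(mode %in% c("concat", "median", "mean"))) {
    stop_value("unknown cross-channel mode: %s", paste(mode, collapse = "/"))
  }
  mode <- match.arg(mode)
  if (!length(channels)) stop_value("empty channel subset")
  cols <- channel_columns(tbl, channels)
  if (!length(cols)) stop_value("no feature columns for channels %s", paste(channels, collapse = ","))
  X <- as.matrix(tbl[, cols, drop = FALSE])
  if (mode == "concat") {
    return(feature_table(tbl[META_COLS], X))
  }
  info <- parse_feature_name(cols)
  key <- paste(info$band, info$domain, info$feature, sep = "__")
  keys <- unique(key)
  fun <- if (mode == "median") function(v) median(v, na.rm = TRUE) else
    function(v) mean(v, na.rm = TRUE)
  out <- vapply(keys, function(k) {
    sub <- X[, key == k, drop = FALSE]
    apply(sub, 1L, fun)
  }, numeric(nrow(X)))
  if (nrow(X) == 1L) out <- matrix(out, nrow = 1L, dimnames = list(NULL, keys))
  out[is.nan(out)] <- NA_real_
  colnames(out) <- make_feature_name(mode, vapply(strsplit(keys, "__"), `[`, "", 1L),
                                     vapply(strsplit(keys, "__"), `[`, "", 2L),
                                     vapply(strsplit(keys, "__"), `[`, "", 3L))
  feature_table(tbl[META_COLS], out)
}
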