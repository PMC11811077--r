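# Feature tables: one row per one-hour segment, metadata columns plus
# channel__band__domain__feature columns, CSV (de)serialisation.

META_COLS <- c("subject_id", "segment_index", "pma_weeks")

#' Compose / parse feature column names
#'
#' Feature columns are named `channel__band__domain__feature`, e.g.
#' `Fp1-Fp2__delta__amplitude__power`. The scheme is invertible:
#' `parse_feature_name()` returns the four components.
#'
#' @param channel,band,domain,feature name components.
#' @return `make_feature_name()`: character vector of names;
#'   `parse_feature_name()`: data frame with one row per name.
#' @export
make_feature_name <- function(channel, band, domain, feature) {
  paste(channel, band, domain, feature, sep = "__")
}

#' @rdname make_feature_name
#' @param x feature column names.
#' @export
parse_feature_name <- function(x) {
  parts <- strsplit(x, "__", fixed = TRUE)
  if (any(lengths(parts) != 4L)) {
    stop_parse("unparseable feature name(s): %s",
               paste(x[lengths(parts) != 4L], collapse = ", "))
  }
  m <- do.call(rbind, parts)
  data.frame(channel = m[, 1], band = m[, 2], domain = m[, 3],
             feature = m[, 4], stringsAsFactors = FALSE)
}

#' Assemble a feature table
#'
#' @param meta data frame with columns `subject_id`, `segment_index`,
#'   `pma_weeks` (one row per segment).
#' @param values numeric matrix of features, rows aligned with `meta`,
#'   columns named by [make_feature_name()]; `NA` marks a missing value.
#' @return a `data.frame` of class `fba_features`.
#' @export
feature_table <- function(meta, values) {
  stopifnot(all(META_COLS %in% names(meta)), nrow(meta) == nrow(values))
  if (anyDuplicated(colnames(values))) {
    stop_parse("duplicate feature column name(s): %s",
               paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  }
  out <- cbind(meta[META_COLS], as.data.frame(values, check.names = FALSE))
  rownames(out) <- NULL
  class(out) <- c("fba_features", "data.frame")
  out
}

feature_cols <- function(tbl) setdiff(names(tbl), META_COLS)

feature_matrix <- function(tbl) {
  as.matrix(tbl[, feature_cols(tbl), drop = FALSE])
}

# Channel IDs (per the montage table) present in a feature table.
table_channels <- function(tbl, montage = neonatal_montage()) {
  ch <- unique(parse_feature_name(feature_cols(tbl))$channel)
  ids <- montage$id[match(ch, montage$name)]
  sort(ids[!is.na(ids)])
}

# Column names belonging to the given montage channel IDs, montage order.
channel_columns <- function(tbl, ids, montage = neonatal_montage()) {
  info <- parse_feature_name(feature_cols(tbl))
  want <- montage$name[match(ids, montage$id)]
  unlist(lapply(want, function(w) feature_cols(tbl)[info$channel == w]), use.names = FALSE)
}

#' Write / read a feature table as CSV
#'
#' Values are serialised with 15 significant digits so a round-trip
#' preserves at least 12; missing values become empty cells.
#'
#' @param tbl a [feature_table()].
#' @param path CSV path.
#' @return `write_feature_table()`: `path` invisibly;
#'   `read_feature_table()`: the table.
#' @export
write_feature_table <- function(tbl, path) {
  out <- tbl
  num <- vapply(out, is.numeric, TRUE)
  out[num] <- lapply(out[num], function(x) {
    ifelse(is.na(x), "", sprintf("%.15g", x))
  })
  write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  hdr <- strsplit(readLines(path, n = 1L), ",")[[1]]
  hdr <- gsub('^"|"$', "", hdr)
  if (anyDuplicated(hdr)) {
    stop_parse("duplicate column name(s) in %s: %s", path,
               paste(unique(hdr[duplicated(hdr)]), collapse = ", "))
  }
  if (!all(META_COLS %in% hdr)) stop_parse("%s is not a feature table (missing metadata columns)", path)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  fc <- setdiff(names(df), META_COLS)
  df[fc] <- lapply(df[fc], as.numeric)
  feature_table(df[META_COLS], as.matrix(df[, fc, drop = FALSE]))
}

#' @export
print.fba_features <- function(x, ...) {
  ids <- tryCatch(table_channels(x), error = function(e) integer())
  cat(sprintf("<fba_features> %d segments | %d subjects | %d features | channels: %s\n",
              nrow(x), length(unique(x$subject_id)), length(feature_cols(x)),
              if (length(ids)) paste(ids, collapse = ",") else "?"))
  invisible(x)
}
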