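# Shared fixtures. Everything is generated in code; the expensive
# signal-level cohort is memoised so several test files can share it.

.fixture_env <- new.env()

# Compact SVR grid for search-heavy tests (linear kernel only).
tiny_grid <- function() {
  data.frame(C = c(0.11, 1.01), gamma = "scale", kernel = "linear",
             stringsAsFactors = FALSE)
}

# Five-channel toy feature table with two informative channels.
toy_table5 <- function(seed = 11, n_subjects = 40) {
  synth_feature_table(n_subjects = n_subjects, channels = 1:5,
                      informative_channels = c(2, 4), n_features = 4,
                      n_informative = 2, effect = 1.2, seed = seed)
}

# Referential white-noise recording for montage / preprocessing tests.
noise_recording <- function(fs = 64, dur = 10, sd_uv = 10, seed = 1,
                            labels = neonatal_electrodes()) {
  with_seed <- getFromNamespace("with_seed", "neofba")
  with_seed(seed, recording(matrix(rnorm(length(labels) * fs * dur, sd = sd_uv),
                                   nrow = length(labels)),
                            fs = fs, labels = labels, subject_id = "noise",
                            pma_weeks = 34))
}

# The study-scale synthetic cohort feature table: 40 subjects, one hour at
# 250 Hz, preprocessed to 64 Hz; memoised across test files.
cohort_table <- function() {
  if (is.null(.fixture_env$cohort)) {
    cfg <- synth_config(n_subjects = 40, fs = 250, duration_s = 3600, seed = 7)
    .fixture_env$cohort <- extract_cohort(cfg, preproc_config())
    .fixture_env$cohort_cfg <- cfg
  }
  .fixture_env$cohort
}

cohort_config <- function() {
  cohort_table()
  .fixture_env$cohort_cfg
}

# Exhaustive per-cardinality optimum over all non-empty subsets of the
# table's channels: the oracle lower bound for every search method.
exhaustive_best <- function(tbl, cv_seed = 1, grid = tiny_grid(), cache = NULL) {
  ids <- getFromNamespace("table_channels", "neofba")(tbl)
  subsets <- unlist(lapply(seq_along(ids), function(m)
    utils::combn(ids, m, simplify = FALSE)), recursive = FALSE)
  maes <- vapply(subsets, function(s)
    evaluate_subset(tbl, s, cv_seed, grid = grid, cache = cache), numeric(1))
  card <- lengths(subsets)
  best <- vapply(sort(unique(card)), function(m) min(maes[card == m]), numeric(1))
  list(per_cardinality = setNames(best, sort(unique(card))),
       optimum = min(maes),
       best_subset = subsets[[which.min(maes)]])
}
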