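# Wrapper channel selection. Candidate channel subsets are scored by the
# grouped 5-fold cross-validated MAE of a grid-searched SVR on the
# concatenated per-channel features (no feature selection at this stage).
# Searches: forward addition (FA), backward elimination (BE), binary
# particle swarm optimisation (BPSO) and the combined BPSO+FA+BE strategy,
# plus genetic-algorithm and simulated-annealing baselines.

#' BPSO configuration
#' @param particles swarm size P.
#' @param inertia velocity inertia w.
#' @param c1,c2 cognitive and social learning factors.
#' @param iterations iteration budget L.
#' @param seed RNG seed for the search.
#' @return a list of class `swarm_config`.
#' @export
swarm_config <- function(particles = 100, inertia = 0.5, c1 = 1.5, c2 = 1.5,
                         iterations = 100, seed = 1) {
  stopifnot(particles >= 2, iterations >= 1, inertia > 0, c1 > 0, c2 > 0)
  structure(as.list(environment()), class = "swarm_config")
}

#' Simulated-annealing configuration
#' @param t0 initial temperature.
#' @param alpha geometric cooling rate (0 < alpha < 1).
#' @param iterations iteration budget L.
#' @param seed RNG seed.
#' @return a list of class `anneal_config`.
#' @export
anneal_config <- function(t0 = 1.0, alpha = 0.8, iterations = 100, seed = 1) {
  stopifnot(alpha > 0, alpha < 1, t0 > 0, iterations >= 1)
  structure(as.list(environment()), class = "anneal_config")
}

#' Genetic-algorithm configuration
#' @param pop_size population size PS.
#' @param generations number of generations NG.
#' @param mutation_rate per-bit mutation probability MR.
#' @param crossover_rate per-pair crossover probability CR.
#' @param seed RNG seed.
#' @return a list of class `genetic_config`.
#' @export
genetic_config <- function(pop_size = 10, generations = 20, mutation_rate = 0.1,
                           crossover_rate = 0.7, seed = 1) {
  stopifnot(pop_size >= 2, generations >= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            crossover_rate >= 0, crossover_rate <= 1)
  structure(as.list(environment()), class = "genetic_config")
}

#' Memoisation cache for subset evaluations
#'
#' FA/BE/BPSO revisit subsets heavily; sharing a cache across searches (with
#' a common `cv_seed`) changes runtime only, never results.
#' @return an environment usable as the `cache` argument of the search
#'   functions.
#' @export
subset_cache <- function() new.env(parent = emptyenv())

#' Cross-validated MAE of a channel subset
#'
#' Concatenates the subset's per-channel features, then scores by grouped
#' PMA-stratified 5-fold CV with fold-wise imputation and z-scoring and a
#' grid-searched SVR; the subset's MAE is the best candidate's CV MAE.
#' Deterministic given `(subset, cv_seed, grid, folds)`.
#'
#' @param tbl training-partition `fba_features` table.
#' @param subset montage channel IDs (non-empty).
#' @param cv_seed fold seed.
#' @param grid SVR candidate grid ([wrapper_grid()] by default; pass
#'   [svr_grid()] for the full search).
#' @param folds CV folds.
#' @param cache optional [subset_cache()].
#' @return the cross-validated MAE in weeks.
#' @export
evaluate_subset <- function(tbl, subset, cv_seed = 1, grid = wrapper_grid(),
                            folds = 5, cache = NULL) {
  if (!length(subset)) stop_value("empty channel subset")
  subset <- sort(unique(as.integer(subset)))
  key <- paste(paste(subset, collapse = ","), cv_seed, folds,
               paste(unlist(grid), collapse = "|"), sep = "#")
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  pre <- subset_precompute(tbl, cache)
  X <- pre$X[, unlist(pre$col_by_channel[as.character(subset)], use.names = FALSE),
             drop = FALSE]
  out <- min(cv_candidate_mae(X, pre$y, pre$groups, grid,
                              folds = folds, seed = cv_seed))
  if (!is.null(cache)) cache[[key]] <- out
  out
}

# The feature matrix and channel -> column map of a table, computed once
# per search and stashed in the evaluation cache (searches revisit the same
# table thousands of times and data-frame subsetting dominates otherwise).
subset_precompute <- function(tbl, cache = NULL) {
  pre <- if (!is.null(cache)) cache[["__precompute"]]
  if (!is.null(pre) && identical(pre$dim, dim(tbl)) &&
      identical(pre$stamp, names(tbl)[length(names(tbl))])) {
    return(pre)
  }
  fc <- feature_cols(tbl)
  mont <- neonatal_montage()
  ids <- mont$id[match(parse_feature_name(fc)$channel, mont$name)]
  pre <- list(X = as.matrix(tbl[, fc, drop = FALSE]),
              col_by_channel = split(seq_along(fc), ids),
              y = tbl$pma_weeks, groups = tbl$subject_id,
              dim = dim(tbl), stamp = names(tbl)[length(names(tbl))])
  if (!is.null(cache)) cache[["__precompute"]] <- pre
  pre
}

#' Rank individual channels by single-channel MAE
#' @inheritParams evaluate_subset
#' @param ... passed to [evaluate_subset()].
#' @return data frame (`channel`, `mae`) in ascending MAE order, ties by
#'   ascending channel ID.
#' @export
rank_single <- function(tbl, cv_seed = 1, ...) {
  ids <- table_channels(tbl)
  m <- vapply(ids, function(ch) evaluate_subset(tbl, ch, cv_seed, ...), numeric(1))
  out <- data.frame(channel = ids, mae = m)
  out <- out[order(out$mae, out$channel), ]
  rownames(out) <- NULL
  out
}

# ---- per-cardinality ledger -------------------------------------------------

ledger_new <- function() new.env(parent = emptyenv())

ledger_update <- function(led, subset, mae) {
  k <- as.character(length(subset))
  cur <- led[[k]]
  if (is.null(cur) || mae < cur$mae) led[[k]] <- list(channels = sort(subset), mae = mae)
  invisible(led)
}

ledger_merge <- function(...) {
  out <- ledger_new()
  for (led in list(...)) {
    for (k in ls(led)) {
      e <- led[[k]]
      ledger_update(out, e$channels, e$mae)
    }
  }
  out
}

ledger_df <- function(led, m_max = Inf) {
  ks <- sort(as.integer(ls(led)))
  ks <- ks[ks <= m_max]
  data.frame(m = ks,
             mae = vapply(as.character(ks), function(k) led[[k]]$mae, numeric(1)),
             channels = I(lapply(as.character(ks), function(k) led[[k]]$channels)),
             row.names = NULL)
}

subset_result <- function(led, method, trace = NULL, m_max = Inf, extra = list()) {
  df <- ledger_df(led, m_max)
  best <- which.min(df$mae)
  structure(c(list(per_cardinality = df,
                   best = list(channels = df$channels[[best]], mae = df$mae[best]),
                   trace = trace, method = method), extra),
            class = "subset_result")
}

#' @export
print.subset_result <- function(x, ...) {
  cat(sprintf("<subset_result> method=%s | best: {%s} MAE %.3f wk\n", x$method,
              paste(x$best$channels, collapse = ","), x$best$mae))
  df <- x$per_cardinality
  for (i in seq_len(nrow(df))) {
    cat(sprintf("  m=%2d  MAE %.3f  {%s}\n", df$m[i], df$mae[i],
                paste(df$channels[[i]], collapse = ",")))
  }
  invisible(x)
}

#' Forward-addition channel search
#'
#' Greedy growth from `start` (possibly empty): at each step the channel
#' whose addition yields the smallest MAE is added (ties to the lowest
#' channel ID), until the full complement is reached.
#'
#' @inheritParams evaluate_subset
#' @param start channel IDs of the starting subset.
#' @param ... passed to [evaluate_subset()].
#' @return a `subset_result` covering cardinalities `|start|+1 .. M`.
#' @export
forward_addition <- function(tbl, start = integer(), cv_seed = 1,
                             cache = subset_cache(), ...) {
  ids <- table_channels(tbl)
  set <- sort(unique(as.integer(start)))
  led <- ledger_new()
  if (length(set) >= length(ids)) {         # nothing to add: score the start
    ledger_update(led, set, evaluate_subset(tbl, set, cv_seed, cache = cache, ...))
    return(subset_result(led, "fa"))
  }
  while (length(set) < length(ids)) {
    cand <- setdiff(ids, set)                 # ascending: first min = lowest ID
    maes <- vapply(cand, function(ch)
      evaluate_subset(tbl, c(set, ch), cv_seed, cache = cache, ...), numeric(1))
    set <- sort(c(set, cand[which.min(maes)]))
    ledger_update(led, set, min(maes))
  }
  subset_result(led, "fa")
}

#' Backward-elimination channel search
#'
#' Greedy shrinkage from `start` (the full complement by default): at each
#' step the channel whose removal yields the best MAE is dropped (ties to
#' the highest channel ID), down to a single channel.
#'
#' @inheritParams forward_addition
#' @return a `subset_result` covering cardinalities `|start|-1 .. 1` (a
#'   singleton start is returned as-is).
#' @export
backward_elimination <- function(tbl, start = table_channels(tbl), cv_seed = 1,
                                 cache = subset_cache(), ...) {
  set <- sort(unique(as.integer(start)))
  led <- ledger_new()
  if (length(set) < 2L) {
    ledger_update(led, set, evaluate_subset(tbl, set, cv_seed, cache = cache, ...))
    return(subset_result(led, "be"))
  }
  while (length(set) > 1L) {
    cand <- sort(set, decreasing = TRUE)      # first min = highest ID removed
    maes <- vapply(cand, function(ch)
      evaluate_subset(tbl, setdiff(set, ch), cv_seed, cache = cache, ...), numeric(1))
    set <- sort(setdiff(set, cand[which.min(maes)]))
    ledger_update(led, set, min(maes))
  }
  subset_result(led, "be")
}

sigmoid <- function(v) 1 / (1 + exp(-v))

resample_zero_rows <- function(Xp, quiet = FALSE) {
  zero <- rowSums(Xp) == 0
  while (any(zero)) {
    if (!quiet) message(sprintf("re-sampling %d all-zero particle(s)", sum(zero)))
    Xp[zero, ] <- matrix(rbinom(sum(zero) * ncol(Xp), 1, 0.5), ncol = ncol(Xp))
    zero <- rowSums(Xp) == 0
  }
  Xp
}

#' Binary particle swarm optimisation over channel subsets
#'
#' Particles are bit-vectors over the montage channels. Positions start
#' Bernoulli(0.5), velocities Uniform(-1, 1); velocities follow the
#' canonical inertia + cognitive + social update and positions are
#' redrawn through the sigmoid transfer (`x = 1` iff `U(0,1) < sigmoid(v)`).
#' Personal and global bests are tracked by subset MAE; every evaluated
#' particle also updates a per-cardinality best ledger.
#'
#' @inheritParams evaluate_subset
#' @param cfg a [swarm_config()].
#' @param ... passed to [evaluate_subset()].
#' @return a `subset_result`; `$trace` holds the (non-increasing) global
#'   best MAE per iteration, `$ledger` the internal per-cardinality ledger.
#' @export
bpso <- function(tbl, cfg = swarm_config(), cv_seed = 1,
                 cache = subset_cache(), ...) {
  ids <- table_channels(tbl)
  M <- length(ids)
  led <- ledger_new()
  score_all <- function(Xp) apply(Xp, 1L, function(bits) {
    s <- ids[bits == 1]
    m <- evaluate_subset(tbl, s, cv_seed, cache = cache, ...)
    ledger_update(led, s, m)
    m
  })
  with_seed(cfg$seed, {
    P <- cfg$particles
    Xp <- resample_zero_rows(matrix(rbinom(P * M, 1, 0.5), nrow = P), quiet = TRUE)
    V <- matrix(runif(P * M, -1, 1), nrow = P)
    fit <- score_all(Xp)
    Pb <- Xp; pb_mae <- fit
    g <- which.min(fit); Gb <- Xp[g, ]; gb_mae <- fit[g]
    trace <- numeric(cfg$iterations)
    for (t in seq_len(cfg$iterations)) {
      r1 <- matrix(runif(P * M), nrow = P)
      r2 <- matrix(runif(P * M), nrow = P)
      V <- cfg$inertia * V + cfg$c1 * r1 * (Pb - Xp) +
        cfg$c2 * r2 * sweep(-Xp, 2L, Gb, "+")
      Xp <- resample_zero_rows((matrix(runif(P * M), nrow = P) < sigmoid(V)) * 1)
      fit <- score_all(Xp)
      upd <- fit < pb_mae
      Pb[upd, ] <- Xp[upd, ]; pb_mae[upd] <- fit[upd]
      g <- which.min(pb_mae)
      if (pb_mae[g] < gb_mae) { Gb <- Pb[g, ]; gb_mae <- pb_mae[g] }
      trace[t] <- gb_mae
    }
    subset_result(led, "bpso", trace = trace,
                  extra = list(gbest = list(channels = ids[Gb == 1], mae = gb_mae),
                               ledger = led))
  })
}

# FA/BE expansion from a search's best subset, merged with its ledger.
expand_fa_be <- function(tbl, res, method, cv_seed, cache, ...) {
  ids <- table_channels(tbl)
  s0 <- res$gbest$channels %||% res$best$channels
  fa <- forward_addition(tbl, start = s0, cv_seed = cv_seed, cache = cache, ...)
  be <- backward_elimination(tbl, start = s0, cv_seed = cv_seed, cache = cache, ...)
  led <- ledger_merge(res$ledger, fa_led(fa), fa_led(be))
  subset_result(led, method, trace = res$trace, m_max = length(ids) - 1L)
}

fa_led <- function(res) {
  led <- ledger_new()
  df <- res$per_cardinality
  for (i in seq_len(nrow(df))) ledger_update(led, df$channels[[i]], df$mae[i])
  led
}

#' Combined BPSO + FA + BE channel selection
#'
#' Runs BPSO for a global search, then expands its best subset upward by
#' forward addition and downward by backward elimination; the per-cardinality
#' ledgers of all three are merged, keeping the minimum MAE at each
#' cardinality `1 .. M-1`.
#'
#' @inheritParams bpso
#' @return a `subset_result` covering every cardinality `1 .. M-1`.
#' @export
bpso_fa_be <- function(tbl, cfg = swarm_config(), cv_seed = 1,
                       cache = subset_cache(), ...) {
  res <- bpso(tbl, cfg, cv_seed, cache = cache, ...)
  expand_fa_be(tbl, res, "bpso_fa_be", cv_seed, cache, ...)
}

#' Simulated-annealing channel selection (with FA/BE expansion)
#'
#' Bit-flip neighbourhood with Metropolis acceptance on the MAE and
#' geometric cooling `T <- alpha * T`; the best visited subset seeds the
#' same FA/BE expansion as [bpso_fa_be()].
#'
#' @inheritParams evaluate_subset
#' @param cfg an [anneal_config()].
#' @param ... passed to [evaluate_subset()].
#' @return a `subset_result` covering every cardinality `1 .. M-1`.
#' @export
sa_select <- function(tbl, cfg = anneal_config(), cv_seed = 1,
                      cache = subset_cache(), ...) {
  ids <- table_channels(tbl)
  M <- length(ids)
  led <- ledger_new()
  res <- with_seed(cfg$seed, {
    bits <- resample_zero_rows(matrix(rbinom(M, 1, 0.5), nrow = 1), quiet = TRUE)[1, ]
    cur <- evaluate_subset(tbl, ids[bits == 1], cv_seed, cache = cache, ...)
    ledger_update(led, ids[bits == 1], cur)
    best_bits <- bits; best <- cur
    temp <- cfg$t0
    trace <- numeric(cfg$iterations)
    for (t in seq_len(cfg$iterations)) {
      cand <- bits
      repeat {
        j <- sample.int(M, 1L)
        cand[j] <- 1 - cand[j]
        if (sum(cand) > 0) break
        cand[j] <- 1 - cand[j]
      }
      m <- evaluate_subset(tbl, ids[cand == 1], cv_seed, cache = cache, ...)
      ledger_update(led, ids[cand == 1], m)
      if (m < cur || runif(1) < exp(-(m - cur) / temp)) { bits <- cand; cur <- m }
      if (cur < best) { best <- cur; best_bits <- bits }
      temp <- temp * cfg$alpha
      trace[t] <- best
    }
    list(best = list(channels = ids[best_bits == 1], mae = best),
         trace = trace)
  })
  expand_fa_be(tbl, list(best = res$best, ledger = led, trace = res$trace),
               "sa_fa_be", cv_seed, cache, ...)
}

#' Genetic-algorithm channel selection (with FA/BE expansion)
#'
#' Bit-string population with fitness-proportional (probabilistic)
#' selection on 1/MAE, uniform crossover at rate CR, per-bit mutation at
#' rate MR and one-elite carry-over; the best subset seeds FA/BE expansion.
#'
#' @inheritParams evaluate_subset
#' @param cfg a [genetic_config()].
#' @param ... passed to [evaluate_subset()].
#' @return a `subset_result` covering every cardinality `1 .. M-1`.
#' @export
ga_select <- function(tbl, cfg = genetic_config(), cv_seed = 1,
                      cache = subset_cache(), ...) {
  ids <- table_channels(tbl)
  M <- length(ids)
  led <- ledger_new()
  score <- function(pop) apply(pop, 1L, function(bits) {
    m <- evaluate_subset(tbl, ids[bits == 1], cv_seed, cache = cache, ...)
    ledger_update(led, ids[bits == 1], m)
    m
  })
  res <- with_seed(cfg$seed, {
    PS <- cfg$pop_size
    pop <- resample_zero_rows(matrix(rbinom(PS * M, 1, 0.5), nrow = PS), quiet = TRUE)
    fit <- score(pop)
    trace <- numeric(cfg$generations)
    for (gen in seq_len(cfg$generations)) {
      b <- which.min(fit)
      elite <- pop[b, ]; elite_fit <- fit[b]
      w <- 1 / (fit + 1e-9)
      parents <- pop[sample.int(PS, PS, replace = TRUE, prob = w / sum(w)), , drop = FALSE]
      child <- parents
      for (p in seq(1, PS - 1, by = 2)) {
        if (runif(1) < cfg$crossover_rate) {
          mask <- runif(M) < 0.5
          child[p, mask] <- parents[p + 1, mask]
          child[p + 1, mask] <- parents[p, mask]
        }
      }
      flip <- matrix(runif(PS * M) < cfg$mutation_rate, nrow = PS)
      child <- (child + flip) %% 2
      child[1, ] <- elite                       # elitism: keep the best
      pop <- resample_zero_rows(child, quiet = TRUE)
      fit <- score(pop)
      if (elite_fit < min(fit)) { pop[1, ] <- elite; fit[1] <- elite_fit }
      trace[gen] <- min(fit)
    }
    b <- which.min(fit)
    list(best = list(channels = ids[pop[b, ] == 1], mae = fit[b]), trace = trace)
  })
  expand_fa_be(tbl, list(best = res$best, ledger = led, trace = res$trace),
               "ga_fa_be", cv_seed, cache, ...)
}
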