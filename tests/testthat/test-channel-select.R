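# Wrapper channel search on feature-level toy cohorts where the informative
# channels are known by construction.

test_that("subset evaluation is deterministic, memoised and validates input", {
  tbl <- toy_table5()
  m1 <- evaluate_subset(tbl, c(2, 4), cv_seed = 3, grid = tiny_grid())
  m2 <- evaluate_subset(tbl, c(4, 2), cv_seed = 3, grid = tiny_grid())
  expect_identical(m1, m2)
  cache <- subset_cache()
  m3 <- evaluate_subset(tbl, c(2, 4), cv_seed = 3, grid = tiny_grid(), cache = cache)
  m4 <- evaluate_subset(tbl, c(2, 4), cv_seed = 3, grid = tiny_grid(), cache = cache)
  expect_identical(m1, m3)
  expect_identical(m3, m4)
  expect_error(evaluate_subset(tbl, integer()), class = "neofba_value_error")
})

test_that("informative channel pairs score better than uninformative ones", {
  for (seed in 1:5) {
    tbl <- toy_table5(seed = 100 + seed)
    good <- evaluate_subset(tbl, c(2, 4), grid = tiny_grid())
    bad <- evaluate_subset(tbl, c(1, 3), grid = tiny_grid())
    expect_lt(good, bad)
  }
})

test_that("single-channel ranking orders all channels by MAE", {
  tbl <- toy_table5(seed = 42)
  rk <- rank_single(tbl, grid = tiny_grid())
  expect_setequal(rk$channel, 1:5)
  expect_false(is.unsorted(rk$mae))
  expect_true(rk$channel[1] %in% c(2, 4))
})

test_that("forward addition grows greedily from any start", {
  tbl <- toy_table5(seed = 13)
  cache <- subset_cache()
  fa <- forward_addition(tbl, cache = cache, grid = tiny_grid())
  expect_equal(fa$per_cardinality$m, 1:5)
  rk <- rank_single(tbl, grid = tiny_grid())
  expect_equal(fa$per_cardinality$channels[[1]], rk$channel[1])
  fa2 <- forward_addition(tbl, start = c(1, 3), cache = cache, grid = tiny_grid())
  expect_equal(fa2$per_cardinality$m, 3:5)
  expect_identical(fa, forward_addition(tbl, grid = tiny_grid()))
})

test_that("backward elimination shrinks to a single channel", {
  tbl <- toy_table5(seed = 13)
  be <- backward_elimination(tbl, grid = tiny_grid())
  expect_equal(be$per_cardinality$m, 1:4)
  one <- backward_elimination(tbl, start = 3, grid = tiny_grid())
  expect_equal(one$per_cardinality$m, 1)
  expect_equal(one$per_cardinality$channels[[1]], 3)
})

test_that("BPSO improves monotonically and honours the sigmoid transfer", {
  expect_equal(getFromNamespace("sigmoid", "neofba")(0), 0.5)
  tbl <- toy_table5(seed = 17)
  res <- bpso(tbl, swarm_config(particles = 10, iterations = 8, seed = 2),
              grid = tiny_grid())
  expect_true(all(diff(res$trace) <= 0))
  expect_true(all(res$best$channels %in% 1:5))
  res2 <- bpso(tbl, swarm_config(particles = 10, iterations = 8, seed = 2),
               grid = tiny_grid())
  expect_identical(res$best, res2$best)
})

test_that("the combined search dominates plain FA and BE at every cardinality", {
  tbl <- toy_table5(seed = 23)
  cache <- subset_cache()
  fa <- forward_addition(tbl, cache = cache, grid = tiny_grid())
  be <- backward_elimination(tbl, cache = cache, grid = tiny_grid())
  comb <- bpso_fa_be(tbl, swarm_config(particles = 10, iterations = 8, seed = 5),
                     cache = cache, grid = tiny_grid())
  expect_equal(comb$per_cardinality$m, 1:4)
  for (m in 1:4) {
    ref <- min(c(fa$per_cardinality$mae[fa$per_cardinality$m == m],
                 be$per_cardinality$mae[be$per_cardinality$m == m]))
    expect_lte(comb$per_cardinality$mae[comb$per_cardinality$m == m], ref + 1e-12)
  }
})

test_that("GA and SA baselines search and expand like the combined method", {
  tbl <- toy_table5(seed = 29)
  cache <- subset_cache()
  ga <- ga_select(tbl, genetic_config(pop_size = 6, generations = 5, seed = 3),
                  cache = cache, grid = tiny_grid())
  sa <- sa_select(tbl, anneal_config(iterations = 15, seed = 3),
                  cache = cache, grid = tiny_grid())
  for (res in list(ga, sa)) {
    expect_equal(res$per_cardinality$m, 1:4)
    expect_true(all(unlist(res$per_cardinality$channels) %in% 1:5))
  }
  # the tracked best never deteriorates
  expect_true(all(diff(ga$trace) <= 0))
  expect_true(all(diff(sa$trace) <= 0))
})
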