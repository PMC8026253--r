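test_that("the parameter grid enumerates all 6120 combinations in order", {
  g <- parameter_grid()
  expect_identical(nrow(g), 6120L)
  expect_identical(nrow(g[g$capacity == 1, ]), 51L)
  expect_true(all(g$decay[g$capacity == 1] == 1))
  expect_true(any(g$capacity == 15 & g$decay == 15 & g$utility == 1))
  expect_true(any(g$capacity == 1 & g$decay == 1 & g$utility == 0))
  expect_true(all(g$decay <= g$capacity))
  # deterministic order: capacity, then decay, then utility
  o <- order(g$capacity, g$decay, g$utility)
  expect_identical(o, seq_len(nrow(g)))
})

test_that("the coefficient of determination follows its formula", {
  expect_equal(coefficient_of_determination(c(0.5, 0.5, 0),
                                            c(0.25, 0.5, 0.25)), 0.25)
  set.seed(51)
  tr <- simulate_agent(forage_params(7, 3, 0.7), 2000)
  m <- as_fit_vector(summarize_trials(tr))
  expect_equal(coefficient_of_determination(m, m), 1)
  # centered on the simulated vector's mean, not the observed one
  m2 <- c(0.5, 0.5, 0)
  s2 <- c(0.2, 0.3, 0.5)
  expect_equal(coefficient_of_determination(m2, s2),
               1 - sum((m2 - s2)^2) / sum((m2 - mean(s2))^2))
  expect_equal(coefficient_of_determination(m2, s2, center = "observed"),
               1 - sum((m2 - s2)^2) / sum((m2 - mean(m2))^2))
  expect_error(coefficient_of_determination(rep(1 / 3, 3), rep(1 / 3, 3)),
               "degenerate")
  expect_error(coefficient_of_determination(1:3, 1:4), "equal length")
})

test_that("a mismatched simulation scores below the self-matched one", {
  set.seed(52)
  m <- as_fit_vector(summarize_trials(
    simulate_agent(forage_params(10, 2, 0.9), 5000)))
  s_same <- as_fit_vector(summarize_trials(
    simulate_agent(forage_params(10, 2, 0.9), 5000)))
  s_rand <- as_fit_vector(summarize_trials(
    simulate_agent(forage_params(1, 1, 0), 5000)))
  expect_gt(coefficient_of_determination(m, s_same),
            coefficient_of_determination(m, s_rand))
})

test_that("fitting is deterministic and cache-consistent", {
  cache <- shared_cache()
  set.seed(53)
  tr <- simulate_agent(forage_params(9, 3, 0.85), 2000)
  f1 <- fit_forage_model(tr, cache)
  f2 <- fit_forage_model(tr, cache)
  expect_identical(f1$grid_cds$cd, f2$grid_cds$cd)
  expect_identical(as.numeric(f1$best_params), as.numeric(f2$best_params))
  # building the cache inline with the same metadata gives the same fit
  f3 <- fit_forage_model(tr, cache = NULL, n_sim_trials = 500L,
                         seed = 20260901L)
  expect_identical(f1$grid_cds$cd, f3$grid_cds$cd)
})

test_that("cache files round-trip through disk", {
  path <- tempfile(fileext = ".rds")
  c1 <- build_grid_cache(n_sim_trials = 50L, seed = 7L, path = path)
  expect_true(file.exists(path))
  c2 <- build_grid_cache(n_sim_trials = 50L, seed = 7L, path = path)
  expect_identical(c1$summaries, c2$summaries)
  expect_warning(build_grid_cache(n_sim_trials = 60L, seed = 7L,
                                  path = path), "mismatch")
  unlink(path)
})

test_that("zero-revisit data identify perfect memory use", {
  cache <- shared_cache()
  set.seed(54)
  tr <- simulate_agent(forage_params(15, 1, 1), 5000)
  f <- fit_forage_model(tr, cache)
  expect_identical(f$best_params$utility, 1)
  expect_gte(f$best_params$capacity, 14L)
})

test_that("pathological data are flagged unreliable", {
  cache <- shared_cache()
  # rigid alternation at the saccade cap: no agent in the grid produces
  # this, so the best CD falls below the reliability threshold
  tr <- rep(list(rep(c(1L, 2L), length.out = 25L)), 40)
  f <- fit_forage_model(summarize_trials(tr), cache)
  expect_false(f$reliable)
  expect_lt(f$best_cd, 0.7)
})

test_that("parameter distance is a scaled squared difference", {
  p1 <- forage_params(10, 2, 0.9)
  expect_equal(parameter_pair_distance(p1, p1), 0)
  expect_equal(parameter_pair_distance(p1, forage_params(9, 2, 0.9)), 1)
  expect_equal(parameter_pair_distance(forage_params(10, 2, 0.8),
                                       forage_params(8, 4, 0.4),
                                       scales = c(2, 2, 0.2)), 6)
  expect_error(parameter_pair_distance(p1, p1, scales = c(0, 1, 1)),
               "positive")
})

test_that("session fits cluster within their generating parameters", {
  cache <- shared_cache()
  set.seed(55)
  fit_one <- function(p) {
    tr <- simulate_agent(p, 2000)
    as.numeric(fit_forage_model(tr, cache)$best_params)
  }
  a <- replicate(4, fit_one(forage_params(10, 2, 0.9)))
  b <- replicate(4, fit_one(forage_params(5, 4, 0.55)))
  all_fits <- t(cbind(a, b))
  scales <- pmax(apply(all_fits, 2, stats::sd), 1e-6)
  dist_of <- function(i, j)
    parameter_pair_distance(all_fits[i, ], all_fits[j, ], scales)
  within <- c(apply(utils::combn(1:4, 2), 2, function(ij)
                dist_of(ij[1], ij[2])),
              apply(utils::combn(5:8, 2), 2, function(ij)
                dist_of(ij[1], ij[2])))
  across <- as.vector(outer(1:4, 5:8, Vectorize(dist_of)))
  expect_lt(mean(within), mean(across))
})

test_that("bootstrap edge cases behave as contracted", {
  cache <- shared_cache()
  set.seed(56)
  tr <- simulate_agent(forage_params(10, 2, 0.9), 300)
  b1 <- bootstrap_intervals(tr, cache, n_boot = 1L)
  expect_equal(b1$intervals$lower, b1$intervals$upper)
  expect_true(all(b1$intervals$lower <= b1$intervals$upper))
  expect_error(bootstrap_intervals(trials_subset(tr, 1L), cache, 2L),
               "at least two")
})

test_that("empty and misconfigured windows are handled explicitly", {
  cache <- shared_cache()
  set.seed(57)
  s <- generate_session(forage_params(10, 2, 0.9), 60,
                        injection_minutes = 0)
  expect_error(sliding_window_fit(s, cache, window_minutes = 5,
                                  step_minutes = 10), "step")
  # non-overlapping windows partition the timeline
  tw <- sliding_window_fit(s, cache, window_minutes = 2, step_minutes = 2)
  expect_true(all(tw$window_end[-nrow(tw)] == tw$window_start[-1]))
  expect_identical(sum(tw$n_trials), 60L -
                     sum(session_trials(s)$t_start_min >= max(tw$window_end)))
})
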