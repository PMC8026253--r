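test_that("parameter validation enforces the model's ranges", {
  expect_s3_class(forage_params(10, 2, 0.9), "forage_params")
  expect_error(forage_params(0, 1, 0.5), "capacity")
  expect_error(forage_params(16, 1, 0.5), "capacity")
  expect_error(forage_params(5, 6, 0.5), "decay")
  expect_error(forage_params(5, 2, 1.2), "utility")
  expect_error(forage_params(5, 0, 0.5), "decay")
})

test_that("memory updates evict among the oldest `decay` entries", {
  p <- forage_params(10, 1, 0.9)
  expect_identical(update_memory(1:10, 11L, p), c(2:10, 11L))
  # below capacity: plain append
  expect_identical(update_memory(1:4, 9L, p), c(1:4, 9L))
  # re-registration refreshes recency without eviction
  expect_identical(update_memory(1:10, 3L, p), c(1:2, 4:10, 3L))
  expect_identical(update_memory(1:10, 3L, p, refresh = "ignore"), 1:10)
})

test_that("eviction is uniform over the `decay` oldest entries", {
  p <- forage_params(3, 2, 0.9)
  set.seed(101)
  evicted <- replicate(10000, {
    m <- update_memory(c(4L, 5L, 6L), 7L, p)
    setdiff(c(4L, 5L, 6L), m)
  })
  tab <- table(factor(evicted, levels = c(4, 5, 6))) / 10000
  # a and b evicted ~50% each, c (newest of the three) never
  expect_lt(abs(tab[["4"]] - 0.5), 0.015)
  expect_lt(abs(tab[["5"]] - 0.5), 0.015)
  expect_identical(tab[["6"]], 0)
})

test_that("memory invariants hold under random update streams", {
  set.seed(202)
  for (rep in 1:20) {
    cap <- sample(1:15, 1)
    p <- forage_params(cap, sample(cap, 1), runif(1))
    m <- integer(0)
    for (i in 1:60) {
      m <- update_memory(m, sample(15L, 1), p)
      expect_lte(length(m), cap)
      expect_false(anyDuplicated(m) > 0)
    }
  }
})

test_that("first choice is uniform over all objects", {
  p <- forage_params(10, 2, 1)
  set.seed(303)
  draws <- replicate(15000, choose_next(NA, integer(0), p))
  freq <- table(factor(draws, levels = 1:15)) / 15000
  se <- sqrt((1 / 15) * (14 / 15) / 15000)
  expect_true(all(abs(freq - 1 / 15) < 3.5 * se))
})

test_that("pure exploration excludes only the current object", {
  p <- forage_params(10, 2, 0)
  set.seed(304)
  draws <- replicate(14000, choose_next(7L, c(1L, 2L, 3L), p))
  expect_false(any(draws == 7L))
  freq <- table(factor(draws, levels = setdiff(1:15, 7))) / 14000
  se <- sqrt((1 / 14) * (13 / 14) / 14000)
  expect_true(all(abs(freq - 1 / 14) < 3.5 * se))
})

test_that("exploit mode falls back to exploration when memory is full", {
  p <- forage_params(15, 1, 1)
  set.seed(305)
  ch <- choose_next(3L, setdiff(1:15, 3L), p)
  expect_true(ch %in% setdiff(1:15, 3L))
})

test_that("no trial contains consecutive identical choices", {
  set.seed(404)
  tr <- simulate_agent(forage_params(5, 3, 0.5), 2000)
  for (ch in tr$choices)
    if (length(ch) > 1L) expect_false(any(diff(ch) == 0))
})

test_that("perfect memory yields zero revisits and uniform search length", {
  set.seed(505)
  tr <- simulate_agent(forage_params(15, 1, 1), 20000)
  expect_true(all(!unlist(lapply(tr$choices, duplicated))))
  # sampling without replacement: count uniform on 1..15, mean 8
  expect_true(all(tr$n_saccades <= 15))
  se <- sqrt((15^2 - 1) / 12 / 20000)
  expect_lt(abs(mean(tr$n_saccades) - 8), 4 * se)
})

test_that("zero utility gives the geometric-search saccade count", {
  set.seed(606)
  tr <- simulate_agent(forage_params(10, 2, 0), 20000, max_saccades = 2000L)
  # 1/15 + (14/15) * 15 = 211/15
  expect_lt(abs(mean(tr$n_saccades) - 211 / 15), 0.35)
})

test_that("compiled and reference engines are bit-identical under a seed", {
  p <- forage_params(8, 4, 0.7)
  set.seed(707)
  a <- simulate_agent(p, 400, engine = "compiled")
  set.seed(707)
  b <- simulate_agent(p, 400, engine = "reference")
  expect_identical(a$choices, b$choices)
  expect_identical(a$target, b$target)
  expect_identical(a$found, b$found)
  set.seed(707)
  a2 <- simulate_agent(p, 400, engine = "compiled")
  expect_identical(a$choices, a2$choices)
})

test_that("revisit rate rises monotonically as utility drops", {
  set.seed(808)
  revisit_rate <- vapply(c(1, 0.75, 0.5, 0.25, 0), function(u) {
    tr <- simulate_agent(forage_params(10, 2, u), 5000)
    mean(unlist(lapply(tr$choices, duplicated)))
  }, numeric(1))
  expect_true(all(diff(revisit_rate) > 0))
})

test_that("mean saccade count decreases in utility and in capacity", {
  set.seed(909)
  mean_count <- function(cap, u)
    mean(simulate_agent(forage_params(cap, 2, u), 5000)$n_saccades)
  by_u <- vapply(c(0.3, 0.6, 0.9), function(u) mean_count(10, u), numeric(1))
  expect_true(all(diff(by_u) < 0))
  by_c <- vapply(c(3, 8, 13), function(cap) mean_count(cap, 0.9), numeric(1))
  expect_true(all(diff(by_c) < 0))
})
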