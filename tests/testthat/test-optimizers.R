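test_that("benchmark objectives have their analytic minima", {
  suite <- benchmark_objectives(4, shift = 1.5)
  expect_equal(suite$sphere$evaluate(rep(0, 4)), 0)
  expect_equal(suite$rastrigin$evaluate(rep(0, 4)), 0)
  expect_equal(suite$shifted_quadratic$evaluate(rep(1.5, 4)), 0)
  expect_gt(suite$rastrigin$evaluate(rep(0.5, 4)), 0)
})

test_that("normalised fitness and leader probabilities match hand values", {
  nf <- normalized_fitness(c(1, 2, 3))
  expect_equal(nf, c(2 / 3, 1 / 3, 0))
  lp <- leader_probabilities(nf, 2)
  expect_equal(lp$P, c(2 / 3, 1 / 3))
  expect_equal(lp$C, c(2 / 3, 1))

  # degenerate population: uniform fallback, not an error
  expect_equal(normalized_fitness(c(4, 4, 4, 4)), rep(0.25, 4))
  expect_equal(leader_probabilities(c(0, 0, 0), 2)$P, c(0.5, 0.5))

  # probabilities sum to 1 for random non-degenerate populations
  set.seed(8)
  for (i in 1:20) {
    f <- sort(rnorm(12))
    lp <- leader_probabilities(normalized_fitness(f), 3)
    expect_equal(sum(lp$P), 1, tolerance = 1e-9)
  }
})

test_that("roulette selection returns the first band containing r", {
  expect_identical(roulette_select(c(2 / 3, 1), 0.5), 1L)
  expect_identical(roulette_select(c(2 / 3, 1), 0.9), 2L)
  expect_identical(roulette_select(c(2 / 3, 1), 0), 1L)
  expect_identical(roulette_select(c(0.2, 0.2, 1), 0.2), 1L)
  expect_error(roulette_select(c(0.5, 0.4), 0.1), "non-decreasing")
  expect_error(roulette_select(c(0.3, 0.8), 0.1), "end at 1")
})

test_that("EPO finds a non-origin 1-D optimum and keeps a monotone trace", {
  q <- objective_spec(function(x) (x - 3)^2, 0, 10, 1)
  for (s in 1:10) {
    res <- epo_optimize(q, epo_params(30, 200, seed = s))
    expect_lt(abs(res$best - 3), 0.1)
    expect_true(all(diff(res$trace$best_fitness) <= 0))
  }
})

test_that("MLO minimises the shifted quadratic away from the origin", {
  obj <- benchmark_objectives(3, shift = 1.5)$shifted_quadratic
  res <- mlo_optimize(obj, mlo_params(20, 3, 120, seed = 5))
  expect_lt(res$fitness, 1e-4)
  expect_equal(res$best, rep(1.5, 3), tolerance = 0.05)
  expect_true(all(diff(res$trace$best_fitness) <= 0))
})

test_that("optimizer runs are bit-reproducible and respect bounds", {
  obj <- benchmark_objectives(3)$rastrigin
  a <- epo_optimize(obj, epo_params(12, 40, seed = 9))
  b <- epo_optimize(obj, epo_params(12, 40, seed = 9))
  expect_identical(a, b)
  expect_true(all(a$best >= obj$lower & a$best <= obj$upper))

  c1 <- mlo_optimize(obj, mlo_params(12, 3, 40, seed = 9))
  c2 <- mlo_optimize(obj, mlo_params(12, 3, 40, seed = 9))
  expect_identical(c1, c2)
  expect_true(all(c1$best >= obj$lower & c1$best <= obj$upper))

  # the optimizer must not disturb the caller's RNG stream
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(mlo_optimize(obj, mlo_params(8, 2, 5, seed = 1)))
  expect_identical(runif(1), before)
})

test_that("non-finite objective values raise an error naming the vector", {
  bad <- objective_spec(function(x) if (x[1] > 0) NaN else sum(x^2),
                        -1, 1, 2)
  expect_error(epo_optimize(bad, epo_params(10, 5, seed = 2)), "non-finite")
  expect_error(mlo_optimize(bad, mlo_params(10, 2, 5, seed = 2)), "non-finite")
})

test_that("EPO search recovers exhaustive thresholds on an easy histogram", {
  h <- generate_multimodal_histogram(L = 64, n_modes = 3, seed = 17)
  ex <- exhaustive_mlt(h, 2)
  ep <- epo_mlt(h, 2, epo_params(30, 150, seed = 17))
  expect_gte(ep$score$F, 0.99 * ex$score$F)
})
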