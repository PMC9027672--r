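test_that("histograms count levels and normalise correctly", {
  px <- matrix(0L, 8, 8)
  px[1, 2] <- 1L; px[2, 1] <- 1L; px[3, 3] <- 3L
  img <- gray_image(px, L = 4)
  h <- compute_histogram(img)
  expect_identical(h$counts, c(61L, 2L, 0L, 1L))
  expect_equal(h$probs, c(61, 2, 0, 1) / 64)
  expect_identical(h$n_pixels, 64L)
  expect_equal(sum(h$probs), 1, tolerance = 1e-12)

  const <- compute_histogram(gray_image(matrix(5L, 8, 8), L = 8))
  expect_equal(const$probs, c(0, 0, 0, 0, 0, 1, 0, 0))
})

test_that("between-class variance matches hand-computed values", {
  h <- histogram_from_counts(c(1, 1, 1, 1))  # uniform over {0..3}
  s <- otsu_objective(h, threshold_set(2, L = 4))
  expect_equal(s$class_probs, c(0.5, 0.5))
  expect_equal(s$class_means, c(0.5, 2.5))
  expect_equal(s$global_mean, 1.5)
  expect_equal(s$F, 1.0)
  expect_equal(total_variance(h), 1.25)

  # two spikes at levels 1 and 6 (L = 8)
  h2 <- histogram_from_counts(c(0, 4, 0, 0, 0, 0, 4, 0))
  s2 <- otsu_objective(h2, threshold_set(2, L = 8))
  expect_equal(s2$F, 6.25)
  expect_equal(total_variance(h2), 6.25)

  # constant image: zero variance for any threshold
  hc <- histogram_from_counts(c(0, 0, 64, 0))
  expect_equal(otsu_objective(hc, threshold_set(1, L = 4))$F, 0)
  expect_equal(otsu_objective(hc, threshold_set(3, L = 4))$F, 0)
  expect_equal(total_variance(hc), 0)
})

test_that("otsu_score satisfies its probability and mean identities", {
  for (seed in 1:10) {
    h <- random_histogram(32, seed)
    K <- (seed %% 3) + 1L
    ts <- threshold_set(sort(sample(1:31, K)), L = 32)
    s <- otsu_objective(h, ts)
    expect_gte(s$F, 0)
    expect_equal(sum(s$class_probs), 1, tolerance = 1e-12)
    ok <- s$class_probs > 0
    expect_equal(sum(s$class_probs[ok] * s$class_means[ok]), s$global_mean,
                 tolerance = 1e-9)
  }
})

test_that("threshold sets validate bounds and monotonicity", {
  expect_error(threshold_set(c(3, 3), L = 8), "increasing")
  expect_error(threshold_set(0, L = 8), "\\[1, L-1\\]")
  expect_error(threshold_set(8, L = 8), "\\[1, L-1\\]")
  expect_error(otsu_objective(histogram_from_counts(c(1, 1)),
                              threshold_set(3, L = 8)), "L = 8")
})

test_that("exhaustive search finds the maximiser with smallest-tuple ties", {
  h2 <- histogram_from_counts(c(0, 4, 0, 0, 0, 0, 4, 0))
  res <- exhaustive_mlt(h2, 1)
  expect_identical(as.integer(res$thresholds), 2L)  # 2..6 tie at F = 6.25
  expect_equal(res$score$F, 6.25)

  hu <- histogram_from_counts(c(1, 1, 1, 1))
  res_u <- exhaustive_mlt(hu, 1)
  expect_identical(as.integer(res_u$thresholds), 2L)
  expect_equal(res_u$score$F, 1.0)

  expect_error(exhaustive_mlt(h2, 0), "K")
  expect_error(exhaustive_mlt(h2, 5), "occupied")
  expect_error(exhaustive_mlt(histogram_from_counts(rep(1, 256)), 5),
               "EPO")
})

test_that("exhaustive K=1 agrees with the classical binary Otsu reference", {
  for (seed in 1:10) {
    h <- random_histogram(64, seed + 100)
    a <- exhaustive_mlt(h, 1)
    b <- otsu_binary(h)
    expect_identical(as.integer(a$thresholds), b$threshold)
    expect_equal(a$score$F, b$sigma_b2, tolerance = 1e-12)
  }
})

test_that("between- plus within-class variance equals the total variance", {
  for (seed in 1:20) {
    h <- random_histogram(48, seed + 200)
    K <- (seed %% 4) + 1L
    ts <- threshold_set(sort(sample(1:47, K)), L = 48)
    s <- otsu_objective(h, ts)
    expect_equal(s$F + within_class_variance(h, ts), total_variance(h),
                 tolerance = 1e-9)
    expect_lte(s$F, total_variance(h) + 1e-9)
  }
})

test_that("adding a threshold never lowers the exhaustive optimum", {
  for (seed in 1:5) {
    h <- random_histogram(16, seed + 300)
    occupied <- sum(h$counts > 0)
    best <- vapply(seq_len(min(4L, occupied - 1L)), function(K) {
      exhaustive_mlt(h, K)$score$F
    }, numeric(1))
    expect_true(all(diff(best) >= -1e-12))
  }
})

test_that("label maps implement the closed-open class ranges", {
  px <- matrix(3L, 8, 8)
  px[1, 1] <- 0L; px[1, 2] <- 1L; px[1, 3] <- 2L
  img <- gray_image(px, L = 4)

  lm1 <- apply_thresholds(img, threshold_set(2, L = 4))
  expect_identical(lm1[1, 2], 0L)  # value 1 < t1 = 2 -> class 0
  expect_identical(lm1[1, 3], 1L)  # value 2 >= t1 -> class 1

  lm2 <- apply_thresholds(img, threshold_set(c(1, 3), L = 4))
  expect_identical(lm2[1, 1:3], c(0L, 1L, 1L))
  expect_identical(lm2[2, 1], 2L)  # value 3 >= t2 = 3
  expect_true(all(lm2 %in% 0:2))
})

test_that("candidate decoding yields valid strictly increasing thresholds", {
  expect_identical(as.integer(decode_thresholds(c(10.4, 3.6), 64)), c(4L, 10L))
  expect_identical(as.integer(decode_thresholds(c(5, 5.2), 64)), c(5L, 6L))
  expect_identical(as.integer(decode_thresholds(c(63, 63), 64)), c(62L, 63L))
  set.seed(4)
  for (i in 1:25) {
    x <- runif(3, 1, 63)
    ts <- decode_thresholds(x, 64)
    expect_true(all(diff(as.integer(ts)) > 0))
    expect_true(all(ts >= 1 & ts <= 63))
  }
})
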