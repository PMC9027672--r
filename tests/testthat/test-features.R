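test_that("texture features have the documented dimension and structure", {
  img <- generate_phantom(tiny_spec(mode_sds = 5, seed = 3))
  ts <- exhaustive_mlt(compute_histogram(img), 2)$thresholds
  lm <- apply_thresholds(img, ts)
  f <- extract_texture_stats(img, lm)
  expect_length(f, 4 * 3 + 4)
  expect_identical(attr(f, "extractor_id"), "texture_stats")
  # area fractions (every 4th entry of the per-class block) sum to 1
  expect_equal(sum(f[c(1, 5, 9)]), 1, tolerance = 1e-12)
  expect_true(all(is.finite(f)))
})

test_that("a constant image yields zero spread and zero entropy", {
  img <- gray_image(matrix(7L, 16, 16), L = 16)
  lm <- apply_thresholds(img, threshold_set(9, L = 16))
  f <- extract_texture_stats(img, lm)
  # class 0 holds everything: area 1, mean 7, sd 0, entropy 0
  expect_equal(f[1:4], c(1, 7, 0, 0))
  # class 1 empty: all zeros
  expect_equal(f[5:8], c(0, 0, 0, 0))
  expect_error(extract_texture_stats(img, matrix(0L, 4, 4)), "shape")
})

test_that("tumor and non-tumor noiseless phantoms separate in class means", {
  sp1 <- tiny_spec(has_tumor = TRUE, mode_sds = 0)
  sp0 <- tiny_spec(has_tumor = FALSE, mode_sds = 0)
  ts <- threshold_set(c(80, 160), L = 256)
  f1 <- extract_texture_stats(generate_phantom(sp1),
                              apply_thresholds(generate_phantom(sp1), ts))
  f0 <- extract_texture_stats(generate_phantom(sp0),
                              apply_thresholds(generate_phantom(sp0), ts))
  # the tumor class mean coordinate differs by far more than the noise sd
  expect_gt(max(abs(f1 - f0)), 5)
})

test_that("the deep-feature adapter refuses to run without local weights", {
  img <- generate_phantom(tiny_spec())
  lm <- apply_thresholds(img, threshold_set(c(80, 160), L = 256))
  expect_error(extract_mobilenet(img, lm), "extract_texture_stats")
  expect_error(extract_mobilenet(img, lm, weights = "/no/such/file"),
               "never downloads")
})

test_that("feature matrices round-trip through CSV with labels last", {
  ds <- separable_clusters(5, dim = 4, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_csv(dataset_features(ds), dataset_labels(ds), path)
  header <- names(read.csv(path))
  expect_identical(header, c("f1", "f2", "f3", "f4", "label"))
  back <- read_feature_csv(path)
  expect_equal(dataset_features(back), dataset_features(ds))
  expect_identical(dataset_labels(back), dataset_labels(ds))
})

test_that("segment_and_extract is deterministic given its seed", {
  img <- generate_phantom(tiny_spec(mode_sds = 5, seed = 5))
  a <- segment_and_extract(img, epo = epo_params(10, 20, seed = 4))
  b <- segment_and_extract(img, epo = epo_params(10, 20, seed = 4))
  expect_identical(a$features, b$features)
  expect_identical(a$thresholds, b$thresholds)
  expect_identical(dim(a$label_map), dim(img))
})
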