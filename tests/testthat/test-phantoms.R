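test_that("noiseless phantoms contain exactly the mode intensities", {
  img <- generate_phantom(tiny_spec(has_tumor = TRUE, mode_sds = 0, seed = 7))
  expect_identical(sort(unique(as.vector(img))), c(40L, 120L, 200L))

  img0 <- generate_phantom(tiny_spec(has_tumor = FALSE, mode_sds = 0, seed = 7))
  expect_identical(sort(unique(as.vector(img0))), c(40L, 120L))

  # histogram mass only at the modes
  h <- compute_histogram(img)
  expect_identical(which(h$counts > 0) - 1L, c(40L, 120L, 200L))
})

test_that("phantom generation is a pure function of spec and seed", {
  sp <- tiny_spec(mode_sds = 5, seed = 7)
  expect_identical(generate_phantom(sp), generate_phantom(sp))
  sp2 <- tiny_spec(mode_sds = 5, seed = 8)
  expect_false(identical(generate_phantom(sp), generate_phantom(sp2)))
})

test_that("noisy phantom region means stay close to the mode means", {
  sp <- phantom_spec(mode_sds = 5, seed = 21)
  img <- generate_phantom(sp)
  region <- phantom_regions(sp)
  for (k in 0:2) {
    expect_lt(abs(mean(img[region == k]) - sp$mode_intensities[k + 1]), 2)
  }
})

test_that("invalid phantom specs raise errors naming the field", {
  expect_error(phantom_spec(mode_intensities = c(120, 40, 200)),
               "mode_intensities")
  expect_error(phantom_spec(organ_ellipse = list(center = c(5, 64),
                                                 axes = c(38, 26),
                                                 angle = 0)),
               "organ_ellipse")
  expect_error(phantom_spec(has_tumor = FALSE,
                            tumor_blob = list(center = c(64, 64), radius = 5)),
               "tumor_blob")
  expect_error(phantom_spec(has_tumor = TRUE, tumor_blob = NULL),
               "tumor_blob")
  # tumor blob centered outside the organ
  expect_error(phantom_spec(tumor_blob = list(center = c(5, 5), radius = 3)),
               "tumor_blob")
})

test_that("generate_dataset is balanced, sized 2n, and seed-reproducible", {
  base <- tiny_spec()
  ds <- generate_dataset(5, base, jitter = tiny_jitter, seed = 2)
  expect_length(ds$items, 10L)
  expect_identical(sum(ds$labels == 1L), 5L)
  expect_identical(sum(ds$labels == 0L), 5L)

  ds_min <- generate_dataset(1, base, jitter = tiny_jitter, seed = 2)
  expect_length(ds_min$items, 2L)
  expect_setequal(ds_min$labels, c(0L, 1L))

  ds2 <- generate_dataset(5, base, jitter = tiny_jitter, seed = 2)
  expect_identical(ds$labels, ds2$labels)
  expect_identical(attr(ds, "specs"), attr(ds2, "specs"))
  expect_identical(ds$items, ds2$items)

  expect_error(generate_dataset(0, base), "n_per_class")
})

test_that("the study-scale dataset has 500 items, 250 per label", {
  base <- tiny_spec()
  ds <- generate_dataset(250, base, jitter = tiny_jitter, seed = 1)
  expect_length(ds$items, 500L)
  expect_identical(unname(ds$class_counts), c(250L, 250L))
})

test_that("feature clusters are separable by the nearest-center rule", {
  ds <- separable_clusters(50, dim = 8, seed = 4)
  X <- dataset_features(ds)
  y <- dataset_labels(ds)
  c0 <- rep(0, 8)
  c1 <- rep(10, 8)
  pred <- as.integer(colSums((t(X) - c1)^2) < colSums((t(X) - c0)^2))
  expect_identical(pred, y)

  expect_identical(separable_clusters(10, seed = 5)$items,
                   separable_clusters(10, seed = 5)$items)
  expect_error(generate_feature_clusters(0, 2, list(c(0, 0), c(1, 1))),
               "n_per_class")
  expect_error(generate_feature_clusters(5, 2, list(c(1, 1), c(1, 1))),
               "centers")
})

test_that("multimodal histograms are seeded and well-formed", {
  h <- generate_multimodal_histogram(L = 64, seed = 9)
  h2 <- generate_multimodal_histogram(L = 64, seed = 9)
  expect_identical(h, h2)
  expect_equal(sum(h$probs), 1, tolerance = 1e-12)
  expect_length(h$counts, 64L)
})

test_that("phantom datasets round-trip through PNG plus manifest", {
  dir <- withr::local_tempdir()
  ds <- generate_dataset(2, tiny_spec(), jitter = tiny_jitter, seed = 6)
  manifest <- write_phantom_dataset(ds, dir)
  man <- read.csv(manifest)
  expect_identical(nrow(man), 4L)
  expect_identical(sort(man$label), c(0L, 0L, 1L, 1L))
  img <- read_image_png(file.path(dir, man$filename[1]))
  expect_identical(dim(img), dim(ds$items[[1]]))
  expect_identical(as.integer(img), as.integer(ds$items[[1]]))
})
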