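#' Labeled dataset container
#'
#' Holds a list of items (images or feature vectors) with binary labels
#' (0 = non-tumor, 1 = tumor).
#'
#' @param items List of [gray_image()] objects or numeric feature vectors.
#' @param labels Integer vector of 0/1 labels, one per item.
#' @return A `labeled_dataset` list with `items`, `labels`, `class_counts`.
#' @export
labeled_dataset <- function(items, labels) {
  labels <- as.integer(labels)
  if (length(items) != length(labels)) {
    stop("`items` and `labels` lengths differ", call. = FALSE)
  }
  if (!all(labels %in% c(0L, 1L))) {
    stop("`labels` must be 0 (non-tumor) or 1 (tumor)", call. = FALSE)
  }
  structure(list(items = items, labels = labels,
                 class_counts = c(`0` = sum(labels == 0L),
                                  `1` = sum(labels == 1L))),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset: %d items (%d non-tumor, %d tumor)>\n",
              length(x$items), x$class_counts[["0"]], x$class_counts[["1"]]))
  invisible(x)
}

#' @rdname labeled_dataset
#' @param dataset A `labeled_dataset` whose items are numeric vectors.
#' @return `dataset_features()` returns the items stacked as a matrix (one
#'   row per item); `dataset_labels()` the label vector.
#' @export
dataset_features <- function(dataset) {
  if (!inherits(dataset, "labeled_dataset")) stop("expected a labeled_dataset", call. = FALSE)
  do.call(rbind, lapply(dataset$items, as.numeric))
}

#' @rdname labeled_dataset
#' @export
dataset_labels <- function(dataset) {
  if (!inherits(dataset, "labeled_dataset")) stop("expected a labeled_dataset", call. = FALSE)
  dataset$labels
}

# Half-extent of a rotated ellipse along image rows/cols.
.ellipse_extent <- function(axes, angle) {
  c(row = sqrt((axes[1] * sin(angle))^2 + (axes[2] * cos(angle))^2),
    col = sqrt((axes[1] * cos(angle))^2 + (axes[2] * sin(angle))^2))
}

#' Phantom image specification
#'
#' Describes one synthetic CT-like image: a dark background, a brighter
#' elliptical "organ", and (for tumor-labelled phantoms) a still-brighter
#' circular "tumor" blob inside the organ. Each region's intensity is its
#' mode mean plus additive Gaussian noise, rounded and clipped to
#' `[0, L - 1]`, so a noiseless phantom has a three-spike histogram at
#' exactly the mode intensities.
#'
#' @param image_size `c(height, width)`, each >= 8 (default 128 x 128).
#' @param mode_intensities Strictly increasing background/organ/tumor mean
#'   intensities (default `c(40, 120, 200)`).
#' @param mode_sds Per-mode Gaussian noise standard deviations (default 5).
#' @param organ_ellipse List with `center` `c(row, col)`, `axes` `c(a, b)`
#'   (semi-axes in pixels) and `angle` (radians); must fit inside the image.
#' @param tumor_blob List with `center` and `radius` (pixels), required when
#'   `has_tumor`; its center must lie inside the organ ellipse.
#' @param has_tumor Logical label; a blob is drawn iff `TRUE`.
#' @param L Gray-level count (default 256).
#' @param seed Integer seed for the noise.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(image_size = c(128L, 128L),
                         mode_intensities = c(40, 120, 200),
                         mode_sds = c(5, 5, 5),
                         organ_ellipse = list(center = c(64, 64),
                                              axes = c(38, 26),
                                              angle = 0.5),
                         tumor_blob = if (has_tumor) list(center = c(68, 70), radius = 9),
                         has_tumor = TRUE,
                         L = 256L, seed = 1L) {
  image_size <- as.integer(image_size)
  if (length(image_size) != 2L || any(image_size < 8L)) {
    stop("invalid `image_size`: need height and width >= 8", call. = FALSE)
  }
  if (length(mode_intensities) != 3L || any(diff(mode_intensities) <= 0)) {
    stop("invalid `mode_intensities`: must be 3 strictly increasing values",
         call. = FALSE)
  }
  if (any(mode_intensities < 0) || any(mode_intensities > L - 1)) {
    stop("invalid `mode_intensities`: values must lie in [0, L-1]", call. = FALSE)
  }
  mode_sds <- rep_len(as.numeric(mode_sds), 3L)
  if (any(mode_sds < 0)) stop("invalid `mode_sds`: must be nonnegative", call. = FALSE)
  ext <- .ellipse_extent(organ_ellipse$axes, organ_ellipse$angle)
  ctr <- organ_ellipse$center
  if (any(organ_ellipse$axes <= 0) ||
      ctr[1] - ext["row"] < 1 || ctr[1] + ext["row"] > image_size[1] ||
      ctr[2] - ext["col"] < 1 || ctr[2] + ext["col"] > image_size[2]) {
    stop("invalid `organ_ellipse`: must lie fully inside the image", call. = FALSE)
  }
  if (has_tumor) {
    if (is.null(tumor_blob)) {
      stop("invalid `tumor_blob`: required when `has_tumor`", call. = FALSE)
    }
    if (tumor_blob$radius <= 0) {
      stop("invalid `tumor_blob`: radius must be positive", call. = FALSE)
    }
    if (!.inside_ellipse(tumor_blob$center[1], tumor_blob$center[2],
                         organ_ellipse)) {
      stop("invalid `tumor_blob`: center must lie inside the organ ellipse",
           call. = FALSE)
    }
  } else if (!is.null(tumor_blob)) {
    stop("invalid `tumor_blob`: must be absent when `has_tumor` is FALSE",
         call. = FALSE)
  }
  structure(list(image_size = image_size,
                 mode_intensities = as.numeric(mode_intensities),
                 mode_sds = mode_sds,
                 organ_ellipse = organ_ellipse,
                 tumor_blob = if (has_tumor) tumor_blob else NULL,
                 has_tumor = isTRUE(has_tumor),
                 L = as.integer(L), seed = as.integer(seed)),
            class = "phantom_spec")
}

.inside_ellipse <- function(r, c, ellipse) {
  u <- c - ellipse$center[2]
  v <- r - ellipse$center[1]
  a <- ellipse$angle
  xp <- u * cos(a) + v * sin(a)
  yp <- -u * sin(a) + v * cos(a)
  (xp / ellipse$axes[1])^2 + (yp / ellipse$axes[2])^2 <= 1
}

#' Region masks of a phantom
#'
#' @param spec A [phantom_spec()].
#' @return Integer matrix of ground-truth region labels: 0 background,
#'   1 organ, 2 tumor.
#' @export
phantom_regions <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stop("expected a phantom_spec", call. = FALSE)
  h <- spec$image_size[1]
  w <- spec$image_size[2]
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  region <- matrix(0L, h, w)
  region[.inside_ellipse(rows, cols, spec$organ_ellipse)] <- 1L
  if (spec$has_tumor) {
    d2 <- (rows - spec$tumor_blob$center[1])^2 +
      (cols - spec$tumor_blob$center[2])^2
    region[region == 1L & d2 <= spec$tumor_blob$radius^2] <- 2L
  }
  region
}

#' Generate one phantom image
#'
#' Renders the regions of `spec` at their mode intensities, adds per-mode
#' Gaussian noise, and rounds/clips to `[0, L - 1]`. Identical specs
#' (including seed) yield bit-identical images.
#'
#' @param spec A [phantom_spec()].
#' @return A [gray_image()].
#' @examples
#' img <- generate_phantom(phantom_spec(mode_sds = 0, seed = 3))
#' sort(unique(as.vector(img)))  # exactly the mode intensities
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stop("expected a phantom_spec", call. = FALSE)
  region <- phantom_regions(spec)
  px <- spec$mode_intensities[region + 1L]
  with_private_seed(spec$seed, {
    sds <- spec$mode_sds[region + 1L]
    noisy <- which(sds > 0)
    if (length(noisy) > 0) {
      px[noisy] <- px[noisy] + stats::rnorm(length(noisy), 0, sds[noisy])
    }
  })
  px <- pmin(pmax(round(px), 0), spec$L - 1L)
  gray_image(matrix(as.integer(px), spec$image_size[1], spec$image_size[2]),
             L = spec$L)
}

# Draw one jittered per-item spec. `rng` draws come from the caller's stream.
.jitter_spec <- function(base, jitter, label, item_seed) {
  j <- function(name, default) if (!is.null(jitter[[name]])) jitter[[name]] else default
  ctr_j <- j("center", 6)
  axes_j <- j("axes", 5)
  angle_j <- j("angle", 0.3)
  radius_j <- j("radius", 3)
  int_j <- j("intensity", 10)

  ell <- base$organ_ellipse
  ell$center <- ell$center + stats::runif(2, -ctr_j, ctr_j)
  ell$axes <- pmax(ell$axes + stats::runif(2, -axes_j, axes_j), 8)
  ell$angle <- ell$angle + stats::runif(1, -angle_j, angle_j)

  modes <- base$mode_intensities + stats::runif(3, -int_j, int_j)
  # jitter is bounded well below half the mode gaps, so order is preserved

  blob <- NULL
  if (label == 1L) {
    radius <- max(base$tumor_blob$radius + stats::runif(1, -radius_j, radius_j), 4)
    # place the blob center at a bounded offset from the organ center so it
    # stays inside the ellipse
    frac <- stats::runif(1, 0, 0.4)
    dir <- stats::runif(1, 0, 2 * pi)
    amin <- min(ell$axes)
    blob <- list(center = c(ell$center[1] + frac * amin * sin(dir),
                            ell$center[2] + frac * amin * cos(dir)),
                 radius = radius)
  }
  phantom_spec(image_size = base$image_size,
               mode_intensities = modes,
               mode_sds = base$mode_sds,
               organ_ellipse = ell,
               tumor_blob = blob,
               has_tumor = label == 1L,
               L = base$L,
               seed = item_seed)
}

#' Generate a balanced labeled phantom dataset
#'
#' Draws `2 * n_per_class` per-item specifications by jittering `base_spec`
#' (organ geometry, tumor blob, mode intensities) and renders each phantom.
#' Exactly `n_per_class` items carry each label; everything derives
#' reproducibly from `seed`.
#'
#' @param n_per_class Number of items per label (>= 1).
#' @param base_spec A [phantom_spec()] used as the jitter center; must have
#'   `has_tumor = TRUE` so a tumor-blob prototype exists.
#' @param jitter Named list of perturbation half-ranges: `center`, `axes`,
#'   `angle` (radians), `radius`, `intensity`. Defaults: 6 px, 5 px, 0.3,
#'   3 px, 10 intensity units.
#' @param seed Integer seed.
#' @return A [labeled_dataset()] of [gray_image()] items; the per-item specs
#'   are attached as attribute `specs`.
#' @export
generate_dataset <- function(n_per_class, base_spec = phantom_spec(),
                             jitter = list(), seed = 1L) {
  n_per_class <- as.integer(n_per_class)
  if (is.na(n_per_class) || n_per_class < 1L) {
    stop("`n_per_class` must be >= 1", call. = FALSE)
  }
  if (!inherits(base_spec, "phantom_spec") || !base_spec$has_tumor) {
    stop("`base_spec` must be a phantom_spec with has_tumor = TRUE", call. = FALSE)
  }
  labels <- rep(c(1L, 0L), each = n_per_class)
  specs <- with_private_seed(seed, {
    item_seeds <- sample.int(.Machine$integer.max - 1L, 2L * n_per_class)
    lapply(seq_along(labels), function(i) {
      .jitter_spec(base_spec, jitter, labels[i], item_seeds[i])
    })
  })
  items <- lapply(specs, generate_phantom)
  ds <- labeled_dataset(items, labels)
  attr(ds, "specs") <- specs
  ds
}

#' Generate two separable Gaussian feature clusters
#'
#' Test fixture for the classifier: `n_per_class` points per label drawn from
#' isotropic Gaussians about two distinct centers.
#'
#' @param n_per_class Points per label (>= 1).
#' @param dim Feature dimension.
#' @param centers List of two distinct numeric vectors of length `dim`
#'   (label 0 and label 1 cluster centers).
#' @param sd Isotropic standard deviation (> 0).
#' @param seed Integer seed.
#' @return A [labeled_dataset()] of numeric feature vectors.
#' @export
generate_feature_clusters <- function(n_per_class, dim, centers, sd = 1,
                                      seed = 1L) {
  n_per_class <- as.integer(n_per_class)
  if (is.na(n_per_class) || n_per_class < 1L) {
    stop("`n_per_class` must be >= 1", call. = FALSE)
  }
  if (length(centers) != 2L ||
      length(centers[[1]]) != dim || length(centers[[2]]) != dim) {
    stop("`centers` must be two vectors of length `dim`", call. = FALSE)
  }
  if (isTRUE(all.equal(centers[[1]], centers[[2]]))) {
    stop("`centers` must be distinct", call. = FALSE)
  }
  if (sd <= 0) stop("`sd` must be positive", call. = FALSE)
  labels <- rep(c(0L, 1L), each = n_per_class)
  items <- with_private_seed(seed, {
    lapply(labels, function(lab) {
      centers[[lab + 1L]] + stats::rnorm(dim, 0, sd)
    })
  })
  labeled_dataset(items, labels)
}

#' Generate a seeded multimodal gray-level histogram
#'
#' Samples pixel intensities from a mixture of Gaussians with random means,
#' spreads and weights, rounds and clips them to `[0, L - 1]`, and tabulates.
#' Used to exercise the multilevel-threshold search on histograms with a
#' known multimodal structure.
#'
#' @param L Gray-level count (default 64).
#' @param n_modes Number of mixture modes (default 3).
#' @param n_pixels Number of sampled intensities (default 8000).
#' @param seed Integer seed.
#' @return A `gl_histogram`.
#' @export
generate_multimodal_histogram <- function(L = 64L, n_modes = 3L,
                                          n_pixels = 8000L, seed = 1L) {
  L <- as.integer(L)
  n_modes <- as.integer(n_modes)
  if (n_modes < 2L) stop("`n_modes` must be >= 2", call. = FALSE)
  counts <- with_private_seed(seed, {
    mu <- sort(stats::runif(n_modes, 0.06 * L, 0.94 * L))
    sd <- stats::runif(n_modes, 0.03 * L, 0.09 * L)
    w <- stats::runif(n_modes, 0.5, 1.5)
    w <- w / sum(w)
    sizes <- round(n_pixels * w)
    v <- unlist(lapply(seq_len(n_modes), function(k) {
      stats::rnorm(sizes[k], mu[k], sd[k])
    }))
    tabulate(pmin(pmax(round(v), 0), L - 1L) + 1L, nbins = L)
  })
  histogram_from_counts(counts)
}

#' Write a phantom dataset to disk
#'
#' Writes each phantom as an 8-bit grayscale PNG plus a CSV manifest with
#' columns `filename`, `label`, `seed` and the three mode intensities.
#'
#' @param dataset A [labeled_dataset()] from [generate_dataset()].
#' @param dir Output directory (created if missing).
#' @return Path of the manifest CSV, invisibly.
#' @export
write_phantom_dataset <- function(dataset, dir) {
  if (!inherits(dataset, "labeled_dataset")) stop("expected a labeled_dataset", call. = FALSE)
  specs <- attr(dataset, "specs")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(dataset$items)
  fn <- sprintf("phantom_%04d.png", seq_len(n))
  for (i in seq_len(n)) {
    write_image_png(dataset$items[[i]], file.path(dir, fn[i]))
  }
  manifest <- data.frame(
    filename = fn,
    label = dataset$labels,
    seed = if (is.null(specs)) NA_integer_ else
      vapply(specs, function(s) s$seed, integer(1)),
    mode_background = if (is.null(specs)) NA_real_ else
      vapply(specs, function(s) s$mode_intensities[1], numeric(1)),
    mode_organ = if (is.null(specs)) NA_real_ else
      vapply(specs, function(s) s$mode_intensities[2], numeric(1)),
    mode_tumor = if (is.null(specs)) NA_real_ else
      vapply(specs, function(s) s$mode_intensities[3], numeric(1))
  )
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}
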