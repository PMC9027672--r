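#' Statistical texture features from a segmented image
#'
#' The built-in, fully offline feature extractor. For each of the `K + 1`
#' segmentation classes it computes four region statistics — area fraction,
#' mean intensity, intensity standard deviation, and Shannon entropy (base 2)
#' of the region's gray-level distribution — and appends four whole-image
#' histogram moments (mean, sd, skewness, kurtosis). The dimension is
#' therefore `4 * (K + 1) + 4`. Empty classes contribute zeros.
#'
#' @param image A [gray_image()].
#' @param label_map Integer class-label matrix from [apply_thresholds()],
#'   same shape as `image`, with attribute `K`.
#' @return Numeric feature vector with attribute `extractor_id = "texture_stats"`.
#' @export
extract_texture_stats <- function(image, label_map) {
  assert_gray_image(image)
  if (!is.matrix(label_map) || !all(dim(label_map) == dim(image))) {
    stop("`label_map` must be a matrix with the same shape as `image`",
         call. = FALSE)
  }
  K <- attr(label_map, "K")
  if (is.null(K)) K <- max(label_map)
  n <- length(image)
  vals <- as.numeric(image)
  labs <- as.integer(label_map)

  per_class <- lapply(0:K, function(k) {
    v <- vals[labs == k]
    if (length(v) == 0L) return(c(0, 0, 0, 0))
    tab <- table(v) / length(v)
    entropy <- -sum(tab * log2(tab))
    c(length(v) / n, mean(v),
      if (length(v) > 1L) stats::sd(v) else 0,
      entropy)
  })
  mu <- mean(vals)
  s <- stats::sd(vals)
  skew <- if (s > 0) mean((vals - mu)^3) / s^3 else 0
  kurt <- if (s > 0) mean((vals - mu)^4) / s^4 else 0
  out <- c(unlist(per_class), mu, s, skew, kurt)
  if (any(!is.finite(out))) stop("non-finite feature computed", call. = FALSE)
  attr(out, "extractor_id") <- "texture_stats"
  out
}

#' MobileNetV2 feature adapter (optional, requires local weights)
#'
#' Deep-feature alternative to [extract_texture_stats()]: the segmented image
#' would be replicated to three channels, bilinearly resized to 224 x 224 and
#' passed through a pretrained MobileNetV2, returning the 1280-dimensional
#' global-pooled penultimate activations. The adapter never downloads
#' weights: it requires a local weights file and an available deep-learning
#' runtime, and raises an informative error otherwise so offline pipelines
#' fall back to the texture extractor explicitly.
#'
#' @param image A [gray_image()].
#' @param label_map Segmentation label map (masking is applied before the
#'   network in this design).
#' @param weights Path to a local MobileNetV2 weights file.
#' @return Numeric feature vector of length 1280 (when a runtime and weights
#'   are available).
#' @export
extract_mobilenet <- function(image, label_map, weights = NULL) {
  if (is.null(weights) || !file.exists(weights)) {
    stop(paste("MobileNetV2 weights not available locally; this adapter",
               "never downloads. Use extract_texture_stats() as the offline",
               "feature extractor."), call. = FALSE)
  }
  stop(paste("no deep-learning runtime is available to load MobileNetV2;",
             "use extract_texture_stats() instead."), call. = FALSE)
}

#' Segment one image and extract features
#'
#' Pipeline building block: optional Gabor preprocessing, EPO-driven
#' multilevel Otsu segmentation with `K` thresholds, then the texture feature
#' extractor.
#'
#' @param image A [gray_image()].
#' @param K Threshold count for segmentation (default 2, i.e. three classes:
#'   background / organ / tumor candidate).
#' @param gabor_bank Gabor bank, or `NULL` to skip preprocessing.
#' @param epo An [epo_params()] for the threshold search.
#' @return List with `features`, `thresholds`, `label_map`, `filtered`.
#' @export
segment_and_extract <- function(image, K = 2L, gabor_bank = default_gabor_bank(),
                                epo = epo_params(population_size = 20L,
                                                 max_iterations = 60L)) {
  filtered <- if (is.null(gabor_bank)) image else gabor_filter(image, gabor_bank)
  hist <- compute_histogram(filtered)
  seg <- epo_mlt(hist, K, epo)
  label_map <- apply_thresholds(filtered, seg$thresholds)
  feats <- extract_texture_stats(filtered, label_map)
  list(features = feats, thresholds = seg$thresholds,
       label_map = label_map, filtered = filtered)
}

#' Write a feature matrix as CSV
#'
#' One row per image; feature columns `f1 ... fd`, label column last.
#'
#' @param features Numeric matrix (rows = items).
#' @param labels Integer 0/1 labels.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(features, labels, path) {
  if (nrow(features) != length(labels)) {
    stop("`features` rows and `labels` length differ", call. = FALSE)
  }
  df <- as.data.frame(features)
  names(df) <- sprintf("f%d", seq_len(ncol(features)))
  df$label <- as.integer(labels)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature CSV written by [write_feature_csv()]
#'
#' @param path CSV path.
#' @return A [labeled_dataset()] of feature vectors.
#' @export
read_feature_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!"label" %in% names(df)) stop("feature CSV must have a `label` column", call. = FALSE)
  labels <- as.integer(df$label)
  feats <- as.matrix(df[setdiff(names(df), "label")])
  labeled_dataset(lapply(seq_len(nrow(feats)), function(i) as.numeric(feats[i, ])),
                  labels)
}
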