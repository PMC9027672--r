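#' Pipeline configuration
#'
#' Collects the tunables of the full image-to-label pipeline.
#'
#' @param K Threshold count for segmentation (default 2: background / organ /
#'   tumor-candidate classes, matching the phantom structure).
#' @param use_gabor Apply Gabor preprocessing (default `TRUE`).
#' @param gabor_bank Gabor bank (default [default_gabor_bank()]).
#' @param epo_population,epo_iterations Emperor-penguin search budget per
#'   image (defaults 20 and 60; the histogram objective is smooth at desk
#'   scale).
#' @param latent_dim Autoencoder latent dimension, or `NULL` for
#'   `ceiling(m / 4)`.
#' @param activation Autoencoder activation.
#' @param mlo_population,mlo_iterations,mlo_leaders Multileader tuning budget
#'   (defaults 30, 120, 3).
#' @param search_box Weight/bias search half-width (default 3).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(K = 2L, use_gabor = TRUE,
                            gabor_bank = default_gabor_bank(),
                            epo_population = 20L, epo_iterations = 60L,
                            latent_dim = NULL,
                            activation = "sigmoid",
                            mlo_population = 30L, mlo_iterations = 120L,
                            mlo_leaders = 3L, search_box = 3) {
  structure(list(K = as.integer(K), use_gabor = isTRUE(use_gabor),
                 gabor_bank = gabor_bank,
                 epo_population = as.integer(epo_population),
                 epo_iterations = as.integer(epo_iterations),
                 latent_dim = latent_dim, activation = activation,
                 mlo_population = as.integer(mlo_population),
                 mlo_iterations = as.integer(mlo_iterations),
                 mlo_leaders = as.integer(mlo_leaders),
                 search_box = search_box),
            class = "pipeline_config")
}

#' Evaluation plan
#'
#' Either a series of stratified train/test splits at the given training
#' fractions, or stratified k-fold cross-validation at the given fold counts.
#'
#' @param mode `"train_split"` or `"kfold"`.
#' @param train_fractions Training fractions in (0, 1)
#'   (default `c(0.4, 0.5, 0.6, 0.7, 0.8)`).
#' @param folds Fold counts (default `6:10`).
#' @param seed Integer seed for the whole evaluation.
#' @return An `eval_plan` list.
#' @export
eval_plan <- function(mode = c("train_split", "kfold"),
                      train_fractions = c(0.4, 0.5, 0.6, 0.7, 0.8),
                      folds = 6:10, seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "train_split" &&
      (any(train_fractions <= 0) || any(train_fractions >= 1))) {
    stop("`train_fractions` must lie in (0, 1)", call. = FALSE)
  }
  if (mode == "kfold" && any(folds < 2L)) {
    stop("`folds` must all be >= 2", call. = FALSE)
  }
  structure(list(mode = mode, train_fractions = train_fractions,
                 folds = as.integer(folds), seed = as.integer(seed)),
            class = "eval_plan")
}

# Deterministic per-item sub-seed derived from the global seed (kept within
# 32-bit integer range).
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(i) * 16807) %% 2147483647) + 1L
}

#' Segment a phantom dataset and extract feature vectors
#'
#' Runs the per-image stages (Gabor preprocessing, EPO multilevel Otsu
#' segmentation, texture feature extraction) for every item. Each image gets
#' its own search seed derived from `seed` and the item index, so results are
#' reproducible and independent across images. Per-image stages use no
#' information from other images, so features may be computed once and split
#' afterwards without leakage.
#'
#' @param dataset A [labeled_dataset()] of [gray_image()] items.
#' @param config A [pipeline_config()].
#' @param seed Integer seed.
#' @return A [labeled_dataset()] of feature vectors, with per-image
#'   thresholds attached as attribute `thresholds`.
#' @export
extract_dataset_features <- function(dataset, config = pipeline_config(),
                                     seed = 1L) {
  if (!inherits(dataset, "labeled_dataset")) stop("expected a labeled_dataset", call. = FALSE)
  n <- length(dataset$items)
  out <- vector("list", n)
  thr <- vector("list", n)
  for (i in seq_len(n)) {
    res <- tryCatch(
      segment_and_extract(
        dataset$items[[i]], K = config$K,
        gabor_bank = if (config$use_gabor) config$gabor_bank else NULL,
        epo = epo_params(population_size = config$epo_population,
                         max_iterations = config$epo_iterations,
                         seed = derive_seed(seed, i))),
      error = function(e) {
        stop(sprintf("stage 'segment_and_extract' failed on item %d: %s",
                     i, conditionMessage(e)), call. = FALSE)
      })
    out[[i]] <- res$features
    thr[[i]] <- as.integer(res$thresholds)
  }
  fd <- labeled_dataset(out, dataset$labels)
  attr(fd, "thresholds") <- thr
  fd
}

# Train on one split and evaluate on its test portion.
.eval_split <- function(features, train_idx, test_idx, config, seed) {
  y <- dataset_labels(features)
  train <- labeled_dataset(features$items[train_idx], y[train_idx])
  X <- dataset_features(train)
  cfg <- ae_config(ncol(X),
                   latent_dim = if (is.null(config$latent_dim))
                     ceiling(ncol(X) / 4) else config$latent_dim,
                   activation = config$activation)
  model <- train_mlo(train, cfg,
                     mlo = mlo_params(population_size = config$mlo_population,
                                      n_leaders = config$mlo_leaders,
                                      max_iterations = config$mlo_iterations,
                                      seed = seed),
                     search_box = config$search_box)
  test_X <- do.call(rbind, lapply(features$items[test_idx], as.numeric))
  pred <- classify(test_X, model)
  list(cm = confusion_matrix(pred, y[test_idx]), model = model)
}

# Average metric rows, skipping NA (undefined) entries per column.
.average_row <- function(rows) {
  data.frame(sensitivity = mean(rows$sensitivity, na.rm = TRUE),
             specificity = mean(rows$specificity, na.rm = TRUE),
             accuracy = mean(rows$accuracy, na.rm = TRUE),
             f_score = mean(rows$f_score, na.rm = TRUE))
}

#' Run the full pipeline under an evaluation plan
#'
#' For every split of the plan: preprocess and segment the images, extract
#' features, tune the per-class autoencoders on the training portion only
#' (feature scaling included), predict the test portion, and accumulate a
#' confusion matrix. Returns one metric row per split plus an `Average` row
#' (undefined metrics are `NA` and excluded from averages). The whole run is
#' a pure function of the inputs and `plan$seed`.
#'
#' @param images A [labeled_dataset()] of [gray_image()] items (>= 10 items,
#'   both classes present).
#' @param config A [pipeline_config()].
#' @param plan An [eval_plan()].
#' @return List of class `pipeline_report`: `report` (data frame with a
#'   `split` column), `confusions`, `features`.
#' @export
run_pipeline <- function(images, config = pipeline_config(),
                         plan = eval_plan(seed = 1L)) {
  if (!inherits(images, "labeled_dataset")) stop("expected a labeled_dataset", call. = FALSE)
  if (length(images$items) < 10L) stop("need at least 10 images", call. = FALSE)
  features <- extract_dataset_features(images, config, seed = plan$seed)
  y <- dataset_labels(features)

  rows <- list()
  cms <- list()
  if (plan$mode == "train_split") {
    for (j in seq_along(plan$train_fractions)) {
      fr <- plan$train_fractions[j]
      sp <- split_train_test(features, fr, seed = derive_seed(plan$seed, 1000L + j))
      ev <- .eval_split(features, sp$train_idx,
                        setdiff(seq_along(y), sp$train_idx),
                        config, seed = derive_seed(plan$seed, 2000L + j))
      rows[[j]] <- cbind(data.frame(split = sprintf("TS=%d%%", round(100 * fr))),
                         compute_metrics(ev$cm))
      cms[[j]] <- ev$cm
    }
  } else {
    j <- 0L
    for (fo in plan$folds) {
      j <- j + 1L
      kf <- kfold_plan(features, fo, seed = derive_seed(plan$seed, 3000L + j))
      # pool test predictions over the folds into one confusion matrix
      tot <- list(TP = 0L, FP = 0L, TN = 0L, FN = 0L)
      for (k in seq_along(kf)) {
        ev <- .eval_split(features,
                          setdiff(seq_along(y), kf[[k]]$test_idx),
                          kf[[k]]$test_idx, config,
                          seed = derive_seed(plan$seed, 4000L + 100L * j + k))
        for (f in names(tot)) tot[[f]] <- tot[[f]] + ev$cm[[f]]
      }
      cm <- structure(tot, class = "confusion_matrix")
      rows[[j]] <- cbind(data.frame(split = sprintf("CV=%d", fo)),
                         compute_metrics(cm))
      cms[[j]] <- cm
    }
  }
  report <- do.call(rbind, rows)
  report <- rbind(report,
                  cbind(data.frame(split = "Average"), .average_row(report)))
  rownames(report) <- NULL
  structure(list(report = report, confusions = cms, features = features),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  print(x$report, digits = 4)
  invisible(x)
}
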