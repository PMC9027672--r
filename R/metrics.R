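#' Confusion matrix for binary tumor classification
#'
#' Tumor (label 1) is the positive class.
#'
#' @param predictions,labels Equal-length 0/1 vectors.
#' @return A `confusion_matrix` list with `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_matrix <- function(predictions, labels) {
  if (length(predictions) != length(labels) || length(labels) == 0L) {
    stop("`predictions` and `labels` must be non-empty and equal length",
         call. = FALSE)
  }
  structure(list(TP = sum(predictions == 1L & labels == 1L),
                 FP = sum(predictions == 1L & labels == 0L),
                 TN = sum(predictions == 0L & labels == 0L),
                 FN = sum(predictions == 0L & labels == 1L)),
            class = "confusion_matrix")
}

.safe_ratio <- function(num, den) if (den > 0) num / den else NA_real_

#' Classification metrics from a confusion matrix
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, accuracy
#' `(TP+TN)/total`, and F-score `2*precision*recall/(precision+recall)` with
#' precision `TP/(TP+FP)`. A zero denominator yields `NA` (an explicit
#' "undefined" marker), never a silent zero, and `NA` propagates from
#' precision/recall into the F-score.
#'
#' @param cm A [confusion_matrix()].
#' @return One-row data frame: `sensitivity`, `specificity`, `accuracy`,
#'   `f_score`.
#' @examples
#' compute_metrics(confusion_matrix(rep(1, 4), c(1, 1, 1, 0)))
#' @export
compute_metrics <- function(cm) {
  if (!inherits(cm, "confusion_matrix")) {
    stop("expected a confusion_matrix()", call. = FALSE)
  }
  sens <- .safe_ratio(cm$TP, cm$TP + cm$FN)
  spec <- .safe_ratio(cm$TN, cm$TN + cm$FP)
  acc <- .safe_ratio(cm$TP + cm$TN, cm$TP + cm$TN + cm$FP + cm$FN)
  prec <- .safe_ratio(cm$TP, cm$TP + cm$FP)
  f <- if (is.na(prec) || is.na(sens) || prec + sens == 0) NA_real_ else
    2 * prec * sens / (prec + sens)
  data.frame(sensitivity = sens, specificity = spec, accuracy = acc,
             f_score = f)
}

#' Stratified train/test split
#'
#' Splits a labeled dataset into train and test portions, sampling
#' `round(fraction * n_c)` training items within each class `c`, so the
#' class balance is preserved to within one item. Reproducible under `seed`.
#'
#' @param dataset A [labeled_dataset()] with both classes present (>= 2 items
#'   each).
#' @param fraction Training fraction in (0, 1).
#' @param seed Integer seed.
#' @return List with `train` and `test` [labeled_dataset()]s and the
#'   selected `train_idx`.
#' @export
split_train_test <- function(dataset, fraction, seed = 1L) {
  if (!inherits(dataset, "labeled_dataset")) stop("expected a labeled_dataset", call. = FALSE)
  if (fraction <= 0 || fraction >= 1) stop("`fraction` must be in (0, 1)", call. = FALSE)
  y <- dataset$labels
  if (min(table(factor(y, levels = c(0L, 1L)))) < 2L) {
    stop("each class needs at least 2 items", call. = FALSE)
  }
  train_idx <- with_private_seed(seed, {
    unlist(lapply(c(0L, 1L), function(cl) {
      idx <- which(y == cl)
      n_tr <- max(1L, min(length(idx) - 1L, round(fraction * length(idx))))
      sort(sample(idx, n_tr))
    }))
  })
  subset_ds <- function(idx) labeled_dataset(dataset$items[idx], y[idx])
  list(train = subset_ds(train_idx),
       test = subset_ds(setdiff(seq_along(y), train_idx)),
       train_idx = train_idx)
}

#' Stratified k-fold plan
#'
#' Assigns each item to exactly one test fold, stratified by class, with
#' per-class fold sizes differing by at most one. The leftover items of the
#' two classes are assigned to offset folds, so combined fold sizes also
#' differ by at most one.
#'
#' @param dataset A [labeled_dataset()].
#' @param folds Number of folds (>= 2, at most the smaller class count).
#' @param seed Integer seed.
#' @return List of `folds` elements, each with `train`, `test`, `test_idx`.
#' @export
kfold_plan <- function(dataset, folds, seed = 1L) {
  if (!inherits(dataset, "labeled_dataset")) stop("expected a labeled_dataset", call. = FALSE)
  folds <- as.integer(folds)
  if (folds < 2L) stop("`folds` must be >= 2", call. = FALSE)
  y <- dataset$labels
  counts <- table(factor(y, levels = c(0L, 1L)))
  if (min(counts) < folds) {
    stop("`folds` exceeds the size of the smaller class", call. = FALSE)
  }
  assignment <- integer(length(y))
  with_private_seed(seed, {
    for (cl in c(0L, 1L)) {
      idx <- sample(which(y == cl))
      n <- length(idx)
      base <- n %/% folds
      extra <- n %% folds
      sizes <- rep(base, folds)
      if (extra > 0L) {
        offset <- (cl * (folds %/% 2L)) %% folds
        sizes[((seq_len(extra) - 1L + offset) %% folds) + 1L] <-
          sizes[((seq_len(extra) - 1L + offset) %% folds) + 1L] + 1L
      }
      assignment[idx] <- rep(seq_len(folds), times = sizes)
    }
  })
  subset_ds <- function(idx) labeled_dataset(dataset$items[idx], y[idx])
  lapply(seq_len(folds), function(k) {
    test_idx <- which(assignment == k)
    list(train = subset_ds(which(assignment != k)),
         test = subset_ds(test_idx),
         test_idx = test_idx)
  })
}
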