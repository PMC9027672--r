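#' Autoencoder configuration
#'
#' A single-hidden-layer autoencoder: encoder `h = f(W x + b)` maps the
#' `m`-dimensional input to an `n < m`-dimensional latent vector, decoder
#' `x' = f'(W' h + b')` reconstructs it. Encoder and decoder share the
#' activation choice here.
#'
#' @param input_dim Input dimension `m`.
#' @param latent_dim Latent dimension `n`, `1 <= n < m`; defaults to
#'   `ceiling(m / 4)` (a genuine compression).
#' @param activation `"sigmoid"` (default) or `"relu"`.
#' @return An `ae_config` list.
#' @export
ae_config <- function(input_dim, latent_dim = ceiling(input_dim / 4),
                      activation = c("sigmoid", "relu")) {
  input_dim <- as.integer(input_dim)
  latent_dim <- as.integer(latent_dim)
  activation <- match.arg(activation)
  if (input_dim < 2L) stop("`input_dim` must be >= 2", call. = FALSE)
  if (latent_dim < 1L || latent_dim >= input_dim) {
    stop("`latent_dim` must satisfy 1 <= n < input_dim", call. = FALSE)
  }
  structure(list(input_dim = input_dim, latent_dim = latent_dim,
                 activation = activation),
            class = "ae_config")
}

.activation_fn <- function(name) {
  switch(name,
         sigmoid = function(z) 1 / (1 + exp(-z)),
         relu = function(z) pmax(z, 0),
         stop("unknown activation", call. = FALSE))
}

#' Number of free parameters of one autoencoder
#' @param config An [ae_config()].
#' @return Integer count `n*m + n + m*n + m`.
#' @export
ae_n_params <- function(config) {
  m <- config$input_dim
  n <- config$latent_dim
  n * m + n + m * n + m
}

#' Flatten / unflatten autoencoder parameters
#'
#' Maps between the structured weight set (`W` `n x m`, `b` length `n`,
#' `Wp` `m x n`, `bp` length `m`) and the flat decision vector the optimizer
#' searches over (column-major, in that order). The two functions are exact
#' inverses.
#'
#' @param params List with `W`, `b`, `Wp`, `bp`.
#' @param config An [ae_config()].
#' @return `ae_flatten()` a numeric vector of length [ae_n_params()];
#'   `ae_unflatten()` the structured list.
#' @export
ae_flatten <- function(params) {
  c(as.numeric(params$W), params$b, as.numeric(params$Wp), params$bp)
}

#' @rdname ae_flatten
#' @param x Flat numeric vector of length [ae_n_params()].
#' @export
ae_unflatten <- function(x, config) {
  m <- config$input_dim
  n <- config$latent_dim
  if (length(x) != ae_n_params(config)) {
    stop("flat parameter vector has the wrong length", call. = FALSE)
  }
  i <- 0L
  W <- matrix(x[(i + 1L):(i + n * m)], n, m); i <- i + n * m
  b <- x[(i + 1L):(i + n)]; i <- i + n
  Wp <- matrix(x[(i + 1L):(i + m * n)], m, n); i <- i + m * n
  bp <- x[(i + 1L):(i + m)]
  list(W = W, b = b, Wp = Wp, bp = bp)
}

#' Autoencoder forward pass
#'
#' @param x Input vector of length `input_dim`.
#' @param params Structured parameters (see [ae_unflatten()]).
#' @param config An [ae_config()].
#' @return List with `h` (latent) and `xprime` (reconstruction).
#' @examples
#' cfg <- ae_config(4, 2)
#' p <- ae_unflatten(rep(0, ae_n_params(cfg)), cfg)
#' ae_forward(c(1, 2, 3, 4), p, cfg)$h  # sigmoid(0) = 0.5
#' @export
ae_forward <- function(x, params, config) {
  if (length(x) != config$input_dim) {
    stop("input length does not match `input_dim`", call. = FALSE)
  }
  f <- .activation_fn(config$activation)
  h <- f(drop(params$W %*% x) + params$b)
  xprime <- f(drop(params$Wp %*% h) + params$bp)
  list(h = h, xprime = xprime)
}

# Reconstruction of many samples at once; X is input_dim x n_samples.
.ae_reconstruct <- function(X, params, config) {
  f <- .activation_fn(config$activation)
  H <- f(params$W %*% X + params$b)
  f(params$Wp %*% H + params$bp)
}

#' Squared reconstruction error
#'
#' `||x - x'||^2`, the per-instance reconstruction loss (averaged over
#' instances at the dataset level).
#'
#' @param x,xprime Equal-length numeric vectors.
#' @return Nonnegative scalar.
#' @export
reconstruction_error <- function(x, xprime) {
  if (length(x) != length(xprime)) {
    stop("`x` and `xprime` lengths differ", call. = FALSE)
  }
  sum((x - xprime)^2)
}

# Min-max scaling fitted on training rows only.
.fit_scaling <- function(X) {
  lo <- apply(X, 2L, min)
  hi <- apply(X, 2L, max)
  rng <- hi - lo
  rng[rng == 0] <- 1  # constant feature: maps to 0
  list(min = lo, range = rng)
}

.apply_scaling <- function(X, scaling) {
  sweep(sweep(X, 2L, scaling$min, "-"), 2L, scaling$range, "/")
}

# Per-class reconstruction errors for scaled samples (rows of Xs);
# returns an n_samples x n_classes matrix.
.class_errors <- function(model, Xs) {
  Xt <- t(Xs)
  err <- vapply(model$class_params, function(p) {
    colSums((Xt - .ae_reconstruct(Xt, p, model$config))^2)
  }, numeric(nrow(Xs)))
  matrix(err, nrow = nrow(Xs))
}

#' Classify feature vectors with a per-class autoencoder model
#'
#' Each class owns one autoencoder trained (tuned) to reconstruct that
#' class's feature vectors; a sample is assigned the class whose autoencoder
#' reconstructs it with the smaller squared error. Ties go to label 0.
#'
#' @param x A numeric feature vector, or a matrix with one row per sample.
#' @param model An `ae_classifier_model` from [train_mlo()].
#' @return Integer label(s) in `{0, 1}`.
#' @export
classify <- function(x, model) {
  if (!inherits(model, "ae_classifier_model")) {
    stop("`model` must come from train_mlo()", call. = FALSE)
  }
  X <- if (is.matrix(x)) x else matrix(x, 1L)
  if (ncol(X) != model$config$input_dim) {
    stop("feature dimension does not match the model", call. = FALSE)
  }
  err <- .class_errors(model, .apply_scaling(X, model$scaling))
  as.integer(err[, 2L] < err[, 1L])  # tie -> 0
}

#' Classification error rate (percent)
#'
#' `100 * misclassified / total` — the fitness the parameter tuner minimises.
#'
#' @param predictions,labels Equal-length label vectors.
#' @return Percentage in `[0, 100]`.
#' @export
fitness_error_rate <- function(predictions, labels) {
  if (length(predictions) == 0L || length(predictions) != length(labels)) {
    stop("`predictions` and `labels` must be non-empty and equal length",
         call. = FALSE)
  }
  100 * mean(predictions != labels)
}

#' Tune per-class autoencoders with the multileader optimizer
#'
#' The decision vector concatenates the flattened parameters of the label-0
#' and label-1 autoencoders; the multileader optimizer searches the box
#' `[-search_box, search_box]` per coordinate, minimising the training
#' classification error rate plus a small (`mse_weight`) mean
#' true-class reconstruction error that breaks plateaus of the discrete
#' error-rate objective. Features are min-max scaled to `[0, 1]` using the
#' training rows only; the scaling is stored and reapplied at prediction
#' time.
#'
#' @param train A [labeled_dataset()] of feature vectors with both classes
#'   present.
#' @param config An [ae_config()]; defaults to the feature dimension with
#'   `ceiling(m / 4)` latent units.
#' @param mlo An [mlo_params()].
#' @param search_box Half-width of the weight/bias search box (default 3;
#'   sigmoid pre-activations saturate beyond that).
#' @param mse_weight Weight of the secondary reconstruction term (default 1e-3).
#' @return An `ae_classifier_model`: `config`, `scaling`, `class_params`
#'   (list of two structured parameter sets), `train_fitness`, `trace`.
#' @export
train_mlo <- function(train, config = NULL,
                      mlo = mlo_params(population_size = 30L,
                                       max_iterations = 150L),
                      search_box = 3, mse_weight = 1e-3) {
  if (!inherits(train, "labeled_dataset")) stop("`train` must be a labeled_dataset", call. = FALSE)
  y <- dataset_labels(train)
  if (length(unique(y)) < 2L) {
    stop("training data must contain both classes", call. = FALSE)
  }
  X <- dataset_features(train)
  if (is.null(config)) config <- ae_config(ncol(X))
  if (config$input_dim != ncol(X)) {
    stop("`config$input_dim` does not match the feature dimension", call. = FALSE)
  }
  scaling <- .fit_scaling(X)
  Xs <- .apply_scaling(X, scaling)
  Xt <- t(Xs)                       # input_dim x n_samples
  np <- ae_n_params(config)
  idx0 <- seq_len(np)
  idx1 <- np + idx0

  evaluate <- function(v) {
    p0 <- ae_unflatten(v[idx0], config)
    p1 <- ae_unflatten(v[idx1], config)
    e0 <- colSums((Xt - .ae_reconstruct(Xt, p0, config))^2)
    e1 <- colSums((Xt - .ae_reconstruct(Xt, p1, config))^2)
    pred <- as.integer(e1 < e0)
    err <- 100 * mean(pred != y)
    true_mse <- mean(ifelse(y == 1L, e1, e0))
    err + mse_weight * true_mse
  }
  obj <- objective_spec(evaluate, lower = -search_box, upper = search_box,
                        dimension = 2L * np)
  res <- mlo_optimize(obj, mlo)

  model <- structure(
    list(config = config, scaling = scaling,
         class_params = list(ae_unflatten(res$best[idx0], config),
                             ae_unflatten(res$best[idx1], config)),
         train_fitness = res$fitness, trace = res$trace),
    class = "ae_classifier_model")
  model$train_error_rate <- fitness_error_rate(classify(X, model), y)
  model
}

#' @export
print.ae_classifier_model <- function(x, ...) {
  cat(sprintf("<ae_classifier_model: m = %d, n = %d, %s; training error %.2f%%>\n",
              x$config$input_dim, x$config$latent_dim, x$config$activation,
              x$train_error_rate))
  invisible(x)
}

#' @export
predict.ae_classifier_model <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "labeled_dataset")) dataset_features(newdata) else newdata
  classify(X, object)
}

#' Serialize / restore a classifier model as JSON
#'
#' @param model An `ae_classifier_model`.
#' @param path JSON path.
#' @return `save_model_json()` returns `path` invisibly; `load_model_json()`
#'   the restored model.
#' @export
save_model_json <- function(model, path) {
  if (!inherits(model, "ae_classifier_model")) stop("expected an ae_classifier_model", call. = FALSE)
  payload <- list(
    config = model$config[c("input_dim", "latent_dim", "activation")],
    scaling = model$scaling,
    params = lapply(model$class_params, ae_flatten),
    train_fitness = model$train_fitness,
    train_error_rate = model$train_error_rate
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model_json
#' @export
load_model_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  config <- ae_config(p$config$input_dim, p$config$latent_dim,
                      p$config$activation)
  flat <- if (is.matrix(p$params)) {
    lapply(seq_len(nrow(p$params)), function(i) as.numeric(p$params[i, ]))
  } else {
    lapply(p$params, as.numeric)
  }
  structure(
    list(config = config,
         scaling = list(min = as.numeric(p$scaling$min),
                        range = as.numeric(p$scaling$range)),
         class_params = lapply(flat, ae_unflatten, config = config),
         train_fitness = p$train_fitness,
         train_error_rate = p$train_error_rate),
    class = "ae_classifier_model")
}
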