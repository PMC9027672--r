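#' Bounded continuous objective specification
#'
#' The shared contract both population optimizers work against: a fitness
#' function to MINIMISE over an axis-aligned box.
#'
#' @param evaluate Function mapping a numeric vector of length `dimension`
#'   to a finite scalar fitness (minimisation convention).
#' @param lower,upper Numeric vectors (or scalars, recycled) of per-dimension
#'   bounds, `lower < upper`.
#' @param dimension Problem dimension.
#' @return An `objective_spec` list.
#' @export
objective_spec <- function(evaluate, lower, upper, dimension) {
  dimension <- as.integer(dimension)
  if (dimension < 1L) stop("`dimension` must be >= 1", call. = FALSE)
  lower <- rep_len(as.numeric(lower), dimension)
  upper <- rep_len(as.numeric(upper), dimension)
  if (any(!is.finite(lower)) || any(!is.finite(upper)) || any(lower >= upper)) {
    stop("bounds must be finite with lower < upper per dimension",
         call. = FALSE)
  }
  if (!is.function(evaluate)) stop("`evaluate` must be a function", call. = FALSE)
  structure(list(evaluate = evaluate, lower = lower, upper = upper,
                 dimension = dimension),
            class = "objective_spec")
}

assert_objective <- function(obj) {
  if (!inherits(obj, "objective_spec")) {
    stop("expected an objective_spec (see objective_spec())", call. = FALSE)
  }
  invisible(obj)
}

.check_fitness <- function(f, x) {
  if (length(f) != 1L || is.na(f) || !is.finite(f)) {
    stop(sprintf("objective returned a non-finite fitness at (%s)",
                 paste(signif(x, 4), collapse = ", ")), call. = FALSE)
  }
  f
}

#' Benchmark objectives with known minima
#'
#' Standard test functions used to exercise the optimizers: the sphere
#' `sum(x^2)`, the Rastrigin function, and a shifted quadratic
#' `sum((x - s)^2)`. All have known global minimum value 0.
#'
#' @param dimension Problem dimension (default 5).
#' @param shift Shift vector for the shifted quadratic (recycled; default 1.5).
#' @return Named list of `objective_spec` objects: `sphere`, `rastrigin`,
#'   `shifted_quadratic`.
#' @export
benchmark_objectives <- function(dimension = 5L, shift = 1.5) {
  s <- rep_len(shift, dimension)
  list(
    sphere = objective_spec(function(x) sum(x^2),
                            lower = -5, upper = 5, dimension = dimension),
    rastrigin = objective_spec(
      function(x) 10 * length(x) + sum(x^2 - 10 * cos(2 * pi * x)),
      lower = -5.12, upper = 5.12, dimension = dimension),
    shifted_quadratic = objective_spec(function(x) sum((x - s)^2),
                                       lower = -5, upper = 5,
                                       dimension = dimension)
  )
}

#' Multilevel-Otsu threshold search as a minimisation objective
#'
#' Wraps a histogram and threshold count `K` into the optimizer contract:
#' candidates are `K` reals in `[1, L - 1]`, decoded by
#' [decode_thresholds()], and the fitness is the NEGATED between-class
#' variance (the optimizers minimise; the Otsu criterion is maximised).
#' Cumulative histogram sums are precomputed so each evaluation is O(K).
#'
#' @param hist A `gl_histogram`.
#' @param K Number of thresholds.
#' @return An `objective_spec` with an extra `decode` element mapping a
#'   candidate vector to a [threshold_set()].
#' @export
mlt_objective <- function(hist, K) {
  assert_histogram(hist)
  K <- as.integer(K)
  if (K < 1L || K > hist$L - 1L) stop("invalid `K` for this histogram", call. = FALSE)
  L <- hist$L
  cum_p <- c(0, cumsum(hist$probs))
  lv <- seq_len(L) - 1L
  cum_vp <- c(0, cumsum(lv * hist$probs))
  mu <- cum_vp[L + 1L]
  obj <- objective_spec(
    evaluate = function(x) {
      ts <- decode_thresholds(x, L)
      -.f_direct(as.integer(ts), cum_p, cum_vp, L, mu)
    },
    lower = 1, upper = L - 1, dimension = K)
  obj$decode <- function(x) decode_thresholds(x, L)
  obj
}
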