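#' Emperor penguin optimizer parameters
#'
#' Controls for [epo_optimize()]. `M` is the huddle movement parameter (fixed
#' at 2 in the original formulation); `f` and `l` shape the social-force
#' function `S(x) = (f * exp(-x / l) - exp(-x))^2`; `theta_cap` bounds the
#' temperature profile, which otherwise diverges as the iteration counter
#' approaches `max_iterations`.
#'
#' @param population_size Number of penguins (>= 2).
#' @param max_iterations Iteration budget (>= 1).
#' @param M Movement parameter (default 2).
#' @param f,l Social-force shape parameters (defaults 2 and 1.5).
#' @param theta_cap Upper cap on the temperature profile (default 50).
#' @param seed Integer seed; every random draw in the run derives from it.
#' @return An `epo_params` list.
#' @export
epo_params <- function(population_size = 30L, max_iterations = 500L,
                       M = 2, f = 2, l = 1.5, theta_cap = 50, seed = 1L) {
  population_size <- as.integer(population_size)
  max_iterations <- as.integer(max_iterations)
  if (population_size < 2L) stop("`population_size` must be >= 2", call. = FALSE)
  if (max_iterations < 1L) stop("`max_iterations` must be >= 1", call. = FALSE)
  if (f <= 1) stop("`f` must exceed 1", call. = FALSE)
  if (l <= 0 || theta_cap <= 0) stop("`l` and `theta_cap` must be positive", call. = FALSE)
  structure(list(population_size = population_size,
                 max_iterations = max_iterations,
                 M = M, f = f, l = l, theta_cap = theta_cap,
                 seed = as.integer(seed)),
            class = "epo_params")
}

# Run `expr` under a private RNG stream seeded by `seed`, restoring the
# caller's RNG state afterwards.
with_private_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Emperor penguin optimizer
#'
#' Population metaheuristic modelled on penguin-huddling behaviour,
#' minimising `obj$evaluate` over the bounding box. Each iteration `C` draws
#' one uniform `R` and sets the huddle indicator `theta` (0 when `R > 0.5`,
#' else 1); the temperature profile is `theta - Itermax / (C - Itermax)`,
#' capped at `theta_cap`. Every penguin then moves relative to the
#' best-so-far position `X*`:
#' `U = M * (theta' + |X* - X|) * Rand() - theta'` (per-dimension draws; the
#' grouping follows the original emperor-penguin formulation, so `U` crosses
#' zero and steps can be arbitrarily small),
#' `D = |S(|U|) * X* - Rand() * X|`, and `X <- X* - U * D`, clamped to the
#' box. Draws occur in a fixed member-major, dimension-minor order so runs
#' are bit-reproducible for a given seed.
#'
#' @param obj An [objective_spec()].
#' @param params An [epo_params()].
#' @return List with `best` (position), `fitness`, and `trace`
#'   (data frame: iteration, best_fitness, mean_fitness).
#' @examples
#' obj <- benchmark_objectives(2)$sphere
#' res <- epo_optimize(obj, epo_params(10, 50, seed = 1))
#' res$fitness
#' @export
epo_optimize <- function(obj, params = epo_params()) {
  assert_objective(obj)
  if (!inherits(params, "epo_params")) stop("`params` must be epo_params()", call. = FALSE)
  N <- params$population_size
  m <- obj$dimension
  itermax <- params$max_iterations

  with_private_seed(params$seed, {
    X <- matrix(runif(N * m, rep(obj$lower, each = N), rep(obj$upper, each = N)),
                N, m)
    fit <- apply(X, 1L, function(x) .check_fitness(obj$evaluate(x), x))
    b <- which.min(fit)
    best_x <- X[b, ]
    best_f <- fit[b]

    trace <- data.frame(iteration = 0:itermax,
                        best_fitness = NA_real_, mean_fitness = NA_real_)
    trace$best_fitness[1L] <- best_f
    trace$mean_fitness[1L] <- mean(fit)

    for (C in seq_len(itermax)) {
      R <- runif(1)
      theta <- if (R > 0.5) 0 else 1
      thp <- theta - itermax / (C - itermax)
      if (!is.finite(thp) || thp > params$theta_cap) thp <- params$theta_cap

      ref <- best_x  # frozen for the whole iteration
      for (i in seq_len(N)) {
        xi <- X[i, ]
        grid <- abs(ref - xi)
        U <- params$M * (thp + grid) * runif(m) - thp
        V <- runif(m)
        S <- (params$f * exp(-abs(U) / params$l) - exp(-abs(U)))^2
        D <- abs(S * ref - V * xi)
        xn <- pmin(pmax(ref - U * D, obj$lower), obj$upper)
        X[i, ] <- xn
        fit[i] <- .check_fitness(obj$evaluate(xn), xn)
        if (fit[i] < best_f) {
          best_f <- fit[i]
          best_x <- xn
        }
      }
      trace$best_fitness[C + 1L] <- best_f
      trace$mean_fitness[C + 1L] <- mean(fit)
    }
    list(best = best_x, fitness = best_f, trace = trace)
  })
}

#' Multilevel Otsu thresholding via the emperor penguin optimizer
#'
#' Convenience wrapper: builds the negated between-class-variance objective
#' ([mlt_objective()]) and searches it with [epo_optimize()].
#'
#' @param hist A `gl_histogram`.
#' @param K Number of thresholds.
#' @param params An [epo_params()]; the histogram objective is cheap, so the
#'   default budget is generous.
#' @return List with `thresholds` (a [threshold_set()]), `score`
#'   (an `otsu_score` for the decoded thresholds) and `trace`.
#' @export
epo_mlt <- function(hist, K, params = epo_params(max_iterations = 200L)) {
  obj <- mlt_objective(hist, K)
  res <- epo_optimize(obj, params)
  ts <- obj$decode(res$best)
  list(thresholds = ts, score = otsu_objective(hist, ts), trace = res$trace)
}
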