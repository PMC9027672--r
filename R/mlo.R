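#' Multileader optimizer parameters
#'
#' @param population_size Number of members `N` (>= 2).
#' @param n_leaders Number of leaders `nL`, `1 <= nL <= N` (default 3).
#' @param max_iterations Iteration budget `T` (>= 1).
#' @param seed Integer seed; every random draw in the run derives from it.
#' @return An `mlo_params` list.
#' @export
mlo_params <- function(population_size = 30L, n_leaders = 3L,
                       max_iterations = 200L, seed = 1L) {
  population_size <- as.integer(population_size)
  n_leaders <- as.integer(n_leaders)
  max_iterations <- as.integer(max_iterations)
  if (population_size < 2L) stop("`population_size` must be >= 2", call. = FALSE)
  if (n_leaders < 1L || n_leaders > population_size) {
    stop("`n_leaders` must lie in [1, population_size]", call. = FALSE)
  }
  if (max_iterations < 1L) stop("`max_iterations` must be >= 1", call. = FALSE)
  structure(list(population_size = population_size, n_leaders = n_leaders,
                 max_iterations = max_iterations, seed = as.integer(seed)),
            class = "mlo_params")
}

#' Normalised fitness of a population (minimisation)
#'
#' `fitn_i = (fit_i - max(fit)) / sum_j (fit_j - max(fit))`: nonnegative,
#' summing to 1, and largest for the best (smallest-fitness) member. When all
#' fitnesses are equal the ratio is 0/0; the limit convention of a uniform
#' vector is returned.
#'
#' @param fitnesses Numeric vector of raw fitness values.
#' @return Numeric vector of the same length summing to 1.
#' @examples
#' normalized_fitness(c(1, 2, 3))  # 2/3, 1/3, 0
#' @export
normalized_fitness <- function(fitnesses) {
  if (length(fitnesses) < 1L || anyNA(fitnesses)) {
    stop("`fitnesses` must be non-empty and free of NA", call. = FALSE)
  }
  d <- fitnesses - max(fitnesses)
  s <- sum(d)
  if (s == 0) return(rep(1 / length(fitnesses), length(fitnesses)))
  d / s
}

#' Leader selection probabilities and cumulative bands
#'
#' Restricts the normalised fitness to the `nL` leaders (the best-ranked
#' members, assumed first in `norm_fit` when it comes from a sorted
#' population) and renormalises: `P_l = fitn_l / sum_{j<=nL} fitn_j`, with
#' cumulative sums `C_l` defining the roulette bands. If the leaders' shares
#' are all zero (degenerate population) the probabilities fall back to
#' uniform.
#'
#' @param norm_fit Normalised fitness of the sorted population
#'   ([normalized_fitness()] of ascending-sorted fitnesses).
#' @param n_leaders Number of leaders.
#' @return List with `P` (probabilities, length `n_leaders`) and
#'   `C` (cumulative probabilities; last entry 1).
#' @examples
#' leader_probabilities(normalized_fitness(c(1, 2, 3)), 2)
#' @export
leader_probabilities <- function(norm_fit, n_leaders) {
  n_leaders <- as.integer(n_leaders)
  if (n_leaders < 1L || n_leaders > length(norm_fit)) {
    stop("`n_leaders` out of range", call. = FALSE)
  }
  w <- norm_fit[seq_len(n_leaders)]
  s <- sum(w)
  P <- if (s > 0) w / s else rep(1 / n_leaders, n_leaders)
  list(P = P, C = cumsum(P))
}

#' Roulette-wheel leader selection
#'
#' Returns the smallest index `l` with `r <= C_l`, i.e. the band of the
#' cumulative probability vector that `r` falls into.
#'
#' @param cumulative Non-decreasing cumulative probabilities ending at 1
#'   (within 1e-9).
#' @param r A draw in `[0, 1]`.
#' @return Integer leader index.
#' @examples
#' roulette_select(c(2 / 3, 1), 0.9)  # 2
#' @export
roulette_select <- function(cumulative, r) {
  if (length(cumulative) < 1L || anyNA(cumulative) ||
      any(diff(cumulative) < 0) ||
      abs(cumulative[length(cumulative)] - 1) > 1e-9) {
    stop("`cumulative` must be non-decreasing and end at 1", call. = FALSE)
  }
  if (length(r) != 1L || is.na(r) || r < 0 || r > 1) {
    stop("`r` must be a single value in [0, 1]", call. = FALSE)
  }
  match(TRUE, r <= cumulative)
}

# Vectorised roulette for one member's per-dimension draws.
.roulette_vec <- function(cumulative, r) {
  rowSums(outer(r, cumulative, ">")) + 1L
}

#' Multileader optimizer
#'
#' Population metaheuristic minimising `obj$evaluate` over the bounding box.
#' Each iteration sorts the population by fitness; the best `nL` members act
#' as leaders. Every member then makes two greedy moves: (1) a leader-guided
#' move where, per dimension, a leader is picked by roulette wheel over the
#' normalised-fitness probabilities and the coordinate is updated as
#' `x_d <- x_d + rand * (leader_d - 2 * x_d)`, accepted only if the full
#' proposal does not worsen the fitness; (2) a shrinking local move
#' `x_d <- x_d + 2 * (1 - t/T) * (-0.2 + 0.4 * rand) * x_d`, also greedily
#' accepted. Positions are clamped to the box after every proposal. Draws
#' occur in a fixed member-major, dimension-minor order (roulette draws,
#' then step draws, then local-move draws) so runs are bit-reproducible.
#'
#' Note the local move scales the coordinate itself, so a coordinate exactly
#' at 0 is never perturbed in that phase; initial positions are drawn
#' uniformly over the box, making exact zeros a measure-zero event.
#'
#' @param obj An [objective_spec()].
#' @param params An [mlo_params()].
#' @return List with `best` (position), `fitness`, and `trace`
#'   (data frame: iteration, best_fitness, mean_fitness).
#' @examples
#' obj <- benchmark_objectives(2)$sphere
#' res <- mlo_optimize(obj, mlo_params(10, 3, 50, seed = 1))
#' res$fitness
#' @export
mlo_optimize <- function(obj, params = mlo_params()) {
  assert_objective(obj)
  if (!inherits(params, "mlo_params")) stop("`params` must be mlo_params()", call. = FALSE)
  N <- params$population_size
  nL <- params$n_leaders
  Tmax <- params$max_iterations
  m <- obj$dimension

  with_private_seed(params$seed, {
    X <- matrix(runif(N * m, rep(obj$lower, each = N), rep(obj$upper, each = N)),
                N, m)
    fit <- apply(X, 1L, function(x) .check_fitness(obj$evaluate(x), x))
    b <- which.min(fit)
    best_x <- X[b, ]
    best_f <- fit[b]

    trace <- data.frame(iteration = 0:Tmax,
                        best_fitness = NA_real_, mean_fitness = NA_real_)
    trace$best_fitness[1L] <- best_f
    trace$mean_fitness[1L] <- mean(fit)

    for (t in seq_len(Tmax)) {
      ord <- order(fit)
      leaders <- X[ord[seq_len(nL)], , drop = FALSE]
      fitn <- normalized_fitness(fit[ord])
      bands <- leader_probabilities(fitn, nL)$C
      shrink <- 2 * (1 - t / Tmax)

      for (i in seq_len(N)) {
        xi <- X[i, ]
        # leader-guided move
        r <- runif(m)
        idx <- .roulette_vec(bands, r)
        lam <- leaders[cbind(idx, seq_len(m))]
        step <- runif(m)
        xn <- pmin(pmax(xi + step * (lam - 2 * xi), obj$lower), obj$upper)
        fn <- .check_fitness(obj$evaluate(xn), xn)
        if (fn <= fit[i]) {
          X[i, ] <- xn
          fit[i] <- fn
          xi <- xn
        }
        # shrinking local move
        loc <- runif(m)
        xn <- pmin(pmax(xi + shrink * (-0.2 + 0.4 * loc) * xi,
                        obj$lower), obj$upper)
        fn <- .check_fitness(obj$evaluate(xn), xn)
        if (fn <= fit[i]) {
          X[i, ] <- xn
          fit[i] <- fn
        }
        if (fit[i] < best_f) {
          best_f <- fit[i]
          best_x <- X[i, ]
        }
      }
      trace$best_fitness[t + 1L] <- best_f
      trace$mean_fitness[t + 1L] <- mean(fit)
    }
    list(best = best_x, fitness = best_f, trace = trace)
  })
}
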