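#' Gray-level histogram of an image
#'
#' Counts pixels per gray level `u = 0 ... L - 1` and derives level
#' probabilities `P_u = h_u / N_p`, the quantities the multilevel Otsu
#' criterion is computed from.
#'
#' @param image A [gray_image()].
#' @return A `gl_histogram`: list with `counts` (length `L`), `probs`,
#'   `n_pixels`, `L`.
#' @examples
#' img <- gray_image(matrix(c(0, 1, 1, 3), 8, 8), L = 4)
#' compute_histogram(img)$counts
#' @export
compute_histogram <- function(image) {
  assert_gray_image(image)
  L <- gray_levels(image)
  counts <- tabulate(as.integer(image) + 1L, nbins = L)
  n <- length(image)
  structure(list(counts = counts, probs = counts / n,
                 n_pixels = n, L = L),
            class = "gl_histogram")
}

#' Construct a histogram from raw level counts
#'
#' @param counts Nonnegative integer vector of per-level counts; its length
#'   is the level count `L`.
#' @return A `gl_histogram` as in [compute_histogram()].
#' @export
histogram_from_counts <- function(counts) {
  if (length(counts) < 2L || any(counts < 0) || anyNA(counts)) {
    stop("`counts` must be a nonnegative vector of length >= 2", call. = FALSE)
  }
  n <- sum(counts)
  if (n <= 0) stop("histogram has no mass", call. = FALSE)
  structure(list(counts = counts, probs = counts / n,
                 n_pixels = n, L = length(counts)),
            class = "gl_histogram")
}

assert_histogram <- function(hist) {
  if (!inherits(hist, "gl_histogram")) {
    stop("expected a gl_histogram (see compute_histogram())", call. = FALSE)
  }
  invisible(hist)
}

#' Threshold set for multilevel segmentation
#'
#' `K` strictly increasing integer thresholds `t_1 < ... < t_K`, each in
#' `[1, L - 1]`, partition the level range into `K + 1` classes: class `u`
#' covers levels `t_u ... t_{u+1} - 1` with the conventions `t_0 = 0` and
#' `t_{K+1} = L`.
#'
#' @param thresholds Integer vector of thresholds.
#' @param L Gray-level count the thresholds refer to.
#' @return An integer vector of class `threshold_set` with attribute `L`.
#' @export
threshold_set <- function(thresholds, L = 256L) {
  L <- as.integer(L)
  t <- as.numeric(thresholds)
  if (length(t) < 1L || anyNA(t)) stop("need at least one threshold", call. = FALSE)
  if (any(t != round(t))) stop("thresholds must be integers", call. = FALSE)
  t <- as.integer(t)
  if (any(diff(t) <= 0L)) {
    stop("thresholds must be strictly increasing", call. = FALSE)
  }
  if (t[1L] < 1L || t[length(t)] > L - 1L) {
    stop("thresholds must lie in [1, L-1]", call. = FALSE)
  }
  structure(t, L = L, class = "threshold_set")
}

assert_threshold_set <- function(ts, L) {
  if (!inherits(ts, "threshold_set")) ts <- threshold_set(ts, L)
  if (attr(ts, "L") != L) {
    stop(sprintf("threshold set was built for L = %d, histogram has L = %d",
                 attr(ts, "L"), L), call. = FALSE)
  }
  ts
}

#' Between-class variance (multilevel Otsu criterion)
#'
#' Scores a threshold set on a histogram by the between-class variance
#' `F = sum_u A_u * (eta_u - mu)^2`, where `A_u` is the probability mass of
#' class `u`, `eta_u` its mean level, and `mu` the global mean level of the
#' image. Maximising `F` over threshold sets is the multilevel Otsu
#' segmentation problem. Empty classes (`A_u = 0`) contribute zero, so the
#' objective stays defined for degenerate candidates proposed mid-search.
#'
#' @param hist A `gl_histogram`.
#' @param ts A [threshold_set()] (or integer vector) valid for `hist$L`.
#' @return List of class `otsu_score`: `F`, `class_probs` (`A_u`),
#'   `class_means` (`eta_u`, `NA` for empty classes), `global_mean`.
#' @examples
#' h <- histogram_from_counts(c(1, 1, 1, 1))
#' otsu_objective(h, threshold_set(2, L = 4))$F  # 1.0
#' @export
otsu_objective <- function(hist, ts) {
  assert_histogram(hist)
  ts <- assert_threshold_set(ts, hist$L)
  bounds <- c(0L, as.integer(ts), hist$L)      # t_0 = 0, t_{K+1} = L
  cum_p <- c(0, cumsum(hist$probs))
  lv <- seq_len(hist$L) - 1L
  cum_vp <- c(0, cumsum(lv * hist$probs))
  mu <- cum_vp[hist$L + 1L]

  lo <- bounds[-length(bounds)]
  hi <- bounds[-1L]
  A <- cum_p[hi + 1L] - cum_p[lo + 1L]
  m1 <- cum_vp[hi + 1L] - cum_vp[lo + 1L]
  eta <- ifelse(A > 0, m1 / A, NA_real_)
  contrib <- ifelse(A > 0, A * (eta - mu)^2, 0)
  structure(list(F = sum(contrib), class_probs = A, class_means = eta,
                 global_mean = mu),
            class = "otsu_score")
}

#' Total gray-level variance of a histogram
#'
#' `sum_v P_v * (v - mu)^2`. For any threshold set, the between-class
#' variance plus the probability-weighted within-class variances equals this
#' quantity, which bounds the Otsu criterion from above.
#'
#' @param hist A `gl_histogram`.
#' @return Scalar variance in squared intensity units.
#' @export
total_variance <- function(hist) {
  assert_histogram(hist)
  if (hist$n_pixels <= 0) stop("histogram has no mass", call. = FALSE)
  lv <- seq_len(hist$L) - 1L
  mu <- sum(lv * hist$probs)
  sum(hist$probs * (lv - mu)^2)
}

# Between-class variance of one K-tuple, from precomputed cumulative sums
# (leading 0). Empty classes contribute 0 so degenerate tuples stay scored.
.f_direct <- function(t, cum_p, cum_vp, L, mu) {
  bounds <- c(0L, t, L)
  lo <- bounds[-length(bounds)] + 1L
  hi <- bounds[-1L] + 1L
  A <- cum_p[hi] - cum_p[lo]
  m1 <- cum_vp[hi] - cum_vp[lo]
  ok <- A > 0
  if (!any(ok)) return(0)
  eta <- m1[ok] / A[ok]
  sum(A[ok] * (eta - mu)^2)
}

#' Exhaustive multilevel Otsu search
#'
#' Enumerates every strictly increasing `K`-tuple of thresholds in
#' `[1, L - 1]` and returns the maximiser of the between-class variance.
#' Ties are broken by the lexicographically smallest tuple, which makes the
#' result deterministic. Intended as the exact reference at desk scale; the
#' enumeration is refused when `choose(L - 1, K)` exceeds `1e7`, in which
#' case the metaheuristic search ([epo_mlt()]) is the practical route.
#'
#' @param hist A `gl_histogram`.
#' @param K Number of thresholds (>= 1).
#' @return List with `thresholds` (a [threshold_set()]) and `score`
#'   (an `otsu_score`).
#' @export
exhaustive_mlt <- function(hist, K) {
  assert_histogram(hist)
  K <- as.integer(K)
  if (K < 1L) stop("`K` must be >= 1", call. = FALSE)
  occupied <- sum(hist$counts > 0)
  if (K > occupied - 1L) {
    stop("`K` must be at most the number of occupied levels minus 1",
         call. = FALSE)
  }
  n_cand <- hist$L - 1L
  if (choose(n_cand, K) > 1e7) {
    stop("enumeration too large (choose(L-1, K) > 1e7); use EPO search",
         call. = FALSE)
  }
  cum_p <- c(0, cumsum(hist$probs))
  lv <- seq_len(hist$L) - 1L
  cum_vp <- c(0, cumsum(lv * hist$probs))
  mu <- cum_vp[hist$L + 1L]

  best_f <- -Inf
  best_t <- NULL
  if (K == 1L) {
    fs <- vapply(seq_len(n_cand), function(t)
      .f_direct(t, cum_p, cum_vp, hist$L, mu), numeric(1))
    best_t <- which.max(fs)          # which.max returns the first maximum
    best_f <- fs[best_t]
  } else {
    combos <- utils::combn(n_cand, K)  # columns in lexicographic order
    for (j in seq_len(ncol(combos))) {
      f <- .f_direct(combos[, j], cum_p, cum_vp, hist$L, mu)
      if (f > best_f) {
        best_f <- f
        best_t <- combos[, j]
      }
    }
  }
  ts <- threshold_set(best_t, L = hist$L)
  list(thresholds = ts, score = otsu_objective(hist, ts))
}

#' Classical two-class Otsu threshold
#'
#' Textbook binary Otsu on a histogram: for every candidate threshold `t`
#' compute the class weights `w0, w1` and class means `mu0, mu1` and maximise
#' `w0 * w1 * (mu0 - mu1)^2`. Kept as an independent reference for the
#' `K = 1` case of the multilevel criterion; it shares no code with
#' [otsu_objective()] or [exhaustive_mlt()].
#'
#' @param hist A `gl_histogram`.
#' @return List with `threshold` (class 0 is `[0, t - 1]`) and `sigma_b2`
#'   (the maximised between-class variance).
#' @export
otsu_binary <- function(hist) {
  assert_histogram(hist)
  p <- hist$probs
  L <- hist$L
  lv <- 0:(L - 1L)
  best_t <- NA_integer_
  best_s <- -Inf
  for (t in 1:(L - 1L)) {
    w0 <- sum(p[1:t])
    w1 <- 1 - w0
    if (w0 <= 0 || w1 <= 0) {
      s <- 0
    } else {
      mu0 <- sum(lv[1:t] * p[1:t]) / w0
      mu1 <- sum(lv[(t + 1L):L] * p[(t + 1L):L]) / w1
      s <- w0 * w1 * (mu0 - mu1)^2
    }
    if (s > best_s) {
      best_s <- s
      best_t <- t
    }
  }
  list(threshold = best_t, sigma_b2 = best_s)
}

#' Apply thresholds to an image, producing a class label map
#'
#' A pixel of gray level `g` is assigned class `k` when
#' `t_k <= g <= t_{k+1} - 1` (with `t_0 = 0`, `t_{K+1} = L`), so the label
#' map takes values in `0 ... K`.
#'
#' @param image A [gray_image()].
#' @param ts A [threshold_set()] valid for the image's level count.
#' @return Integer matrix of class labels, same shape as `image`, with
#'   attribute `K` (number of thresholds).
#' @export
apply_thresholds <- function(image, ts) {
  assert_gray_image(image)
  L <- gray_levels(image)
  ts <- assert_threshold_set(ts, L)
  labs <- matrix(findInterval(as.integer(image), c(as.integer(ts))),
                 nrow(image), ncol(image))
  structure(labs, K = length(ts))
}

#' Decode a real-valued optimizer candidate into thresholds
#'
#' Population optimizers search over `K` reals in `[1, L - 1]`. The decoding
#' rule sorts the coordinates, rounds to integers and resolves collisions by
#' pushing duplicates up by one within bounds, yielding a strictly
#' increasing valid threshold set whenever `K <= L - 1`.
#'
#' @param x Numeric vector of length `K` with entries in `[1, L - 1]`.
#' @param L Gray-level count.
#' @return A [threshold_set()].
#' @export
decode_thresholds <- function(x, L) {
  t <- sort(round(x))
  t <- pmin(pmax(t, 1), L - 1)
  for (i in seq_along(t)) {
    if (i > 1L && t[i] <= t[i - 1L]) t[i] <- t[i - 1L] + 1L
  }
  if (t[length(t)] > L - 1L) {
    # ran out of headroom at the top: push the tail down instead
    t[length(t)] <- L - 1L
    for (i in rev(seq_len(length(t) - 1L))) {
      if (t[i] >= t[i + 1L]) t[i] <- t[i + 1L] - 1L
    }
  }
  threshold_set(t, L = L)
}
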