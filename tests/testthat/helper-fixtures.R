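# Random sparse-ish histogram with at least two occupied levels.
random_histogram <- function(L, seed) {
  set.seed(seed)
  repeat {
    counts <- stats::rpois(L, lambda = stats::rexp(L, 1 / 20))
    if (sum(counts > 0) >= 2) return(histogram_from_counts(counts))
  }
}

# Probability-weighted within-class variance, computed directly from the
# definition (independent of otsu_objective's internals).
within_class_variance <- function(hist, ts) {
  bounds <- c(0L, as.integer(ts), hist$L)
  total <- 0
  for (u in seq_len(length(bounds) - 1L)) {
    lv <- bounds[u]:(bounds[u + 1L] - 1L)
    p <- hist$probs[lv + 1L]
    A <- sum(p)
    if (A > 0) {
      eta <- sum(lv * p) / A
      total <- total + sum(p * (lv - eta)^2)
    }
  }
  total
}

# Small noiseless phantom spec for fast image tests.
tiny_spec <- function(has_tumor = TRUE, mode_sds = 0, seed = 1L) {
  phantom_spec(image_size = c(48L, 48L),
               mode_sds = mode_sds,
               organ_ellipse = list(center = c(24, 24), axes = c(16, 11),
                                    angle = 0.4),
               tumor_blob = if (has_tumor) list(center = c(25, 26), radius = 5),
               has_tumor = has_tumor,
               seed = seed)
}

# Jitter ranges proportionate to the 48x48 tiny spec.
tiny_jitter <- list(center = 2, axes = 2, angle = 0.2, radius = 1,
                    intensity = 8)

separable_clusters <- function(n_per_class = 100L, dim = 8L, seed = 11L) {
  generate_feature_clusters(n_per_class, dim,
                            centers = list(rep(0, dim), rep(10, dim)),
                            sd = 1, seed = seed)
}
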