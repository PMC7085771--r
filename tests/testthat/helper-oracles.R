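# Independent oracles: naive reimplementations the fast code is checked
# against. These deliberately use explicit loops and recomputation.

# Eq.-style double loop: sum_ij |a_i - b_j|^p * w_ij, outer 1/p root
naive_dima <- function(a, b, w, p = 1) {
  n <- length(a)
  acc <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      acc <- acc + abs(a[i] - b[j])^p * w[i, j]
    }
  }
  if (p == 1) acc else acc^(1 / p)
}

# leave-one-out balanced error with full centroid recomputation per split
# (sign matrix fixed from the full set, as in the default pipeline path)
naive_loo_error <- function(series, labels, lambda, tie = "sick") {
  G <- unclass(build_sign_matrix(class_centroids(series, labels)))
  w <- (1 - lambda) * G + lambda * diag(ncol(series))
  pred <- character(nrow(series))
  for (i in seq_len(nrow(series))) {
    tr <- series[-i, , drop = FALSE]
    trl <- labels[-i]
    ch <- colMeans(tr[trl == "healthy", , drop = FALSE])
    cs <- colMeans(tr[trl == "sick", , drop = FALSE])
    dh <- naive_dima(series[i, ], ch, w)
    ds <- naive_dima(series[i, ], cs, w)
    pred[i] <- if (ds < dh) "sick" else if (dh < ds) "healthy" else tie
  }
  sens <- mean(pred[labels == "sick"] == "sick")
  spec <- mean(pred[labels == "healthy"] == "healthy")
  1 - (sens + spec) / 2
}

# small labelled series set: two Gaussian classes with a pointwise mean shift
toy_series <- function(n_per_class = 4, len = 6, shift = 2, sd = 1,
                       seed = 1) {
  withr::with_seed(seed, {
    h <- matrix(rnorm(n_per_class * len, 10, sd), n_per_class, len)
    s <- matrix(rnorm(n_per_class * len, 10 + shift, sd), n_per_class, len)
    list(series = rbind(h, s),
         labels = rep(c("healthy", "sick"), each = n_per_class))
  })
}

# tiny cohort for pipeline tests: reduced animals, shorter weeks
tiny_cohort <- function(n = 120, hours = 48, seed = 11, prevalence = 0.25,
                        effects = c(lying = 3, ruminating = -4, inactive = 3,
                                    active = -2.2, highly_active = -0.8),
                        missing = TRUE, animal_sd = 4, noise_sd = 7) {
  spec <- cohort_spec(n_animals = n, prevalence = prevalence,
                      series_length = hours, stream_effects = effects,
                      animal_sd = animal_sd, noise_sd = noise_sd,
                      seed = seed)
  coh <- generate_cohort(spec)
  if (missing) coh <- apply_missingness(coh, seed = seed + 1L)
  coh
}
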