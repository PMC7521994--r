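# Shared fixtures, built once per test run and memoised.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# small random landmark set (not symmetric, generic shapes)
random_landmarks <- function(n = 5, k = 6, seed = 1) {
  set.seed(seed)
  landmark_set(lapply(seq_len(n), function(i) matrix(rnorm(k * 3), k, 3)),
               sprintf("s%02d", seq_len(n)))
}

# mid-sized synthetic cohort used by several test files
small_synth <- function() {
  fixture("small_synth", function() {
    generate_cohort(generator_config(
      n_landmarks = 30, n_midline = 4, n_syndromes = 5, n_per_syndrome = 15,
      n_unaffected = 60, n_families = 10, seed = 42))
  })
}

small_prep <- function() {
  fixture("small_prep", function() prepare_shapes(small_synth()$cohort))
}

# strong-effect cohort with many relatives, for the relatives analyses
relatives_synth <- function() {
  fixture("relatives_synth", function() {
    generate_cohort(generator_config(
      n_landmarks = 30, n_midline = 4, n_syndromes = 8, n_per_syndrome = 25,
      n_unaffected = 150, n_families = 60, severity_scale = 0.06,
      relative_attenuation = 0.5, seed = 5))
  })
}

relatives_prep <- function() {
  fixture("relatives_prep", function() prepare_shapes(relatives_synth()$cohort))
}

# Gaussian class data for classifier oracles
gaussian_classes <- function(n_per, p, delta, g = 2, seed = 1,
                             scale_second = 1) {
  set.seed(seed)
  X <- do.call(rbind, lapply(seq_len(g), function(j) {
    mu <- rep(0, p); mu[1] <- (j - 1) * delta
    sc <- if (j == 2) scale_second else 1
    sweep(matrix(rnorm(n_per * p, sd = sc), n_per, p), 2, mu, "+")
  }))
  rownames(X) <- sprintf("x%03d", seq_len(nrow(X)))
  list(X = X, labels = rep(LETTERS[seq_len(g)], each = n_per))
}
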