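triangle <- function(p3 = c(0, 1, 0)) {
  rbind(c(0, 0, 0), c(1, 0, 0), p3)
}

test_that("GPA is invariant to similarity transforms of the input", {
  set.seed(21)
  base <- matrix(rnorm(18), 6, 3)
  th <- 37 * pi / 180
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  moved <- sweep(2.5 * base %*% R, 2, c(3, -1, 7), "+")
  al <- gpa(landmark_set(list(base, moved), c("a", "b")))
  expect_lt(procrustes_distance(al$shapes[1, ], al$shapes[2, ]), 1e-8)
  expect_lt(max(abs(al$shapes[1, ] - al$shapes[2, ])), 1e-8)

  # identical shapes superimpose exactly
  al2 <- gpa(landmark_set(list(triangle(), triangle()), c("a", "b")))
  expect_equal(procrustes_distance(al2$shapes[1, ], al2$shapes[2, ]), 0,
               tolerance = 1e-12)
})

test_that("aligned shapes are centred with unit centroid size", {
  al <- gpa(random_landmarks(n = 6, k = 5, seed = 9))
  for (i in 1:6) {
    m <- matrix(al$shapes[i, ], ncol = 3, byrow = TRUE)
    expect_lt(max(abs(colMeans(m))), 1e-9)
    expect_equal(sqrt(sum(m^2)), 1, tolerance = 1e-9)
  }
  # consensus = renormalized mean of aligned shapes
  mean_shape <- matrix(colMeans(al$shapes), ncol = 3, byrow = TRUE)
  mean_shape <- mean_shape / sqrt(sum(mean_shape^2))
  expect_equal(al$consensus, mean_shape, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("Procrustes distance matches the rotation-grid oracle", {
  A <- triangle(c(0, 1, 0))
  B <- triangle(c(0, 2, 0))
  oracle <- grid_procrustes_distance(A, B)
  cu <- function(m) {
    m <- sweep(m, 2, colMeans(m)); m / sqrt(sum(m^2))
  }
  expect_equal(procrustes_distance(cu(A), cu(B)), oracle, tolerance = 1e-4)

  # and gpa on the pair agrees with pairwise alignment
  al <- gpa(landmark_set(list(A, B), c("a", "b")))
  expect_equal(procrustes_distance(al$shapes[1, ], al$shapes[2, ]), oracle,
               tolerance = 1e-4)
})

test_that("Procrustes distance is a symmetric metric", {
  set.seed(4)
  cu <- function(m) {
    m <- sweep(m, 2, colMeans(m)); m / sqrt(sum(m^2))
  }
  for (i in 1:10) {
    a <- cu(matrix(rnorm(15), 5, 3))
    b <- cu(matrix(rnorm(15), 5, 3))
    c <- cu(matrix(rnorm(15), 5, 3))
    dab <- procrustes_distance(a, b)
    expect_equal(dab, procrustes_distance(b, a), tolerance = 1e-10)
    expect_lte(dab,
               procrustes_distance(a, c) + procrustes_distance(c, b) + 1e-12)
    expect_equal(procrustes_distance(a, a), 0, tolerance = 1e-12)
  }
  expect_error(procrustes_distance(rnorm(9), rnorm(12)), "length")
})

test_that("GPA consensus is a fixed point and variance identities hold", {
  al <- gpa(random_landmarks(n = 10, k = 6, seed = 31))
  configs2 <- lapply(seq_len(10),
                     function(i) matrix(al$shapes[i, ], ncol = 3, byrow = TRUE))
  al2 <- gpa(landmark_set(configs2, al$subject_id))
  # the superimposition frame is defined up to a common rotation: consensus
  # and every shape must be unchanged as shapes
  expect_lt(procrustes_distance(al2$consensus, al$consensus), 1e-8)
  for (i in seq_len(10)) {
    expect_lt(procrustes_distance(al2$shapes[i, ], al$shapes[i, ]), 1e-7)
  }

  # sum of squared distances to consensus = coordinate covariance trace
  cons <- as.vector(t(al$consensus))
  d2 <- vapply(seq_len(10),
               function(i) procrustes_distance(al$shapes[i, ], cons)^2,
               numeric(1))
  expect_equal(mean(d2), total_shape_variance(al), tolerance = 1e-8)
})

test_that("degenerate configurations are rejected by name", {
  lm <- landmark_set(list(matrix(1, 4, 3), matrix(rnorm(12), 4, 3)),
                     c("flat", "ok"))
  expect_error(gpa(lm), "flat")
})

test_that("outlier screening flags planted gross outliers only", {
  set.seed(12)
  base <- matrix(rnorm(15), 5, 3)
  configs <- lapply(1:10, function(i) base + matrix(rnorm(15, sd = 1e-4), 5, 3))
  configs[[11]] <- base + matrix(rnorm(15, sd = 0.8), 5, 3)
  al <- gpa(landmark_set(configs, sprintf("s%02d", 1:11)))
  rep <- detect_outliers(al, z_cut = 3)
  expect_true(rep$flag[11])
  expect_false(any(rep$flag[1:10]))
  expect_equal(attr(rep, "threshold_used"), 3)

  expect_false(any(detect_outliers(al, z_cut = Inf)$flag))
})

test_that("flag rate under a clean Gaussian cohort is below 2%", {
  set.seed(77)
  base <- matrix(rnorm(18), 6, 3)
  configs <- lapply(1:200, function(i) base + matrix(rnorm(18, sd = 0.05), 6, 3))
  al <- gpa(landmark_set(configs, sprintf("s%03d", 1:200)))
  rep <- detect_outliers(al, z_cut = 3)
  expect_lt(mean(rep$flag), 0.02)
})

test_that("threshold sweep reproduces the unfiltered result at cut = Inf", {
  prep <- small_prep()
  al <- prep$aligned
  tab <- sweep_outlier_threshold(prep$shapes, prep$meta, al, z_cuts = Inf,
                                 scheme = "kfold", k = 5, seed = 3)
  direct <- crossvalidate(prep$shapes, prep$meta, method = "hdrda",
                          params = hdrda_params(), scheme = "kfold", k = 5,
                          seed = 3)
  expect_equal(tab$balanced_accuracy,
               glance(direct)$mean_balanced_accuracy, tolerance = 1e-12)
  expect_error(sweep_outlier_threshold(prep$shapes, prep$meta, al,
                                       z_cuts = numeric()), "non-empty")
})

test_that("with planted outliers some finite cut does at least as well", {
  synth <- generate_cohort(generator_config(
    n_landmarks = 30, n_midline = 4, n_syndromes = 3, n_per_syndrome = 20,
    n_unaffected = 30, n_families = 0, severity_scale = 0.05, seed = 8))
  cohort <- synth$cohort
  # corrupt ~5% of subjects with gross landmark noise
  set.seed(8)
  bad <- sample(length(cohort$landmarks), 5)
  for (i in bad) {
    cohort$landmarks$coords[, , i] <- cohort$landmarks$coords[, , i] +
      matrix(rnorm(30 * 3, sd = 0.3), 30, 3)
  }
  prep <- prepare_shapes(cohort)
  tab <- sweep_outlier_threshold(prep$shapes, prep$meta, prep$aligned,
                                 z_cuts = c(2, 3, Inf),
                                 scheme = "kfold", k = 5, seed = 2)
  finite <- tab$balanced_accuracy[is.finite(tab$z_cut) & tab$valid]
  inf_acc <- tab$balanced_accuracy[!is.finite(tab$z_cut)]
  expect_gte(max(finite), inf_acc)
})
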