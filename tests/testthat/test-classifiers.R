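test_that("naive priors are class proportions", {
  # printed cohort composition: 3003 unaffected, 2736 syndromic subjects
  labels <- rep(c("unaffected", "syndromic"), c(3003, 2736))
  pr <- naive_priors(labels)
  expect_equal(round(100 * pr[["unaffected"]], 1), 52.3)
  expect_equal(sum(pr), 1, tolerance = 1e-12)

  expect_equal(unname(naive_priors(rep("A", 7))), 1)
  expect_equal(unname(naive_priors(rep(letters[1:4], 5))), rep(0.25, 4))
  expect_error(naive_priors(character()), "no labels")
})

test_that("HDRDA at (1, 0) equals pooled-covariance LDA", {
  skip_if_not_installed("MASS")
  d <- gaussian_classes(n_per = 40, p = 5, delta = 3, seed = 2)
  test <- gaussian_classes(n_per = 10, p = 5, delta = 3, seed = 3)$X
  fit <- fit_hdrda(d$X, d$labels,
                   hdrda_params(1, 0, gamma_relative = FALSE))
  post <- predict_posteriors(fit, test)
  lfit <- MASS::lda(d$X, grouping = d$labels)
  lpost <- predict(lfit, test)$posterior
  expect_equal(unname(post), unname(lpost[, colnames(post)]),
               tolerance = 1e-8)
})

test_that("HDRDA at (0, 0) equals QDA", {
  skip_if_not_installed("MASS")
  d <- gaussian_classes(n_per = 200, p = 3, delta = 2, seed = 4,
                        scale_second = 2)
  test <- gaussian_classes(n_per = 15, p = 3, delta = 2, seed = 5,
                           scale_second = 2)$X
  fit <- fit_hdrda(d$X, d$labels,
                   hdrda_params(0, 0, gamma_relative = FALSE))
  post <- predict_posteriors(fit, test)
  qfit <- MASS::qda(d$X, grouping = d$labels)
  qpost <- predict(qfit, test)$posterior
  expect_equal(unname(post), unname(qpost[, colnames(post)]),
               tolerance = 1e-8)
})

test_that("huge gamma reduces to nearest-centroid classification", {
  d <- gaussian_classes(n_per = 30, p = 4, delta = 1, g = 3, seed = 6)
  test <- gaussian_classes(n_per = 20, p = 4, delta = 1, g = 3, seed = 7)$X
  # lambda = 1 so the O(1/gamma) log-determinant term is class-constant
  fit <- fit_hdrda(d$X, d$labels,
                   hdrda_params(1, 1e6, gamma_relative = FALSE))
  pred <- as.character(predict(fit, test))
  mus <- rowsum(d$X, d$labels) / 30
  centroid_pred <- rownames(mus)[apply(test, 1, function(x) {
    which.min(colSums((t(mus) - x)^2))
  })]
  expect_equal(pred, centroid_pred)
})

test_that("reduced-subspace HDRDA equals the dense full-space computation", {
  # p = 195 features, n = 60 subjects: exact p >> n case
  set.seed(8)
  p <- 195
  X <- do.call(rbind, lapply(1:3, function(j) {
    mu <- rnorm(p, sd = 0.2)
    sweep(matrix(rnorm(20 * p, sd = 0.5), 20, p), 2, mu, "+")
  }))
  labels <- rep(c("A", "B", "C"), each = 20)
  test <- X[c(1, 25, 50), , drop = FALSE] +
    matrix(rnorm(3 * p, sd = 0.5), 3, p)
  for (lambda in c(0, 0.5, 1)) {
    gamma <- 0.05
    fit <- fit_hdrda(X, labels,
                     hdrda_params(lambda, gamma, gamma_relative = FALSE))
    post <- predict_posteriors(fit, test)
    dense <- dense_hdrda_posteriors(X, labels, lambda, gamma, test)
    expect_equal(unname(post), unname(dense[, colnames(post)]),
                 tolerance = 1e-6)
  }
  # gamma = 0 is impossible when the span is rank-deficient
  expect_error(fit_hdrda(X, labels, hdrda_params(0.5, 0,
                                                 gamma_relative = FALSE)),
               "gamma")
})

test_that("posteriors behave at class means and under duplicated classes", {
  d <- gaussian_classes(n_per = 50, p = 4, delta = 8, seed = 9)
  fit <- fit_hdrda(d$X, d$labels, hdrda_params(1, 1e-3))
  muA <- colMeans(d$X[d$labels == "A", ])
  post <- predict_posteriors(fit, matrix(muA, 1))
  expect_gt(post[1, "A"], 0.99)

  # literally identical class distributions with equal priors
  X2 <- rbind(d$X[1:50, ], d$X[1:50, ])
  lab2 <- rep(c("A", "B"), each = 50)
  fit2 <- fit_hdrda(X2, lab2, hdrda_params(1, 1e-3))
  post2 <- predict_posteriors(fit2, d$X[1:5, ])
  expect_equal(unname(post2), matrix(0.5, 5, 2), tolerance = 1e-9)

  expect_error(predict_posteriors(fit, matrix(c(NA, 1, 2, 3), 1)),
               "non-finite")
  expect_error(fit_hdrda(d$X[c(1, 51:100), ], d$labels[c(1, 51:100)]),
               ">= 2")
})

test_that("posterior rows sum to 1 and predictions are rotation invariant", {
  set.seed(10)
  d <- gaussian_classes(n_per = 25, p = 6, delta = 1.5, g = 3, seed = 10)
  test <- gaussian_classes(n_per = 15, p = 6, delta = 1.5, g = 3, seed = 11)$X
  fit <- fit_hdrda(d$X, d$labels, hdrda_params(0.5, 1e-2))
  post <- predict_posteriors(fit, test)
  expect_equal(unname(rowSums(post)), rep(1, nrow(test)), tolerance = 1e-9)

  Q <- qr.Q(qr(matrix(rnorm(36), 6, 6)))
  fitR <- fit_hdrda(d$X %*% Q, d$labels, hdrda_params(0.5, 1e-2))
  postR <- predict_posteriors(fitR, test %*% Q)
  expect_equal(unname(post), unname(postR), tolerance = 1e-6)
})

test_that("two-class CVA axis matches the closed-form discriminant", {
  set.seed(12)
  n <- 200
  Sig <- matrix(c(1, 0.6, 0.6, 2), 2)
  L <- chol(Sig)
  X <- rbind(matrix(rnorm(n * 2), n, 2) %*% L,
             sweep(matrix(rnorm(n * 2), n, 2) %*% L, 2, c(2, 1), "+"))
  labels <- rep(c("A", "B"), each = n)
  fit <- fit_cva(X, labels, retained_dims = 2)
  mus <- rowsum(X, labels) / n
  W <- (crossprod(sweep(X[1:n, ], 2, mus[1, ])) +
          crossprod(sweep(X[-(1:n), ], 2, mus[2, ]))) / (2 * n - 2)
  oracle <- solve(W, mus[2, ] - mus[1, ])
  a <- fit$cva_axes[, 1]
  expect_equal(abs(sum(a * oracle) / sqrt(sum(a^2) * sum(oracle^2))), 1,
               tolerance = 1e-8)
})

test_that("canonical scores have identity within-group covariance", {
  set.seed(13)
  d <- gaussian_classes(n_per = 40, p = 5, delta = 2, g = 4, seed = 13)
  fit <- fit_cva(d$X, d$labels, retained_dims = 5)
  sc <- cva_scores(fit, d$X)
  g <- 4; n <- nrow(d$X)
  W <- matrix(0, ncol(sc), ncol(sc))
  for (cl in unique(d$labels)) {
    scj <- sc[d$labels == cl, , drop = FALSE]
    W <- W + crossprod(sweep(scj, 2, colMeans(scj)))
  }
  W <- W / (n - g)
  expect_equal(W, diag(ncol(sc)), tolerance = 1e-8, ignore_attr = TRUE)
  expect_lte(ncol(sc), g - 1)
  expect_error(fit_cva(d$X, d$labels, retained_dims = 50), "rank")
})

test_that("classification metrics match hand-counted confusions", {
  # confusion [[5,1,0],[2,3,1],[0,0,6]]: build posteriors realizing it
  conf <- rbind(c(5, 1, 0), c(2, 3, 1), c(0, 0, 6))
  classes <- c("A", "B", "C")
  true <- c(); pred <- c()
  for (i in 1:3) for (j in 1:3) {
    true <- c(true, rep(classes[i], conf[i, j]))
    pred <- c(pred, rep(classes[j], conf[i, j]))
  }
  post <- matrix(0.1, length(true), 3, dimnames = list(NULL, classes))
  post[cbind(seq_along(pred), match(pred, classes))] <- 0.8
  rep <- classification_metrics(post, true, ks = c(1, 2))
  tc <- tidy(rep)
  expect_equal(tc$sensitivity, c(5 / 6, 3 / 6, 6 / 6))
  for (cl in classes) {
    o <- counted_metrics(true, pred, cl)
    expect_equal(tc$specificity[tc$class == cl], o$specificity)
    expect_equal(tc$balanced_accuracy[tc$class == cl],
                 (o$sensitivity + o$specificity) / 2)
  }

  # perfect posteriors
  perfect <- matrix(0, length(true), 3, dimnames = list(NULL, classes))
  perfect[cbind(seq_along(true), match(true, classes))] <- 1
  repp <- classification_metrics(perfect, true, ks = c(1, 3))
  expect_true(all(tidy(repp)$sensitivity == 1))
  expect_true(all(tidy(repp)$specificity == 1))
  expect_true(all(tidy(repp)$top3_sensitivity == 1))
})

test_that("top-k hit rates are monotone in k", {
  set.seed(14)
  g <- 8
  post <- matrix(rexp(60 * g), 60, g)
  post <- post / rowSums(post)
  colnames(post) <- paste0("c", 1:g)
  true <- sample(colnames(post), 60, TRUE)
  rep <- classification_metrics(post, true, ks = c(1, 3, 5))
  gl <- glance(rep)
  expect_lte(gl$mean_top1_sensitivity, gl$mean_top3_sensitivity)
  expect_lte(gl$mean_top3_sensitivity, gl$mean_top5_sensitivity)
})

test_that("family LOOCV reduces to ordinary LOOCV for singleton families", {
  d <- gaussian_classes(n_per = 12, p = 4, delta = 3, g = 2, seed = 15)
  meta <- tibble::tibble(subject_id = rownames(d$X), syndrome = d$labels,
                         diagnosis_status = "clinical",
                         family_id = NA_character_)
  folds <- morphodx:::make_folds(meta, "family", k = NA, seed = 1)
  expect_equal(length(unique(folds)), nrow(meta))

  # families are never split across folds
  meta$family_id[1:6] <- "F1"
  folds2 <- morphodx:::make_folds(meta, "family", k = NA, seed = 1)
  expect_equal(length(unique(folds2[1:6])), 1)
  expect_equal(length(unique(folds2)), nrow(meta) - 5)
})

test_that("family LOOCV and 20-fold CV agree on a well-separated cohort", {
  synth <- generate_cohort(generator_config(
    n_landmarks = 30, n_midline = 4, n_syndromes = 5, n_per_syndrome = 40,
    n_unaffected = 0, n_families = 0, severity_scale = 0.08, seed = 17))
  prep <- prepare_shapes(synth$cohort)
  params <- hdrda_params(1, 1e-2)
  fam <- crossvalidate(prep$shapes, prep$meta, method = "hdrda",
                       params = params, scheme = "family")
  k20 <- crossvalidate(prep$shapes, prep$meta, method = "hdrda",
                       params = params, scheme = "kfold", k = 20, seed = 1)
  expect_lt(abs(glance(fam)$mean_sensitivity - glance(k20)$mean_sensitivity),
            0.05)
})

test_that("two-group CVA separates separable groups and respects priors", {
  synth <- generate_cohort(generator_config(
    n_landmarks = 30, n_midline = 4, n_syndromes = 2, n_per_syndrome = 25,
    n_unaffected = 50, n_families = 0, severity_scale = 0.15, seed = 18))
  prep <- prepare_shapes(synth$cohort)
  rep <- two_group_cva(prep$shapes, prep$meta, k = 5, seed = 1)
  tc <- tidy(rep)
  expect_true(all(tc$sensitivity > 0.95))

  # identical group distributions: accuracy ~ the larger prior
  d <- gaussian_classes(n_per = 60, p = 4, delta = 0, g = 2, seed = 19)
  meta <- tibble::tibble(subject_id = rownames(d$X),
                         syndrome = rep(c("unaffected", "sA"), c(80, 40)),
                         diagnosis_status = "clinical",
                         family_id = NA_character_)
  rep0 <- two_group_cva(d$X, meta, k = 5, seed = 2)
  expect_lt(abs(glance(rep0)$accuracy - 80 / 120), 0.12)
})

test_that("hyperparameter tuning is deterministic and honours the grid", {
  prep <- small_prep()
  one <- tune_hyperparameters(prep$shapes, prep$meta,
                              grid = data.frame(lambda = 1, gamma = 0.01),
                              scheme = "kfold", k = 4, seed = 2)
  expect_equal(one$lambda, 1)
  expect_equal(one$gamma, 0.01)

  grid <- expand.grid(lambda = c(0.5, 1), gamma = c(1e-3, 1e-1))
  a <- tune_hyperparameters(prep$shapes, prep$meta, grid = grid,
                            scheme = "kfold", k = 4, seed = 3)
  b <- tune_hyperparameters(prep$shapes, prep$meta, grid = grid,
                            scheme = "kfold", k = 4, seed = 3)
  expect_equal(a$lambda, b$lambda)
  expect_equal(a$gamma, b$gamma)
  expect_error(tune_hyperparameters(prep$shapes, prep$meta,
                                    grid = data.frame()), "empty")
})
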