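sim_growth <- function(n = 40, p = 12, degree = 3, noise = 0, seed = 1,
                       sex_shift = 0, u = NULL) {
  set.seed(seed)
  age <- runif(n, 1, 60)
  sex <- sample(c("female", "male"), n, TRUE)
  if (is.null(u)) { u <- rnorm(p); u <- u / sqrt(sum(u^2)) }
  v <- rnorm(p); v <- v / sqrt(sum(v^2))
  trend <- switch(degree,
                  `1` = age,
                  `2` = age + 0.02 * age^2,
                  `3` = age + 0.02 * age^2 - 3e-4 * age^3)
  shapes <- outer(trend / 60, u) +
    outer(ifelse(sex == "male", 0.5, -0.5) * sex_shift, v) +
    matrix(rnorm(n * p, sd = noise), n, p)
  list(shapes = shapes, age = age, sex = sex, u = u)
}

ss <- function(m) sum(sweep(m, 2, colMeans(m))^2)

test_that("the cubic model interpolates noiseless polynomial growth", {
  d <- sim_growth(degree = 3, noise = 0, sex_shift = 0.1, seed = 2)
  fit <- fit_age_sex_model(d$shapes, d$age, d$sex)
  res <- d$shapes - standardize(fit, d$shapes, d$age, d$sex)
  std <- standardize(fit, d$shapes, d$age, d$sex)
  expect_lt(ss(std), 1e-12 * ss(d$shapes))
})

test_that("coefficients match a normal-equations solve", {
  d <- sim_growth(n = 10, p = 5, noise = 0.1, seed = 3)
  fit <- fit_age_sex_model(d$shapes, d$age, d$sex)
  pb <- poly(d$age, 3)
  X <- cbind(1, pb, ifelse(d$sex == "male", 0.5, -0.5))
  beta <- solve(crossprod(X), crossprod(X, d$shapes))
  expect_equal(unname(fit$coefficients), unname(beta), tolerance = 1e-8)
})

test_that("null-model R2 matches its expectation and standardization removes signal", {
  set.seed(9)
  n <- 200; p <- 20
  shapes <- matrix(rnorm(n * p), n, p)
  age <- runif(n, 1, 60)
  sex <- sample(c("female", "male"), n, TRUE)
  fit <- fit_age_sex_model(shapes, age, sex)
  std <- standardize(fit, shapes, age, sex)
  r2 <- 1 - ss(std) / ss(shapes)
  expect_lt(abs(r2 - 4 / (n - 1)), 0.015)

  # residual orthogonality: refitting on the standardized output finds nothing
  fit2 <- fit_age_sex_model(std, age, sex)
  std2 <- standardize(fit2, std, age, sex)
  expect_lt(ss(std) - ss(std2), 1e-10 * ss(std))
})

test_that("a model fitted on one cohort standardizes an exchangeable cohort", {
  set.seed(40)
  u <- rnorm(12); u <- u / sqrt(sum(u^2))
  dA <- sim_growth(n = 150, noise = 0.02, seed = 4, u = u)
  dB <- sim_growth(n = 150, noise = 0.02, seed = 5, u = u)
  fit <- fit_age_sex_model(dA$shapes, dA$age, dA$sex)
  r2_of <- function(shapes, age, sex) {
    f <- fit_age_sex_model(shapes, age, sex)
    1 - ss(standardize(f, shapes, age, sex)) / ss(shapes)
  }
  before <- r2_of(dB$shapes, dB$age, dB$sex)
  stdB <- suppressWarnings(standardize(fit, dB$shapes, dB$age, dB$sex))
  after <- r2_of(stdB, dB$age, dB$sex)
  expect_lt(after, 0.1 * before)
})

test_that("degenerate inputs are handled", {
  d <- sim_growth(seed = 6)
  expect_error(fit_age_sex_model(d$shapes, rep(5, 40), d$sex), "constant")
  zero <- matrix(2, 40, 6)
  fit <- fit_age_sex_model(zero, d$age, d$sex)
  std <- standardize(fit, zero, d$age, d$sex)
  expect_lt(max(abs(std - 2)), 1e-10)
})

test_that("age regression scores track age", {
  d <- sim_growth(degree = 1, noise = 0, seed = 7)
  fit <- fit_age_sex_model(d$shapes, d$age, d$sex)
  sc <- age_regression_score(fit, d$shapes)
  expect_equal(cor(sc, d$age), 1, tolerance = 1e-9)
  expect_length(age_regression_score(fit, d$shapes[1, , drop = FALSE]), 1)
  expect_true(is.finite(age_regression_score(fit, d$shapes[1, , drop = FALSE])))

  # age-independent cohort: score an independent sample so the axis is not
  # evaluated on the data that defined it
  set.seed(8)
  shapes0 <- matrix(rnorm(500 * 12), 500, 12)
  age0 <- runif(500, 1, 60)
  sex0 <- sample(c("female", "male"), 500, TRUE)
  fit0 <- fit_age_sex_model(shapes0[1:200, ], age0[1:200], sex0[1:200])
  sc0 <- age_regression_score(fit0, shapes0[201:500, ])
  expect_lt(abs(cor(sc0, age0[201:500])), 0.15)
})

test_that("ordering-averaged type-1 SS is order-invariant on balanced designs", {
  set.seed(10)
  df <- expand.grid(A = factor(c("a1", "a2")), B = factor(c("b1", "b2", "b3")))
  df <- df[rep(seq_len(nrow(df)), each = 4), ]
  n <- nrow(df)
  Y <- matrix(rnorm(n * 6), n, 6) +
    model.matrix(~ A + B, df)[, -1] %*% matrix(rnorm(3 * 6, sd = 2), 3, 6)
  tab <- procrustes_manova(Y, df, c("A", "B"), n_perm = 99, seed = 1)

  # orthogonal design: single-order sequential SS equals the average
  one_order <- function(first, second) {
    QA <- qr.Q(qr(cbind(1, model.matrix(~ df[[first]])[, -1])))
    ss1 <- sum(crossprod(QA, Y)^2) - sum(crossprod(matrix(1 / sqrt(n), n), Y)^2)
    QB <- qr.Q(qr(cbind(1, model.matrix(~ df[[first]])[, -1],
                        model.matrix(~ df[[second]])[, -1])))
    ss2 <- sum(crossprod(QB, Y)^2) - sum(crossprod(QA, Y)^2)
    c(ss1, ss2)
  }
  ab <- one_order("A", "B")
  ba <- one_order("B", "A")
  expect_equal(tab$SS[tab$term == "A"], ab[1], tolerance = 1e-10)
  expect_equal(tab$SS[tab$term == "B"], ab[2], tolerance = 1e-10)
  expect_equal(ab[1], ba[2], tolerance = 1e-10)

  # SS additivity
  expect_equal(sum(tab$SS[tab$term %in% c("A", "B", "Residuals")]),
               tab$SS[tab$term == "Total"], tolerance = 1e-8)
})

test_that("one-factor Procrustes SS matches direct and vegan oracles", {
  set.seed(11)
  grp <- factor(rep(letters[1:3], times = c(8, 10, 12)))
  Y <- matrix(rnorm(30 * 8), 30, 8)
  Y[grp == "b", 1] <- Y[grp == "b", 1] + 1.5
  df <- data.frame(grp = grp)
  tab <- procrustes_manova(Y, df, "grp", n_perm = 199, seed = 2)
  expect_equal(tab$SS[1], between_group_ss(Y, grp), tolerance = 1e-10)
  expect_lt(tab$p[1], 0.05)

  skip_if_not_installed("vegan")
  adn <- vegan::adonis2(dist(Y) ~ grp, data = df, permutations = 99)
  expect_equal(unname(tab$SS[1]), adn$SumOfSqs[1], tolerance = 1e-8)
  expect_equal(unname(tab$F[1]), adn$F[1], tolerance = 1e-8)
})

test_that("aliased terms are rejected by name", {
  df <- data.frame(x = rnorm(20))
  df$y <- 2 * df$x
  Y <- matrix(rnorm(20 * 4), 20, 4)
  expect_error(procrustes_manova(Y, df, c("x", "y"), n_perm = 99), "aliased")
})
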