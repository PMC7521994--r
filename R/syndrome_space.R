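#' Phenotypic severity of a syndrome
#'
#' Mean Procrustes distance between a syndrome's subjects and the mean shape
#' of unrelated, unaffected subjects.
#'
#' @param shapes shape matrix of the syndrome's subjects (standardized).
#' @param unaffected_mean mean unaffected shape vector.
#' @return A non-negative number.
#' @export
severity <- function(shapes, unaffected_mean) {
  if (is.null(dim(shapes))) shapes <- matrix(shapes, nrow = 1)
  mean(tangent_distances(shapes, unaffected_mean))
}

#' Phenotypic distinctiveness of each syndrome
#'
#' Procrustes distance from each syndrome's mean shape to the nearest other
#' syndrome mean. The unaffected class is not a candidate neighbour.
#'
#' @param syndrome_means matrix of mean shapes, rows named by syndrome.
#' @return Named numeric vector of nearest-neighbour distances.
#' @export
distinctiveness <- function(syndrome_means) {
  labs <- rownames(syndrome_means)
  labs <- setdiff(labs, "unaffected")
  if (length(labs) < 2) {
    stop("distinctiveness needs at least 2 syndromes", call. = FALSE)
  }
  m <- syndrome_means[labs, , drop = FALSE]
  out <- setNames(numeric(length(labs)), labs)
  for (i in seq_along(labs)) {
    out[i] <- min(tangent_distances(m[-i, , drop = FALSE], m[i, ]))
  }
  out
}

#' Within-syndrome shape variance
#'
#' Mean squared Procrustes distance of a syndrome's subjects to their own mean
#' shape (the Procrustes variance); equals the trace of the within-class
#' coordinate covariance (divisor `n`).
#'
#' @param shapes shape matrix of the syndrome's subjects.
#' @return A non-negative number.
#' @export
within_variance <- function(shapes) {
  stopifnot(nrow(shapes) >= 2)
  mean(tangent_distances(shapes, colMeans(shapes))^2)
}

#' Integratedness: relative variance of covariance eigenvalues
#'
#' `Var(lambda) / (mean(lambda)^2 (m - 1))` over the `m` nonzero eigenvalues
#' (those above `1e-12` of the largest). 0 for spherical covariance, 1 when
#' all variance lies on one axis.
#'
#' @param covariance positive semidefinite covariance matrix.
#' @return A number in `[0, 1]`.
#' @export
integratedness <- function(covariance) {
  ev <- eigen(covariance, symmetric = TRUE, only.values = TRUE)$values
  if (max(ev) <= 0) stop("covariance matrix is zero", call. = FALSE)
  ev <- ev[ev > 1e-12 * max(ev)]
  m <- length(ev)
  if (m == 1) return(1)
  # population variance of the eigenvalues
  v <- mean((ev - mean(ev))^2)
  v / (mean(ev)^2 * (m - 1))
}

#' Distance between covariance matrices
#'
#' Affine-invariant Riemannian distance
#' `||log(A^{-1/2} B A^{-1/2})||_F` between ridge-regularized covariance
#' matrices (the log-Euclidean distance `||log A - log B||_F` is available as
#' an alternative). Symmetric, zero iff the matrices are equal.
#'
#' @param cov_a,cov_b covariance matrices of equal dimension.
#' @param ridge ridge added to each diagonal, in units of the mean variance,
#'   to make rank-deficient matrices positive definite; sample covariances of
#'   landmark data have rank at most `n - 1`, so a non-negligible ridge
#'   (default 1e-3) is required for the distance to be well conditioned.
#' @param method `"riemannian"` (default) or `"log_euclidean"`.
#' @return A non-negative number.
#' @export
covariance_distance <- function(cov_a, cov_b, ridge = 1e-3,
                                method = c("riemannian", "log_euclidean")) {
  method <- match.arg(method)
  if (!all(dim(cov_a) == dim(cov_b))) {
    stop("covariance matrices have different dimensions", call. = FALSE)
  }
  m <- nrow(cov_a)
  eps <- ridge * mean(c(diag(cov_a), diag(cov_b)))
  if (eps <= 0) eps <- ridge
  A <- cov_a + eps * diag(m)
  B <- cov_b + eps * diag(m)
  if (method == "log_euclidean") {
    return(sqrt(sum((mat_log(A) - mat_log(B))^2)))
  }
  ea <- eigen(A, symmetric = TRUE)
  Ainvhalf <- ea$vectors %*% (t(ea$vectors) / sqrt(ea$values))
  Mid <- Ainvhalf %*% B %*% Ainvhalf
  Mid <- (Mid + t(Mid)) / 2
  ev <- eigen(Mid, symmetric = TRUE, only.values = TRUE)$values
  # guard against eigenvalues driven to <= 0 by rounding
  ev <- pmax(ev, .Machine$double.eps * max(ev))
  sqrt(sum(log(ev)^2))
}

mat_log <- function(M) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  e$vectors %*% (t(e$vectors) * log(e$values))
}

#' Per-syndrome shape-space statistics
#'
#' Computes, for every syndrome with at least `min_n` subjects, the sample
#' size, phenotypic severity, distinctiveness, within-syndrome variance,
#' integratedness, and covariance distance to the reference covariance
#' (unaffected by default).
#'
#' @param shapes standardized shape matrix, rows named by subject.
#' @param meta metadata tibble aligned with `shapes`.
#' @param min_n minimum per-syndrome n (default 10).
#' @param reference reference covariance for [covariance_distance()]:
#'   `"unaffected"` (default) or `"pooled"`.
#' @return A tibble with one row per syndrome.
#' @export
syndrome_stats <- function(shapes, meta, min_n = 10,
                           reference = c("unaffected", "pooled")) {
  reference <- match.arg(reference)
  core <- meta$diagnosis_status != "relative"
  syn <- setdiff(unique(meta$syndrome[core]), "unaffected")
  counts <- table(meta$syndrome[core])
  syn <- sort(syn[counts[syn] >= max(min_n, 2)])
  unaff_idx <- core & meta$syndrome == "unaffected"
  if (!any(unaff_idx)) stop("no unaffected subjects in cohort", call. = FALSE)
  unaff_mean <- colMeans(shapes[unaff_idx, , drop = FALSE])

  means <- t(vapply(syn, function(s) {
    colMeans(shapes[core & meta$syndrome == s, , drop = FALSE])
  }, numeric(ncol(shapes))))
  rownames(means) <- syn
  dist_vec <- if (length(syn) >= 2) distinctiveness(means) else
    setNames(rep(NA_real_, length(syn)), syn)

  ref_cov <- if (reference == "unaffected") {
    stats::cov(shapes[unaff_idx, , drop = FALSE])
  } else {
    pooled_cov(shapes[core, , drop = FALSE], meta$syndrome[core])
  }

  rows <- purrr::map(syn, function(s) {
    sh <- shapes[core & meta$syndrome == s, , drop = FALSE]
    cv <- stats::cov(sh)
    tibble::tibble(
      syndrome = s,
      n = nrow(sh),
      severity = severity(sh, unaff_mean),
      distinctiveness = dist_vec[s],
      within_variance = within_variance(sh),
      integratedness = integratedness(cv),
      covariance_distance = covariance_distance(cv, ref_cov)
    )
  })
  dplyr::bind_rows(rows)
}

pooled_cov <- function(shapes, labels) {
  classes <- unique(labels)
  p <- ncol(shapes)
  acc <- matrix(0, p, p)
  n <- 0L
  for (cl in classes) {
    sh <- shapes[labels == cl, , drop = FALSE]
    if (nrow(sh) < 2) next
    acc <- acc + stats::cov(sh) * (nrow(sh) - 1)
    n <- n + nrow(sh) - 1L
  }
  acc / n
}

#' Determinants of classification performance
#'
#' Simple and combined regressions of per-syndrome sensitivity on severity,
#' distinctiveness, within-syndrome variance, integratedness and log sample
#' size; PCA of the standardized determinant matrix; and a regression of the
#' between-method sensitivity difference on PC1.
#'
#' @param stats a [syndrome_stats()] tibble.
#' @param sensitivities tibble with columns `syndrome` and one sensitivity
#'   column per method (e.g. `hdrda`, `cva`).
#' @return A list of class `determinants_analysis`: `$simple` (per-factor
#'   regressions), `$combined` (multiple-regression coefficients per method),
#'   `$pca` (PC1 scores and variance share), `$method_difference` (regression
#'   of the method sensitivity difference on PC1).
#' @export
determinants_analysis <- function(stats, sensitivities) {
  df <- dplyr::inner_join(stats, sensitivities, by = "syndrome")
  if (nrow(df) < 5) stop("need >= 5 syndromes", call. = FALSE)
  factors <- c("severity", "distinctiveness", "within_variance",
               "integratedness", "log_n")
  df$log_n <- log(df$n)
  methods <- setdiff(names(sensitivities), "syndrome")

  X <- as.matrix(df[factors])
  sds <- apply(X, 2, sd)
  Xs <- sweep(sweep(X, 2, colMeans(X)), 2, ifelse(sds > 0, sds, 1), "/")
  cn <- kappa(Xs, exact = TRUE)
  if (!is.finite(cn) || cn > 1e6) {
    warning("determinant matrix is ill-conditioned (condition number ",
            format(cn, digits = 3), ")", call. = FALSE)
  }

  simple <- purrr::map(methods, function(m) {
    purrr::map(factors, function(f) {
      fit <- lm(df[[m]] ~ df[[f]])
      s <- summary(fit)
      tibble::tibble(method = m, factor = f,
                     estimate = coef(fit)[2],
                     r_squared = s$r.squared,
                     p_value = s$coefficients[2, 4])
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()

  combined <- purrr::map(methods, function(m) {
    fit <- lm(stats::reformulate(factors, response = m), data = df)
    s <- summary(fit)
    tibble::tibble(method = m,
                   factor = rownames(s$coefficients),
                   estimate = s$coefficients[, 1],
                   p_value = s$coefficients[, 4],
                   r_squared = s$r.squared)
  }) |> dplyr::bind_rows()

  pc <- prcomp(Xs, center = FALSE, scale. = FALSE)
  share <- pc$sdev^2 / sum(pc$sdev^2)
  pca <- list(scores = tibble::tibble(syndrome = df$syndrome,
                                      PC1 = pc$x[, 1]),
              variance_share = share[1],
              rotation = pc$rotation)

  method_difference <- NULL
  if (length(methods) >= 2) {
    diff <- df[[methods[1]]] - df[[methods[2]]]
    fit <- lm(diff ~ pc$x[, 1])
    s <- summary(fit)
    method_difference <- tibble::tibble(
      contrast = paste(methods[1], "-", methods[2]),
      slope = coef(fit)[2],
      r_squared = s$r.squared,
      p_value = s$coefficients[2, 4])
  }

  structure(list(data = df, simple = simple, combined = combined, pca = pca,
                 method_difference = method_difference),
            class = "determinants_analysis")
}

#' @export
print.determinants_analysis <- function(x, ...) {
  cat("<determinants_analysis> ", nrow(x$data), " syndromes; PC1 share ",
      round(100 * x$pca$variance_share, 1), "%\n", sep = "")
  invisible(x)
}

#' @export
tidy.determinants_analysis <- function(x, ...) x$simple

#' @export
glance.determinants_analysis <- function(x, ...) {
  tibble::tibble(n_syndromes = nrow(x$data),
                 pc1_variance_share = x$pca$variance_share)
}
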