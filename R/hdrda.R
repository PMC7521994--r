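#' Naive class priors
#'
#' The naive prior of a class is the proportion of subjects belonging to it.
#'
#' @param labels vector of class labels.
#' @return Named probability vector summing to 1, in sorted label order.
#' @export
naive_priors <- function(labels) {
  if (length(labels) == 0L) stop("no labels", call. = FALSE)
  tab <- table(labels)
  p <- as.numeric(tab) / sum(tab)
  names(p) <- names(tab)
  p
}

#' HDRDA hyperparameters
#'
#' @param lambda pooling parameter in `[0, 1]`: 0 keeps class-specific
#'   covariances (QDA-like), 1 pools them (LDA-like).
#' @param gamma ridge parameter (>= 0) shrinking the covariance toward the
#'   identity; required (> 0) whenever features outnumber subjects.
#' @param gamma_relative if `TRUE` (default), `gamma` is expressed in units of
#'   the mean diagonal of the pooled covariance (`trace/p`), so the same value
#'   works across measurement scales; set `FALSE` for an absolute ridge.
#' @return A list of class `hdrda_params`.
#' @export
hdrda_params <- function(lambda = 0.5, gamma = 1e-3, gamma_relative = TRUE) {
  stopifnot(lambda >= 0, lambda <= 1, gamma >= 0)
  structure(list(lambda = lambda, gamma = gamma,
                 gamma_relative = isTRUE(gamma_relative)),
            class = "hdrda_params")
}

#' Fit a high-dimensional regularized discriminant analysis model
#'
#' Gaussian discriminant analysis with the regularized class covariance
#' `S_k(lambda, gamma) = (1 - lambda) S_k + lambda S_pooled + gamma I`.
#' The per-class covariance uses divisor `n_k - 1` and the pooled covariance
#' divisor `n - g`, so `(lambda, gamma) = (1, 0)` reduces exactly to
#' pooled-covariance LDA and `(0, 0)` to QDA.
#'
#' When features outnumber subjects the computation is carried out exactly in
#' the subspace spanned by the centred training data (rank `r <= n - 1`), with
#' `gamma` applied to every retained direction. A test vector's component
#' orthogonal to that span contributes `||x_perp||^2 / gamma` identically to
#' every class score, so posteriors equal the dense full-space computation.
#'
#' @param X `n x p` matrix of (standardized) shape vectors.
#' @param labels class labels, one per row.
#' @param params an [hdrda_params()] object.
#' @param priors class priors; defaults to [naive_priors()] of `labels`.
#' @return An object of class `hdrda`.
#' @export
fit_hdrda <- function(X, labels, params = hdrda_params(), priors = NULL) {
  labels <- as.character(labels)
  stopifnot(nrow(X) == length(labels))
  classes <- sort(unique(labels))
  g <- length(classes)
  n <- nrow(X); p <- ncol(X)
  n_k <- table(factor(labels, levels = classes))
  if (any(n_k < 2)) {
    stop("every class needs >= 2 training subjects (violated by '",
         classes[which(n_k < 2)[1]], "')", call. = FALSE)
  }
  if (is.null(priors)) priors <- naive_priors(labels)
  priors <- priors[classes]
  stopifnot(abs(sum(priors) - 1) < 1e-12)

  center <- colMeans(X)
  Xc <- sweep(X, 2, center)
  sv <- svd(Xc, nu = 0)
  r <- sum(sv$d > max(sv$d) * 1e-10)
  if (r < p && params$gamma <= 0) {
    stop("training span has rank ", r, " < p = ", p,
         "; a positive gamma is required", call. = FALSE)
  }
  basis <- sv$v[, seq_len(r), drop = FALSE]     # p x r
  Z <- Xc %*% basis                             # n x r scores

  means <- matrix(NA_real_, g, r, dimnames = list(classes, NULL))
  S_list <- vector("list", g)
  pooled <- matrix(0, r, r)
  for (j in seq_len(g)) {
    Zj <- Z[labels == classes[j], , drop = FALSE]
    means[j, ] <- colMeans(Zj)
    Cj <- crossprod(sweep(Zj, 2, means[j, ]))
    S_list[[j]] <- Cj / (nrow(Zj) - 1L)
    pooled <- pooled + Cj
  }
  pooled <- pooled / (n - g)
  # trace is invariant under the basis change, so trace/p matches the dense
  # full-space mean diagonal
  gamma_eff <- if (params$gamma_relative) {
    params$gamma * sum(diag(pooled)) / p
  } else {
    params$gamma
  }

  inv_list <- vector("list", g)
  logdet <- numeric(g)
  for (j in seq_len(g)) {
    Sj <- (1 - params$lambda) * S_list[[j]] + params$lambda * pooled +
      gamma_eff * diag(r)
    eg <- eigen(Sj, symmetric = TRUE)
    if (min(eg$values) <= r * max(eg$values) * 1e-14) {
      stop("regularized covariance for class '", classes[j],
           "' is singular; use a positive gamma", call. = FALSE)
    }
    inv_list[[j]] <- eg$vectors %*% (t(eg$vectors) / eg$values)
    logdet[j] <- sum(log(eg$values))
  }

  structure(list(method = "hdrda", class_labels = classes,
                 priors = priors, params = params, gamma_eff = gamma_eff,
                 center = center, basis = basis,
                 class_means = means, inv_cov = inv_list, logdet = logdet,
                 rank = r, p = p),
            class = "hdrda")
}

#' @export
print.hdrda <- function(x, ...) {
  cat("<hdrda> ", length(x$class_labels), " classes, p = ", x$p,
      ", rank = ", x$rank, ", lambda = ", x$params$lambda,
      ", gamma = ", x$params$gamma, "\n", sep = "")
  invisible(x)
}

#' Posterior class probabilities
#'
#' Gaussian class-conditional posteriors,
#' `posterior_k(x) propto pi_k exp(-d_k(x)/2)` with discriminant score
#' `d_k(x) = (x - mu_k)' S_k^{-1} (x - mu_k) + log|S_k| - 2 log pi_k`,
#' normalized per row.
#'
#' @param model a fitted [fit_hdrda()] or [fit_cva()] model.
#' @param X `m x p` matrix of shapes to classify.
#' @return `m x g` posterior matrix with rows summing to 1, columns named by
#'   class.
#' @export
predict_posteriors <- function(model, X) {
  UseMethod("predict_posteriors")
}

#' @export
predict_posteriors.hdrda <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (ncol(X) != model$p) {
    stop("feature dimension ", ncol(X), " does not match training (", model$p,
         ")", call. = FALSE)
  }
  bad <- which(rowSums(!is.finite(X)) > 0)
  if (length(bad)) {
    nm <- rownames(X)[bad[1]]
    stop("non-finite features for subject ",
         if (is.null(nm)) bad[1] else paste0("'", nm, "'"), call. = FALSE)
  }
  Z <- sweep(X, 2, model$center) %*% model$basis
  g <- length(model$class_labels)
  d <- matrix(NA_real_, nrow(X), g)
  for (j in seq_len(g)) {
    dz <- sweep(Z, 2, model$class_means[j, ])
    maha <- rowSums((dz %*% model$inv_cov[[j]]) * dz)
    d[, j] <- maha + model$logdet[j] - 2 * log(model$priors[j])
  }
  posteriors_from_scores(d, model$class_labels, rownames(X))
}

# scores d are -2 log-likelihood-ish; smaller is better
posteriors_from_scores <- function(d, classes, rn = NULL) {
  d <- d - apply(d, 1, min)
  w <- exp(-0.5 * d)
  post <- w / rowSums(w)
  colnames(post) <- classes
  rownames(post) <- rn
  post
}

#' @export
predict.hdrda <- function(object, newdata, ...) {
  post <- predict_posteriors(object, newdata)
  factor(colnames(post)[max.col(post, ties.method = "first")],
         levels = object$class_labels)
}
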