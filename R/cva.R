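#' Fit a canonical variates analysis classifier
#'
#' Shapes are first projected onto principal components (retaining
#' `retained_fraction` of total variance, or exactly `retained_dims`
#' components), then the canonical axes solve the between-/within-group
#' generalized eigenproblem. Axes are scaled so the pooled within-group
#' covariance of canonical scores is the identity; classification is by
#' Mahalanobis distance (Euclidean in canonical space) to class centroids
#' with prior adjustment.
#'
#' @param X `n x p` shape matrix.
#' @param labels class labels.
#' @param retained_dims number of principal components to retain; if `NULL`,
#'   chosen as the smallest number reaching `retained_fraction` of variance
#'   (capped at `n - g` so the within-group covariance stays nonsingular).
#' @param retained_fraction fraction of variance the PCA projection keeps
#'   (default 0.99).
#' @param priors class priors; defaults to [naive_priors()].
#' @return An object of class `cva_model` with canonical axes (`cva_axes`,
#'   expressed in the original feature space), centroids of canonical scores,
#'   and the PCA projection.
#' @export
fit_cva <- function(X, labels, retained_dims = NULL, retained_fraction = 0.99,
                    priors = NULL) {
  labels <- as.character(labels)
  stopifnot(nrow(X) == length(labels))
  classes <- sort(unique(labels))
  g <- length(classes)
  n <- nrow(X)
  if (n <= g) stop("CVA needs n > number of classes", call. = FALSE)
  if (is.null(priors)) priors <- naive_priors(labels)
  priors <- priors[classes]

  center <- colMeans(X)
  Xc <- sweep(X, 2, center)
  sv <- svd(Xc, nu = 0)
  rank <- sum(sv$d > max(sv$d) * 1e-10)
  if (!is.null(retained_dims)) {
    if (retained_dims > rank) {
      stop("retained_dims = ", retained_dims, " exceeds data rank ", rank,
           call. = FALSE)
    }
    q <- retained_dims
  } else {
    varexp <- cumsum(sv$d[seq_len(rank)]^2) / sum(sv$d[seq_len(rank)]^2)
    q <- which(varexp >= retained_fraction)[1]
    q <- min(q, n - g)   # keep within-group covariance nonsingular
  }
  proj <- sv$v[, seq_len(q), drop = FALSE]
  Z <- Xc %*% proj

  means <- rowsum(Z, labels) / as.vector(table(factor(labels, classes)))
  W <- matrix(0, q, q)
  B <- matrix(0, q, q)
  for (j in seq_len(g)) {
    Zj <- Z[labels == classes[j], , drop = FALSE]
    W <- W + crossprod(sweep(Zj, 2, means[j, ]))
    B <- B + nrow(Zj) * tcrossprod(means[j, ] - colMeans(Z))
  }
  W <- W / (n - g)
  ew <- eigen(W, symmetric = TRUE)
  if (min(ew$values) <= q * max(ew$values) * 1e-12) {
    stop("within-group covariance is singular after PCA projection; ",
         "retain fewer dimensions", call. = FALSE)
  }
  Whalf_inv <- ew$vectors %*% (t(ew$vectors) / sqrt(ew$values))
  M <- t(Whalf_inv) %*% B %*% Whalf_inv
  M <- (M + t(M)) / 2
  em <- eigen(M, symmetric = TRUE)
  n_axes <- min(g - 1L, sum(em$values > max(em$values) * 1e-10))
  A <- Whalf_inv %*% em$vectors[, seq_len(n_axes), drop = FALSE]  # q x a

  scores <- Z %*% A
  centroids <- rowsum(scores, labels) /
    as.vector(table(factor(labels, classes)))

  structure(list(method = "cva", class_labels = classes, priors = priors,
                 center = center, pca_proj = proj,
                 cva_axes = proj %*% A, axes_pc = A,
                 centroids = centroids, eigenvalues = em$values[seq_len(n_axes)],
                 retained_dims = q, p = ncol(X)),
            class = "cva_model")
}

#' @export
print.cva_model <- function(x, ...) {
  cat("<cva_model> ", length(x$class_labels), " classes, ",
      ncol(x$axes_pc), " canonical axes on ", x$retained_dims,
      " principal components\n", sep = "")
  invisible(x)
}

#' @export
predict_posteriors.cva_model <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (ncol(X) != model$p) {
    stop("feature dimension ", ncol(X), " does not match training (", model$p,
         ")", call. = FALSE)
  }
  scores <- sweep(X, 2, model$center) %*% model$cva_axes
  g <- length(model$class_labels)
  d <- matrix(NA_real_, nrow(X), g)
  for (j in seq_len(g)) {
    d[, j] <- rowSums(sweep(scores, 2, model$centroids[j, ])^2) -
      2 * log(model$priors[j])
  }
  posteriors_from_scores(d, model$class_labels, rownames(X))
}

#' @export
predict.cva_model <- function(object, newdata, ...) {
  post <- predict_posteriors(object, newdata)
  factor(colnames(post)[max.col(post, ties.method = "first")],
         levels = object$class_labels)
}

#' Canonical scores of shapes
#'
#' @param model a fitted [fit_cva()] model.
#' @param X shape matrix.
#' @return `n x a` matrix of canonical variate scores.
#' @export
cva_scores <- function(model, X) {
  stopifnot(inherits(model, "cva_model"))
  sweep(X, 2, model$center) %*% model$cva_axes
}

#' Two-group discrimination: syndromic versus unaffected
#'
#' Collapses all syndromic subjects into a single class and cross-validates a
#' CVA discrimination of that class against unrelated, unaffected subjects.
#' Relatives are excluded.
#'
#' @param shapes standardized shape matrix, rows named by subject.
#' @param meta metadata tibble aligned with `shapes`.
#' @param scheme,k,seed cross-validation controls (see [crossvalidate()]).
#' @return A `classification_report` for the two-group task.
#' @export
two_group_cva <- function(shapes, meta, scheme = "kfold", k = 20, seed = 1) {
  keep <- meta$diagnosis_status != "relative"
  meta2 <- meta[keep, ]
  shapes2 <- shapes[keep, , drop = FALSE]
  meta2$syndrome <- ifelse(meta2$syndrome == "unaffected",
                           "unaffected", "syndromic")
  if (length(unique(meta2$syndrome)) < 2) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  crossvalidate(shapes2, meta2, method = "cva", scheme = scheme, k = k,
                seed = seed)
}
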