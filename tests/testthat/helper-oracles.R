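# Independent oracles used to freeze expected values.

# brute-force partial Procrustes distance for planar shapes: minimise
# ||A - B R(theta)|| over in-plane rotations on a fine grid
grid_procrustes_distance <- function(A, B, step = 1e-5) {
  center_unit <- function(m) {
    m <- sweep(m, 2, colMeans(m))
    m / sqrt(sum(m^2))
  }
  A <- center_unit(A); B <- center_unit(B)
  thetas <- seq(0, 2 * pi, by = step)
  # ||A - B R||^2 = 2 - 2 tr(R' B' A) for unit-size shapes
  M <- crossprod(B, A)
  tr <- M[1, 1] * cos(thetas) - M[2, 1] * sin(thetas) +
    M[1, 2] * sin(thetas) + M[2, 2] * cos(thetas) + M[3, 3]
  sqrt(max(0, 2 - 2 * max(tr)))
}

# dense full-space HDRDA: explicit p x p covariance algebra
dense_hdrda_posteriors <- function(X, labels, lambda, gamma, Xtest,
                                   priors = NULL) {
  classes <- sort(unique(labels))
  g <- length(classes); n <- nrow(X); p <- ncol(X)
  if (is.null(priors)) {
    priors <- as.numeric(table(labels)[classes]) / n
    names(priors) <- classes
  }
  S_list <- list(); pooled <- matrix(0, p, p)
  mus <- list()
  for (cl in classes) {
    Xj <- X[labels == cl, , drop = FALSE]
    mus[[cl]] <- colMeans(Xj)
    Cj <- crossprod(sweep(Xj, 2, mus[[cl]]))
    S_list[[cl]] <- Cj / (nrow(Xj) - 1)
    pooled <- pooled + Cj
  }
  pooled <- pooled / (n - g)
  d <- matrix(NA_real_, nrow(Xtest), g, dimnames = list(NULL, classes))
  for (j in seq_len(g)) {
    Sj <- (1 - lambda) * S_list[[j]] + lambda * pooled + gamma * diag(p)
    eg <- eigen(Sj, symmetric = TRUE)
    inv <- eg$vectors %*% (t(eg$vectors) / eg$values)
    dz <- sweep(Xtest, 2, mus[[j]])
    d[, j] <- rowSums((dz %*% inv) * dz) + sum(log(eg$values)) -
      2 * log(priors[j])
  }
  d <- d - apply(d, 1, min)
  w <- exp(-0.5 * d)
  w / rowSums(w)
}

# one-factor between-group SS by direct group-mean decomposition
between_group_ss <- function(Y, groups) {
  gm <- colMeans(Y)
  ss <- 0
  for (cl in unique(groups)) {
    Yg <- Y[groups == cl, , drop = FALSE]
    ss <- ss + nrow(Yg) * sum((colMeans(Yg) - gm)^2)
  }
  ss
}

# one-vs-rest confusion counting from labels
counted_metrics <- function(true, predicted, cl) {
  in_cl <- true == cl
  list(sensitivity = sum(predicted[in_cl] == cl) / sum(in_cl),
       specificity = sum(predicted[!in_cl] != cl) / sum(!in_cl))
}
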