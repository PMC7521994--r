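#' Generalized Procrustes analysis
#'
#' Iteratively superimposes landmark configurations: each configuration is
#' centred, scaled to unit centroid size, and rotated onto the current
#' consensus by orthogonal Procrustes rotation (proper rotations only,
#' determinant +1); the consensus is then recomputed as the renormalized
#' arithmetic mean. Iteration stops when the consensus moves less than `tol`
#' (Frobenius norm) or after `max_iter` sweeps. The result is invariant, to
#' `tol`, under arbitrary translation, rotation and uniform scaling of the
#' inputs.
#'
#' @param configs a [landmark_set()] (or `cohort`, whose landmarks are used).
#' @param tol convergence tolerance on the consensus (default 1e-10).
#' @param max_iter maximum number of alignment sweeps.
#' @return An `aligned_shapes` object with elements `shapes` (an `n x 3k`
#'   matrix of superimposed shape vectors, rows named by subject), `consensus`
#'   (`k x 3`), `centroid_sizes`, and `subject_id`.
#' @export
gpa <- function(configs, tol = 1e-10, max_iter = 100) {
  if (inherits(configs, "cohort")) configs <- configs$landmarks
  stopifnot(inherits(configs, "landmark_set"))
  n <- length(configs)
  if (n < 2L) stop("GPA needs at least 2 configurations", call. = FALSE)
  k <- n_landmarks(configs)

  aligned <- array(NA_real_, dim = c(k, 3L, n))
  sizes <- numeric(n)
  for (i in seq_len(n)) {
    m <- configs$coords[, , i]
    m <- sweep(m, 2, colMeans(m))
    cs <- sqrt(sum(m^2))
    if (cs < 1e-12) {
      stop("degenerate configuration (zero centroid size) for subject '",
           configs$subject_id[i], "'", call. = FALSE)
    }
    sizes[i] <- cs
    aligned[, , i] <- m / cs
  }

  consensus <- aligned[, , 1]
  consensus <- consensus / sqrt(sum(consensus^2))
  for (iter in seq_len(max_iter)) {
    for (i in seq_len(n)) {
      aligned[, , i] <- aligned[, , i] %*% procrustes_rotation(aligned[, , i],
                                                               consensus)
    }
    new_cons <- apply(aligned, c(1, 2), mean)
    new_cons <- sweep(new_cons, 2, colMeans(new_cons))
    new_cons <- new_cons / sqrt(sum(new_cons^2))
    delta <- sqrt(sum((new_cons - consensus)^2))
    consensus <- new_cons
    if (delta < tol) break
  }
  # final rotation pass so every shape is optimally rotated to the consensus
  for (i in seq_len(n)) {
    aligned[, , i] <- aligned[, , i] %*% procrustes_rotation(aligned[, , i],
                                                             consensus)
  }
  dimnames(aligned) <- list(NULL, c("x", "y", "z"), configs$subject_id)
  new_aligned_shapes(array_to_shapes(aligned), consensus, sizes,
                     configs$subject_id)
}

new_aligned_shapes <- function(shapes, consensus, sizes, ids) {
  rownames(shapes) <- ids
  structure(list(shapes = shapes, consensus = consensus,
                 centroid_sizes = sizes, subject_id = ids),
            class = "aligned_shapes")
}

#' @export
print.aligned_shapes <- function(x, ...) {
  cat("<aligned_shapes> ", nrow(x$shapes), " shapes, ",
      nrow(x$consensus), " landmarks (unit centroid size)\n", sep = "")
  invisible(x)
}

# Optimal rotation R (det +1) minimizing ||X R - C||_F.
procrustes_rotation <- function(x, target) {
  s <- svd(crossprod(x, target))
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Procrustes distance between two aligned shapes
#'
#' Partial Procrustes distance: the Euclidean norm of `a - b` after `b` is
#' optimally rotated onto `a`. Both inputs must be centred, unit-centroid-size
#' shape vectors (rows of an `aligned_shapes$shapes` matrix) or `k x 3`
#' matrices. Symmetric in its arguments; zero iff the shapes are identical up
#' to rotation.
#'
#' @param a,b shape vectors of equal length (or `k x 3` matrices).
#' @return A non-negative number.
#' @export
procrustes_distance <- function(a, b) {
  if (is.matrix(a)) a <- config_to_vector(a)
  if (is.matrix(b)) b <- config_to_vector(b)
  if (length(a) != length(b)) {
    stop("shape vectors have different lengths", call. = FALSE)
  }
  A <- vector_to_config(a)
  B <- vector_to_config(b)
  B <- B %*% procrustes_rotation(B, A)
  sqrt(sum((A - B)^2))
}

# Euclidean (tangent-space) distances of shape rows to a reference vector;
# used where shapes are already jointly superimposed.
tangent_distances <- function(shapes, ref) {
  sqrt(rowSums(sweep(shapes, 2, ref)^2))
}

#' Export aligned shapes or a symmetry decomposition as wide CSV
#'
#' Writes one row per subject with a `#`-prefixed provenance header recording
#' the package version and alignment parameters (no seeds are involved in
#' superimposition).
#'
#' @param x an `aligned_shapes` or `symmetry_decomposition` object.
#' @param path output path.
#' @param component for decompositions, `"symmetric"` or `"asymmetric"`.
#' @return `path`, invisibly.
#' @export
export_shapes_csv <- function(x, path, component = c("symmetric",
                                                     "asymmetric")) {
  if (inherits(x, "symmetry_decomposition")) {
    component <- match.arg(component)
    shapes <- x[[component]]
    what <- paste("object-symmetry decomposition,", component, "component")
  } else {
    stopifnot(inherits(x, "aligned_shapes"))
    shapes <- x$shapes
    what <- "GPA-aligned shapes (unit centroid size, tol 1e-10, max_iter 100)"
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# morphodx ", as.character(utils::packageVersion("morphodx"))),
    paste0("# ", what),
    paste0("# written ", format(Sys.time(), "%Y-%m-%d"))
  ), con)
  df <- dplyr::bind_cols(
    tibble::tibble(subject_id = rownames(shapes)),
    tibble::as_tibble(shapes))
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Total shape variance of an aligned set
#'
#' Mean squared deviation of the aligned shapes about the consensus; equals
#' the trace of the coordinate-wise second-moment matrix about the consensus.
#'
#' @param aligned an `aligned_shapes` object.
#' @return A non-negative number.
#' @export
total_shape_variance <- function(aligned) {
  cons <- config_to_vector(aligned$consensus)
  mean(rowSums(sweep(aligned$shapes, 2, cons)^2))
}
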