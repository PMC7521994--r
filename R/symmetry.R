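#' Reflect and relabel a configuration
#'
#' Mirrors a configuration across the x = 0 plane and swaps the labels of
#' bilateral landmark pairs, the elementary operation of object-symmetry
#' analysis.
#'
#' @param coords `k x 3` matrix or length-3k shape vector.
#' @param pairing a [symmetry_pairing()].
#' @return Same type as the input.
#' @export
reflect_relabel <- function(coords, pairing) {
  vec_in <- !is.matrix(coords)
  m <- if (vec_in) vector_to_config(coords) else coords
  if (pairing$k != nrow(m)) {
    stop("pairing index range does not match number of landmarks",
         call. = FALSE)
  }
  m[, 1] <- -m[, 1]
  out <- m
  out[pairing$pairs[, 1], ] <- m[pairing$pairs[, 2], ]
  out[pairing$pairs[, 2], ] <- m[pairing$pairs[, 1], ]
  if (vec_in) config_to_vector(out) else out
}

#' Symmetric/asymmetric decomposition of aligned shapes
#'
#' Object-symmetry decomposition: each configuration and its
#' reflected-relabelled copy are jointly superimposed by GPA; the joint
#' consensus is rotated into a mirror-symmetric frame; the symmetric component
#' of each subject is the average of its aligned original and the
#' reflect-relabelled aligned original, and the asymmetric component is half
#' their difference. `symmetric + asymmetric` reconstructs each aligned shape
#' exactly, and the symmetric component is invariant under reflect-relabel.
#'
#' @param aligned an `aligned_shapes` object (or a [landmark_set()]/`cohort`,
#'   which is aligned first).
#' @param pairing a [symmetry_pairing()].
#' @param tol,max_iter GPA controls for the joint superimposition.
#' @return An object of class `symmetry_decomposition` with `symmetric` and
#'   `asymmetric` shape matrices (`n x 3k`), the symmetrized `consensus`, and
#'   the `pairing`.
#' @export
symmetrize <- function(aligned, pairing, tol = 1e-10, max_iter = 100) {
  if (inherits(aligned, "cohort")) {
    if (is.null(pairing)) pairing <- aligned$pairing
    aligned <- gpa(aligned$landmarks, tol = tol, max_iter = max_iter)
  }
  if (inherits(aligned, "landmark_set")) {
    aligned <- gpa(aligned, tol = tol, max_iter = max_iter)
  }
  stopifnot(inherits(aligned, "aligned_shapes"),
            inherits(pairing, "symmetry_pairing"))
  k <- nrow(aligned$consensus)
  if (pairing$k != k) {
    stop("pairing index range does not match number of landmarks",
         call. = FALSE)
  }
  n <- nrow(aligned$shapes)
  ids <- aligned$subject_id

  # joint GPA of originals and reflected-relabelled copies
  both <- vector("list", 2L * n)
  for (i in seq_len(n)) {
    m <- vector_to_config(aligned$shapes[i, ])
    both[[i]] <- m
    both[[n + i]] <- reflect_relabel(m, pairing)
  }
  joint <- gpa(landmark_set(both, c(ids, paste0(ids, "__refl"))),
               tol = tol, max_iter = max_iter)

  # rotate into a frame where the consensus is exactly mirror-symmetric:
  # the joint consensus satisfies reflect_relabel(C) = C %*% U for a rotation
  # U with (U J)^2 = I, so U J is a symmetric reflection; aligning its -1
  # eigenvector with the x axis makes the frame mirror-symmetric.
  C <- joint$consensus
  M <- reflect_relabel(C, pairing)
  U <- procrustes_rotation(C, M)          # C %*% U ~ M
  J <- diag(c(-1, 1, 1))
  K <- U %*% J
  K <- (K + t(K)) / 2
  eg <- eigen(K, symmetric = TRUE)
  v1 <- eg$vectors[, which.min(eg$values)]
  # complete to a rotation with v1 as the first (mirror-normal) axis
  basis <- qr.Q(qr(cbind(v1, diag(3)[, order(abs(v1))[1:2]])))
  if (det(basis) < 0) basis[, 3] <- -basis[, 3]
  rotate <- function(m) m %*% basis
  C <- rotate(C)

  orig <- joint$shapes[seq_len(n), , drop = FALSE]
  sym <- matrix(NA_real_, n, 3L * k)
  asym <- matrix(NA_real_, n, 3L * k)
  for (i in seq_len(n)) {
    o <- rotate(vector_to_config(orig[i, ]))
    r <- reflect_relabel(o, pairing)
    r <- r %*% procrustes_rotation(r, C)
    o2 <- o %*% procrustes_rotation(o, C)
    sym[i, ] <- config_to_vector((o2 + r) / 2)
    asym[i, ] <- config_to_vector((o2 - r) / 2)
  }
  rownames(sym) <- ids
  rownames(asym) <- ids
  colnames(sym) <- shape_colnames(k)
  colnames(asym) <- shape_colnames(k)
  structure(list(symmetric = sym, asymmetric = asym,
                 consensus = (C + reflect_relabel(C, pairing)) / 2,
                 subject_id = ids, pairing = pairing),
            class = "symmetry_decomposition")
}

#' @export
print.symmetry_decomposition <- function(x, ...) {
  cat("<symmetry_decomposition> ", nrow(x$symmetric), " shapes, ",
      x$pairing$k, " landmarks\n", sep = "")
  invisible(x)
}
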