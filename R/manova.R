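#' Procrustes MANOVA with ordering-averaged sequential sums of squares
#'
#' Variance attribution for shape data. Sequential (type-1) Procrustes sums of
#' squares are computed for every ordering of the model terms and averaged per
#' term, removing the arbitrariness of term entry order in non-orthogonal
#' designs. Significance uses Goodall-style F statistics,
#' `F = (SS_term/df_term) / (SS_res/df_res)`, with p-values from residual
#' randomization: for each term, residuals of the reduced model (all other
#' terms) are permuted, the shapes reassembled, and the term's
#' ordering-averaged F recomputed; `p = (1 + #{F* >= F}) / (1 + n_perm)`.
#'
#' @param shapes `n x p` shape matrix.
#' @param data data frame of covariates (one row per shape row).
#' @param terms character vector of model terms; each is an R formula term
#'   evaluated in `data` (e.g. `"sex"`, `"syndrome"`, `"poly(age, 3)"`).
#' @param n_perm number of residual-randomization permutations (default 999).
#' @param seed integer seed for the permutations.
#' @param max_orderings orderings are enumerated exhaustively up to 6 terms;
#'   beyond that, this many are sampled.
#' @return A tibble of class `procrustes_manova` with columns `term`, `df`,
#'   `SS`, `R2`, `F`, `p`, plus `Residuals` and `Total` rows (`p = NA`).
#' @export
procrustes_manova <- function(shapes, data, terms, n_perm = 999, seed = NULL,
                              max_orderings = 720) {
  stopifnot(nrow(shapes) == nrow(data), length(terms) >= 1, n_perm >= 99)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(shapes)

  blocks <- lapply(terms, term_block, data = data)
  names(blocks) <- terms
  dfs <- vapply(blocks, ncol, integer(1))
  full <- cbind(1, do.call(cbind, blocks))
  qr_full <- qr(full)
  if (qr_full$rank < ncol(full)) {
    # locate an aliased pair for the error message
    culprit <- find_aliased_pair(blocks)
    stop("aliased model terms: ", culprit, call. = FALSE)
  }

  orderings <- term_orderings(length(terms), max_orderings)
  Yc <- sweep(shapes, 2, colMeans(shapes))
  ss_total <- sum(Yc^2)

  avg_ss <- ordering_averaged_ss(shapes, blocks, orderings)
  ss_res <- ss_total - sum(avg_ss)
  df_res <- n - 1L - sum(dfs)
  Fobs <- (avg_ss / dfs) / (ss_res / df_res)

  pvals <- vapply(seq_along(terms), function(j) {
    reduced <- cbind(matrix(1, n, 1), do.call(cbind, blocks[-j]))
    Q <- qr.Q(qr(reduced))
    fitted <- Q %*% crossprod(Q, shapes)
    resid <- shapes - fitted
    count <- 0L
    for (b in seq_len(n_perm)) {
      Yp <- fitted + resid[sample.int(n), , drop = FALSE]
      ss_p <- ordering_averaged_ss(Yp, blocks, orderings)
      ss_res_p <- sum(sweep(Yp, 2, colMeans(Yp))^2) - sum(ss_p)
      Fp <- (ss_p[j] / dfs[j]) / (ss_res_p / df_res)
      if (Fp >= Fobs[j]) count <- count + 1L
    }
    (1 + count) / (1 + n_perm)
  }, numeric(1))

  out <- tibble::tibble(
    term = c(terms, "Residuals", "Total"),
    df = c(dfs, df_res, n - 1L),
    SS = c(avg_ss, ss_res, ss_total),
    R2 = c(avg_ss, ss_res, ss_total) / ss_total,
    F = c(Fobs, NA_real_, NA_real_),
    p = c(pvals, NA_real_, NA_real_)
  )
  attr(out, "n_perm") <- n_perm
  attr(out, "n_orderings") <- nrow(orderings)
  class(out) <- c("procrustes_manova", class(out))
  out
}

term_block <- function(term, data) {
  mm <- stats::model.matrix(stats::reformulate(term), data = data)
  mm[, -1, drop = FALSE]
}

term_orderings <- function(m, max_orderings) {
  if (factorial(m) <= max_orderings) {
    perms <- permutations_of(m)
  } else {
    perms <- t(replicate(max_orderings, sample.int(m)))
  }
  perms
}

permutations_of <- function(m) {
  if (m == 1L) return(matrix(1L, 1, 1))
  sub <- permutations_of(m - 1L)
  out <- matrix(0L, 0, m)
  for (i in seq_len(m)) {
    rest <- matrix(seq_len(m)[-i][sub], nrow(sub))
    out <- rbind(out, cbind(i, rest))
  }
  out
}

# Average, over term orderings, of the sequential SS attributed to each term.
ordering_averaged_ss <- function(Y, blocks, orderings) {
  m <- length(blocks)
  n <- nrow(Y)
  acc <- numeric(m)
  one <- matrix(1 / sqrt(n), n, 1)
  for (r in seq_len(nrow(orderings))) {
    ord <- orderings[r, ]
    Q <- one
    fitted_prev <- crossprod(Q, Y)          # coords in current basis
    ss_prev <- sum(fitted_prev^2)
    for (t in ord) {
      B <- blocks[[t]] - Q %*% crossprod(Q, blocks[[t]])
      qrB <- qr(B)
      Qt <- qr.Q(qrB)[, seq_len(qrB$rank), drop = FALSE]
      ss_t <- sum(crossprod(Qt, Y)^2)
      acc[t] <- acc[t] + ss_t
      Q <- cbind(Q, Qt)
    }
  }
  acc / nrow(orderings)
}

find_aliased_pair <- function(blocks) {
  m <- length(blocks)
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (i == j) next
      combined <- cbind(1, blocks[[i]], blocks[[j]])
      if (qr(combined)$rank < ncol(combined)) {
        return(paste(names(blocks)[c(i, j)], collapse = " and "))
      }
    }
  }
  "unidentified collinear terms"
}

#' @export
tidy.procrustes_manova <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @export
glance.procrustes_manova <- function(x, ...) {
  tibble::tibble(
    total_SS = x$SS[x$term == "Total"],
    residual_SS = x$SS[x$term == "Residuals"],
    n_perm = attr(x, "n_perm"),
    n_orderings = attr(x, "n_orderings")
  )
}
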