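#' Classification metrics from a posterior matrix
#'
#' Per-class sensitivity (proportion of the class's subjects correctly
#' classified), specificity (proportion of other subjects not assigned to the
#' class), balanced accuracy (their average), and top-k hits (true class among
#' the k highest posteriors, ties broken by class label order).
#'
#' @param posteriors `n x g` posterior matrix with class-named columns; the
#'   column set must cover the observed labels.
#' @param true_labels vector of true class labels.
#' @param ks top-k levels to report (default `c(1, 3, 10)`).
#' @return An object of class `classification_report`: per-class metric tibble
#'   (`$by_class`), per-subject predictions and top-k hits (`$by_subject`),
#'   the posterior matrix, and overall means.
#' @export
classification_metrics <- function(posteriors, true_labels, ks = c(1, 3, 10)) {
  true_labels <- as.character(true_labels)
  classes <- colnames(posteriors)
  if (!all(true_labels %in% classes)) {
    stop("posterior columns do not cover observed labels: ",
         setdiff(true_labels, classes)[1], call. = FALSE)
  }
  stopifnot(nrow(posteriors) == length(true_labels))
  n <- nrow(posteriors)
  # rank classes per subject: decreasing posterior, ties by label order
  ord <- t(apply(posteriors, 1, function(p) order(-p, seq_along(p))))
  predicted <- classes[ord[, 1]]
  true_idx <- match(true_labels, classes)
  rank_of_true <- vapply(seq_len(n),
                         function(i) which(ord[i, ] == true_idx[i]),
                         integer(1))
  ks <- sort(unique(pmin(ks, length(classes))))
  topk <- vapply(ks, function(k) rank_of_true <= k, logical(n))
  if (is.null(dim(topk))) topk <- matrix(topk, nrow = n)
  colnames(topk) <- paste0("top", ks)

  by_class <- purrr::map(classes, function(cl) {
    in_cl <- true_labels == cl
    tp <- sum(predicted[in_cl] == cl)
    tn <- sum(predicted[!in_cl] != cl)
    sens <- if (any(in_cl)) tp / sum(in_cl) else NA_real_
    spec <- if (any(!in_cl)) tn / sum(!in_cl) else NA_real_
    row <- tibble::tibble(class = cl, n = sum(in_cl),
                          sensitivity = sens, specificity = spec,
                          balanced_accuracy = (sens + spec) / 2)
    for (j in seq_along(ks)) {
      row[[paste0("top", ks[j], "_sensitivity")]] <-
        if (any(in_cl)) mean(topk[in_cl, j]) else NA_real_
    }
    row
  })
  by_class <- dplyr::bind_rows(by_class)

  by_subject <- tibble::tibble(
    subject_id = rownames(posteriors) %||% as.character(seq_len(n)),
    true = true_labels,
    predicted = predicted
  )
  by_subject <- dplyr::bind_cols(by_subject, tibble::as_tibble(topk))

  structure(list(by_class = by_class, by_subject = by_subject,
                 posterior = posteriors, ks = ks),
            class = "classification_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.classification_report <- function(x, ...) {
  g <- glance(x)
  cat("<classification_report> ", nrow(x$by_subject), " subjects, ",
      nrow(x$by_class), " classes; mean sensitivity ",
      round(100 * g$mean_sensitivity, 1), "%, mean balanced accuracy ",
      round(100 * g$mean_balanced_accuracy, 1), "%\n", sep = "")
  invisible(x)
}

#' @export
tidy.classification_report <- function(x, ...) x$by_class

#' @export
glance.classification_report <- function(x, ...) {
  present <- x$by_class[x$by_class$n > 0, ]
  out <- tibble::tibble(
    n = nrow(x$by_subject),
    n_classes = nrow(present),
    accuracy = mean(x$by_subject$true == x$by_subject$predicted),
    mean_sensitivity = mean(present$sensitivity),
    mean_specificity = mean(present$specificity),
    mean_balanced_accuracy = mean(present$balanced_accuracy)
  )
  for (k in x$ks) {
    out[[paste0("mean_top", k, "_sensitivity")]] <-
      mean(present[[paste0("top", k, "_sensitivity")]])
  }
  out
}

#' Cross-validated classification
#'
#' Family-level leave-one-out cross-validation holds out one family at a time
#' (subjects without a `family_id` form singleton families), so a family is
#' never split between training and test. Stratified k-fold is provided for
#' comparison. Relatives (`diagnosis_status == "relative"`) are excluded from
#' all training sets and from the report. Per-subject posteriors come from the
#' fold in which the subject was held out.
#'
#' @param shapes standardized shape matrix, rows named by subject.
#' @param meta metadata tibble aligned with `shapes` rows (needs `subject_id`,
#'   `syndrome`, `diagnosis_status`; `family_id` for the family scheme).
#' @param method `"hdrda"` or `"cva"`.
#' @param params [hdrda_params()] for HDRDA.
#' @param scheme `"family"` (family-level LOOCV) or `"kfold"`.
#' @param k number of folds for `"kfold"` (default 20).
#' @param seed integer seed for fold assignment.
#' @param retained_fraction PCA variance retained for CVA.
#' @param ks top-k levels.
#' @return A `classification_report` over all held-out subjects.
#' @export
crossvalidate <- function(shapes, meta, method = c("hdrda", "cva"),
                          params = hdrda_params(), scheme = c("family", "kfold"),
                          k = 20, seed = 1, retained_fraction = 0.99,
                          ks = c(1, 3, 10)) {
  method <- match.arg(method)
  scheme <- match.arg(scheme)
  keep <- meta$diagnosis_status != "relative"
  meta <- meta[keep, ]
  shapes <- shapes[keep, , drop = FALSE]
  rownames(shapes) <- meta$subject_id
  n <- nrow(shapes)
  labels <- meta$syndrome
  classes <- sort(unique(labels))

  folds <- make_folds(meta, scheme, k, seed)
  post <- matrix(NA_real_, n, length(classes),
                 dimnames = list(meta$subject_id, classes))
  warned <- FALSE
  for (f in unique(folds)) {
    test_idx <- which(folds == f)
    train_idx <- setdiff(seq_len(n), test_idx)
    train_lab <- labels[train_idx]
    present <- sort(unique(train_lab))
    ok <- table(train_lab) >= 2
    present <- present[ok[present]]
    lost <- setdiff(classes, present)
    if (length(lost) && !warned && any(labels[test_idx] %in% lost)) {
      warning("some folds lose an entire class from training; ",
              "affected classes get posterior 0 in those folds",
              call. = FALSE)
      warned <- TRUE
    }
    use <- train_idx[train_lab %in% present]
    model <- if (method == "hdrda") {
      fit_hdrda(shapes[use, , drop = FALSE], labels[use], params = params)
    } else {
      fit_cva(shapes[use, , drop = FALSE], labels[use],
              retained_fraction = retained_fraction)
    }
    pp <- predict_posteriors(model, shapes[test_idx, , drop = FALSE])
    full <- matrix(0, length(test_idx), length(classes),
                   dimnames = list(NULL, classes))
    full[, colnames(pp)] <- pp
    post[test_idx, ] <- full
  }
  classification_metrics(post, labels, ks = ks)
}

make_folds <- function(meta, scheme, k, seed) {
  n <- nrow(meta)
  if (scheme == "family") {
    fam <- meta[["family_id"]]
    if (is.null(fam)) fam <- rep(NA_character_, n)
    fam[is.na(fam)] <- paste0(".singleton_", seq_len(n))[is.na(fam)]
    return(match(fam, unique(fam)))
  }
  set.seed(seed)
  folds <- integer(n)
  for (cl in unique(meta$syndrome)) {
    idx <- which(meta$syndrome == cl)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

#' Tune HDRDA hyperparameters on a grid
#'
#' Maximizes cross-validated mean balanced accuracy over a (lambda, gamma)
#' grid; ties go to larger lambda, then larger gamma (more regularization).
#'
#' @param shapes,meta,scheme,k,seed as in [crossvalidate()].
#' @param grid data frame with columns `lambda` and `gamma`; default
#'   `lambda in {0, .25, .5, .75, 1}` crossed with
#'   `gamma in {1e-4, 1e-3, 1e-2, 1e-1, 1} x mean pooled variance`.
#' @return The selected [hdrda_params()], with the full results table as
#'   attribute `"grid"`.
#' @export
tune_hyperparameters <- function(shapes, meta, grid = NULL,
                                 scheme = "kfold", k = 5, seed = 1) {
  if (is.null(grid)) {
    # gamma values are in units of the mean pooled variance (see
    # hdrda_params(gamma_relative = TRUE))
    grid <- expand.grid(lambda = c(0, 0.25, 0.5, 0.75, 1),
                        gamma = c(1e-4, 1e-3, 1e-2, 1e-1, 1))
  }
  if (nrow(grid) == 0L) stop("empty hyperparameter grid", call. = FALSE)
  res <- purrr::map_dbl(seq_len(nrow(grid)), function(i) {
    rep <- crossvalidate(shapes, meta, method = "hdrda",
                         params = hdrda_params(grid$lambda[i], grid$gamma[i]),
                         scheme = scheme, k = k, seed = seed)
    glance(rep)$mean_balanced_accuracy
  })
  tab <- tibble::as_tibble(grid)
  tab$balanced_accuracy <- res
  best <- tab[order(-tab$balanced_accuracy, -tab$lambda, -tab$gamma), ][1, ]
  out <- hdrda_params(best$lambda, best$gamma)
  attr(out, "grid") <- tab
  out
}
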