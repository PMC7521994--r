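#' Classify unaffected relatives with family-excluded models
#'
#' For each family containing at least one relative, an HDRDA model is fitted
#' on all syndromic and unrelated, unaffected subjects *minus* that family's
#' syndromic members; relatives are never part of any training set. Each
#' relative is then classified by its family-excluded model. Reports, per
#' relative, the predicted class, whether the family syndrome appears among
#' the top-10 posteriors, and phenotypic extremeness (Procrustes distance to
#' the unaffected mean); per syndrome, the fraction classified unaffected and
#' the top-10 match rate; and the cohort-level tests of
#' [extremeness_tests()] when severities and an unrelated-unaffected
#' comparison rate are supplied.
#'
#' @param shapes standardized shape matrix, rows named by subject.
#' @param meta metadata tibble aligned with `shapes` (relatives carry their
#'   affected family member's syndrome label and
#'   `diagnosis_status == "relative"`).
#' @param params [hdrda_params()] for the classifier.
#' @param min_n minimum syndrome size; relatives whose family syndrome fails
#'   the filter are excluded with a message.
#' @param unaffected_rate optional proportion of unrelated, unaffected
#'   subjects classified unaffected in the main cross-validated analysis,
#'   with `unaffected_n` its denominator; enables the chi-square comparison.
#' @param unaffected_n see `unaffected_rate`.
#' @param severities optional tibble with columns `syndrome` and `severity`
#'   (e.g. from [syndrome_stats()]); enables the extremeness regression.
#' @return An object of class `relative_report` with `$by_relative`,
#'   `$by_syndrome` tibbles and `$tests` (see [extremeness_tests()]).
#' @export
classify_relatives <- function(shapes, meta, params = hdrda_params(),
                               min_n = 10, unaffected_rate = NULL,
                               unaffected_n = NULL, severities = NULL) {
  rownames(shapes) <- meta$subject_id
  is_rel <- meta$diagnosis_status == "relative"
  if (!any(is_rel)) stop("cohort contains no relatives", call. = FALSE)
  core <- !is_rel
  syn_counts <- table(meta$syndrome[core & meta$syndrome != "unaffected"])
  ok_syn <- names(syn_counts)[syn_counts >= min_n]

  rel_idx <- which(is_rel)
  fam_ok <- meta$syndrome[rel_idx] %in% ok_syn
  if (any(!fam_ok)) {
    message("classify_relatives: excluding ", sum(!fam_ok),
            " relative(s) whose family syndrome fails the min-n filter")
  }
  rel_idx <- rel_idx[fam_ok]
  if (length(rel_idx) == 0L) {
    stop("no relative has a family syndrome passing the min-n filter",
         call. = FALSE)
  }

  train_pool <- which(core &
                        (meta$syndrome == "unaffected" |
                           meta$syndrome %in% ok_syn))
  unaff_mean <- colMeans(
    shapes[core & meta$syndrome == "unaffected", , drop = FALSE])

  rows <- purrr::map(split(rel_idx, meta$family_id[rel_idx]), function(idx) {
    fam <- meta$family_id[idx[1]]
    drop_ids <- meta$subject_id[core & !is.na(meta$family_id) &
                                  meta$family_id == fam &
                                  meta$syndrome != "unaffected"]
    use <- train_pool[!(meta$subject_id[train_pool] %in% drop_ids)]
    model <- fit_hdrda(shapes[use, , drop = FALSE], meta$syndrome[use],
                       params = params)
    post <- predict_posteriors(model, shapes[idx, , drop = FALSE])
    classes <- colnames(post)
    ord <- t(apply(post, 1, function(p) order(-p, seq_along(p))))
    top10 <- matrix(classes[ord[, seq_len(min(10, ncol(post)))]],
                    nrow = nrow(post))
    tibble::tibble(
      subject_id = meta$subject_id[idx],
      family_id = fam,
      family_syndrome = meta$syndrome[idx],
      predicted = classes[ord[, 1]],
      posterior_unaffected = post[, "unaffected"],
      classified_unaffected = classes[ord[, 1]] == "unaffected",
      top10_contains_family_syndrome =
        vapply(seq_len(nrow(post)),
               function(i) meta$syndrome[idx[i]] %in% top10[i, ], logical(1)),
      extremeness = tangent_distances(shapes[idx, , drop = FALSE], unaff_mean)
    )
  })
  by_relative <- dplyr::bind_rows(rows)

  by_syndrome <- by_relative |>
    dplyr::group_by(.data$family_syndrome) |>
    dplyr::summarise(
      n_relatives = dplyr::n(),
      fraction_classified_unaffected = mean(.data$classified_unaffected),
      top10_match_rate = mean(.data$top10_contains_family_syndrome),
      mean_extremeness = mean(.data$extremeness),
      .groups = "drop"
    )

  tests <- NULL
  if (!is.null(severities) || !is.null(unaffected_rate)) {
    sev <- NULL
    if (!is.null(severities)) {
      sev <- severities$severity[match(by_relative$family_syndrome,
                                       severities$syndrome)]
    }
    tab <- NULL
    if (!is.null(unaffected_rate)) {
      stopifnot(!is.null(unaffected_n))
      tab <- rbind(
        relatives = c(sum(by_relative$classified_unaffected),
                      sum(!by_relative$classified_unaffected)),
        unrelated = c(round(unaffected_rate * unaffected_n),
                      round((1 - unaffected_rate) * unaffected_n))
      )
      colnames(tab) <- c("unaffected", "not_unaffected")
    }
    tests <- extremeness_tests(by_relative$extremeness,
                               by_relative$family_syndrome,
                               severities = sev, table_2x2 = tab)
  }

  structure(list(by_relative = by_relative, by_syndrome = by_syndrome,
                 tests = tests),
            class = "relative_report")
}

#' @export
print.relative_report <- function(x, ...) {
  cat("<relative_report> ", nrow(x$by_relative), " relatives from ",
      nrow(x$by_syndrome), " syndromes; ",
      round(100 * mean(x$by_relative$classified_unaffected), 1),
      "% classified unaffected\n", sep = "")
  invisible(x)
}

#' @export
tidy.relative_report <- function(x, ...) x$by_syndrome

#' @export
glance.relative_report <- function(x, ...) {
  tibble::tibble(
    n_relatives = nrow(x$by_relative),
    n_syndromes = nrow(x$by_syndrome),
    fraction_classified_unaffected = mean(x$by_relative$classified_unaffected),
    top10_match_rate = mean(x$by_relative$top10_contains_family_syndrome),
    mean_extremeness = mean(x$by_relative$extremeness)
  )
}

#' Phenotypic extremeness of relatives
#'
#' Procrustes distance of each (standardized) relative shape to the
#' unrelated-unaffected mean shape.
#'
#' @param shapes shape matrix of relatives.
#' @param unaffected_mean mean unaffected shape vector.
#' @return Numeric vector of distances.
#' @export
relative_extremeness <- function(shapes, unaffected_mean) {
  if (is.null(dim(shapes))) shapes <- matrix(shapes, nrow = 1)
  tangent_distances(shapes, unaffected_mean)
}

#' Cohort-level tests on relative extremeness
#'
#' Brown-Forsythe (median-centred) Levene test of extremeness across family
#' syndromes; OLS regression of extremeness on the family syndrome's
#' phenotypic severity (reporting the model mean square and F); and a Pearson
#' chi-square (no continuity correction) on the 2x2 classified-unaffected
#' table of relatives versus unrelated unaffecteds.
#'
#' @param extremeness numeric vector of relative extremeness values.
#' @param groups family syndrome of each relative.
#' @param severities severity of each relative's family syndrome (same
#'   length), or `NULL` to skip the regression.
#' @param table_2x2 2x2 count matrix (rows: relatives/unrelated; columns:
#'   classified unaffected / not), or `NULL` to skip the chi-square.
#' @param center `"median"` (Brown-Forsythe, default) or `"mean"` for the
#'   Levene test.
#' @param correct logical; apply Yates continuity correction (default FALSE).
#' @return A list with elements `levene` (df, F, p), `regression`
#'   (MS, F, p, slope), `chi_square` (statistic, p).
#' @export
extremeness_tests <- function(extremeness, groups, severities = NULL,
                              table_2x2 = NULL,
                              center = c("median", "mean"), correct = FALSE) {
  center <- match.arg(center)
  groups <- as.character(groups)
  sizes <- table(groups)
  singletons <- names(sizes)[sizes < 2]
  if (length(singletons)) {
    warning("dropping ", length(singletons),
            " syndrome group(s) of size 1 from the Levene test",
            call. = FALSE)
  }
  keep <- !(groups %in% singletons)
  levene <- NULL
  if (length(unique(groups[keep])) >= 2) {
    lt <- car::leveneTest(extremeness[keep], factor(groups[keep]),
                          center = if (center == "median") median else mean)
    levene <- list(df = unname(lt$Df[1]), df_resid = unname(lt$Df[2]),
                   F = lt$`F value`[1], p = lt$`Pr(>F)`[1])
  }

  regression <- NULL
  if (!is.null(severities)) {
    fit <- lm(extremeness ~ severities)
    a <- stats::anova(fit)
    regression <- list(MS = a$`Mean Sq`[1], F = a$`F value`[1],
                       p = a$`Pr(>F)`[1], slope = unname(coef(fit)[2]))
  }

  chi_square <- NULL
  if (!is.null(table_2x2)) {
    ct <- suppressWarnings(chisq.test(table_2x2, correct = correct))
    chi_square <- list(statistic = unname(ct$statistic),
                       p = unname(ct$p.value))
  }

  list(levene = levene, regression = regression, chi_square = chi_square)
}
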