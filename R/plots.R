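#' @export
autoplot.classification_report <- function(object, ...) {
  df <- tidy(object)
  long <- tidyr::pivot_longer(
    df, dplyr::all_of(c("sensitivity", "balanced_accuracy")),
    names_to = "metric", values_to = "value")
  ggplot2::ggplot(long,
                  ggplot2::aes(x = stats::reorder(.data$class, .data$value),
                               y = .data$value, fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "rate", fill = NULL,
                  title = "Per-class classification performance") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.procrustes_manova <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df <- df[!df$term %in% c("Total"), ]
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$term, .data$R2),
                                   y = .data$R2)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = expression(R^2),
                  title = "Shape variance attribution") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.outlier_report <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$distance_to_mean,
                               y = .data$landmark_deviation_variance,
                               colour = .data$flag)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "Procrustes distance to mean",
                  y = "landmark deviation variance",
                  colour = "flagged",
                  title = "Outlier screening") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.relative_report <- function(object, ...) {
  ggplot2::ggplot(object$by_syndrome,
                  ggplot2::aes(x = stats::reorder(.data$family_syndrome,
                                                  .data$mean_extremeness),
                               y = .data$mean_extremeness)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "mean phenotypic extremeness",
                  title = "Relative extremeness by family syndrome") +
    ggplot2::theme_minimal()
}

#' Age regression score plot
#'
#' Scatter of the polynomial age regression score against age, optionally
#' coloured by group.
#'
#' @param model an [fit_age_sex_model()] fit.
#' @param shapes shape matrix.
#' @param age ages for the rows of `shapes`.
#' @param group optional grouping vector.
#' @return A ggplot object.
#' @export
plot_age_score <- function(model, shapes, age, group = NULL) {
  df <- tibble::tibble(age = age,
                       score = age_regression_score(model, shapes),
                       group = if (is.null(group)) "all" else group)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$age, y = .data$score,
                                   colour = .data$group)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "age (years)", y = "age regression score") +
    ggplot2::theme_minimal()
}
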