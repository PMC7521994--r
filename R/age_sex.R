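#' Fit the age and sex standardization model
#'
#' Multivariate least-squares regression of shape on an orthogonal cubic
#' polynomial in age plus a centred sex contrast (female = -1/2,
#' male = +1/2), so the intercept row is the balanced-sex mean at the mean
#' age. Classification analyses consume the residuals of this model.
#'
#' @param shapes `n x 3k` shape matrix (rows named by subject).
#' @param age numeric vector of ages in years.
#' @param sex character vector (`"female"`/`"male"`) or numeric contrast.
#' @return An object of class `age_sex_model`: `coefficients` (5 x 3k:
#'   intercept, age^1..age^3, sex), the orthogonal polynomial `basis`
#'   attributes, the training `consensus_shape`, the fitted `age_axis`
#'   direction, and the training age range.
#' @export
fit_age_sex_model <- function(shapes, age, sex) {
  n <- nrow(shapes)
  stopifnot(length(age) == n, length(sex) == n)
  if (n <= 6) stop("need n > 6 subjects to fit a cubic age + sex model",
                   call. = FALSE)
  if (!all(is.finite(age))) stop("age must be finite", call. = FALSE)
  if (length(unique(age)) < 4) {
    stop("age vector is (nearly) constant: cubic polynomial basis is degenerate",
         call. = FALSE)
  }
  sexc <- code_sex(sex)
  pb <- poly(age, 3)
  X <- cbind(intercept = 1, pb, sex = sexc)
  fit <- stats::lm.fit(X, shapes)
  coefs <- fit$coefficients
  rownames(coefs) <- c("intercept", "age1", "age2", "age3", "sex")

  # direction of maximal age-fitted shape variance; used for regression scores
  age_fit <- pb %*% coefs[2:4, , drop = FALSE]
  sv <- svd(age_fit, nu = 0, nv = 1)
  axis <- sv$v[, 1]
  pred_hi <- predict_poly(pb, max(age)) %*% coefs[2:4, , drop = FALSE]
  pred_lo <- predict_poly(pb, min(age)) %*% coefs[2:4, , drop = FALSE]
  if (sum((pred_hi - pred_lo) * axis) < 0) axis <- -axis

  structure(list(coefficients = coefs,
                 basis = list(coefs = attr(pb, "coefs")),
                 consensus_shape = colMeans(shapes),
                 age_axis = axis,
                 age_range = range(age)),
            class = "age_sex_model")
}

code_sex <- function(sex) {
  if (is.numeric(sex)) return(sex - mean(range(sex)))
  lev <- c("female", "male")
  if (!all(sex %in% lev)) stop("sex must be 'female' or 'male'", call. = FALSE)
  ifelse(sex == "male", 0.5, -0.5)
}

predict_poly <- function(pb, age) {
  poly(age, 3, coefs = attr(pb, "coefs"))
}

model_matrix_age_sex <- function(model, age, sex) {
  pb <- poly(age, 3, coefs = model$basis$coefs)
  cbind(1, pb, code_sex(sex))
}

#' Remove age and sex effects from shapes
#'
#' Returns the model residuals plus the training consensus shape, so output
#' rows remain interpretable as shapes. Refitting the model on the output
#' yields age/sex sums of squares near zero.
#'
#' @param model an [fit_age_sex_model()] fit.
#' @param shapes `n x 3k` shape matrix.
#' @param age,sex covariates for these rows.
#' @return Standardized shape matrix of the same dimensions.
#' @export
standardize <- function(model, shapes, age, sex) {
  stopifnot(inherits(model, "age_sex_model"))
  out_of_range <- age < model$age_range[1] | age > model$age_range[2]
  if (any(out_of_range)) {
    warning(sum(out_of_range),
            " subject(s) outside the fitted age range; extrapolating",
            call. = FALSE)
  }
  X <- model_matrix_age_sex(model, age, sex)
  fitted <- X %*% model$coefficients
  res <- shapes - fitted
  out <- sweep(res, 2, model$consensus_shape, "+")
  rownames(out) <- rownames(shapes)
  out
}

#' Polynomial age regression score
#'
#' Projects each shape (centred on the training consensus) onto the direction
#' of maximal age-fitted shape variation, oriented so the score increases with
#' predicted age. For noiseless linear growth the score correlates perfectly
#' with age.
#'
#' @param model an [fit_age_sex_model()] fit.
#' @param shapes `n x 3k` shape matrix.
#' @return Numeric vector of scores, one per row.
#' @export
age_regression_score <- function(model, shapes) {
  stopifnot(inherits(model, "age_sex_model"))
  drop(sweep(shapes, 2, model$consensus_shape) %*% model$age_axis)
}

#' @export
tidy.age_sex_model <- function(x, ...) {
  tibble::tibble(
    term = rownames(x$coefficients),
    norm = sqrt(rowSums(x$coefficients^2))
  )
}

#' @export
glance.age_sex_model <- function(x, ...) {
  tibble::tibble(
    n_coefficients = nrow(x$coefficients),
    p = ncol(x$coefficients),
    age_min = x$age_range[1],
    age_max = x$age_range[2]
  )
}
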