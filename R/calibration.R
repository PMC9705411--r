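#' Fit a ridge-multinomial calibration model on out-of-fold scores
#'
#' Maps raw classifier scores to calibrated probabilities with
#' ridge-penalized multinomial logistic regression, fitted on the
#' out-of-fold scores of the winning cross-validation configuration (never
#' resubstitution scores, which would make the calibration overconfident).
#' The penalty is chosen as the lambda with minimum mean cross-validated
#' multinomial deviance over a descending 100-value path auto-scaled from
#' the data. The symmetric multinomial parameterization (one ridge-penalized
#' coefficient vector per class, no reference class) makes the fit
#' equivariant under permuting class columns and labels together.
#'
#' @param oof_scores Samples x classes matrix of out-of-fold scores (the
#'   `oof_scores` element of a `cv_result`).
#' @param labels True class labels, one per row.
#' @param lambda Optional descending lambda path (default: auto path).
#' @param nfolds Internal CV folds (default 10).
#' @param seed Integer seed for the internal fold split.
#' @return A `calibration_model`: list with `coefficients` (score-space x
#'   class matrix), `intercepts`, `lambda`, `classes`, and the underlying
#'   `glmnet_fit`.
#' @export
fit_calibration <- function(oof_scores, labels, lambda = NULL, nfolds = 10,
                            seed = 42L) {
  x <- as.matrix(oof_scores)
  labels <- as.character(labels)
  classes <- colnames(x)
  absent <- setdiff(classes, labels)
  if (length(absent) > 0) {
    stop("class absent from labels: ", paste(absent, collapse = ", "),
      call. = FALSE
    )
  }
  y <- factor(labels, levels = classes)
  cvfit <- withr::with_seed(seed, glmnet::cv.glmnet(
    x, y,
    family = "multinomial", alpha = 0, nfolds = nfolds,
    lambda = lambda, type.measure = "deviance"
  ))
  new_calibration_model(
    coefficients = .glmnet_coef_matrix(cvfit, classes, s = cvfit$lambda.min),
    intercepts = .glmnet_intercepts(cvfit, classes, s = cvfit$lambda.min),
    classes = classes,
    lambda = cvfit$lambda.min,
    glmnet_fit = cvfit
  )
}

#' @rdname fit_calibration
#' @param coefficients Numeric matrix (score columns x classes) of logit
#'   coefficients.
#' @param intercepts Named numeric vector of per-class intercepts.
#' @param classes Ordered class names.
#' @param glmnet_fit Optional underlying `cv.glmnet` fit.
#' @export
new_calibration_model <- function(coefficients, intercepts, classes,
                                  lambda = NA_real_, glmnet_fit = NULL) {
  stopifnot(
    ncol(coefficients) == length(classes),
    length(intercepts) == length(classes)
  )
  structure(
    list(
      coefficients = coefficients, intercepts = intercepts,
      classes = classes, lambda = lambda, glmnet_fit = glmnet_fit
    ),
    class = "calibration_model"
  )
}

.glmnet_coef_matrix <- function(fit, classes, s) {
  co <- glmnet::coef.glmnet(fit, s = s)
  vapply(
    classes, function(cl) as.numeric(co[[cl]])[-1],
    numeric(nrow(co[[1]]) - 1)
  )
}

.glmnet_intercepts <- function(fit, classes, s) {
  co <- glmnet::coef.glmnet(fit, s = s)
  vapply(classes, function(cl) as.numeric(co[[cl]])[1], numeric(1))
}

#' Apply a calibration model to raw scores
#'
#' Computes the softmax of the affine map defined by the calibration
#' coefficients: `P = softmax(raw %*% B + b)`, row-normalized so every row
#' sums to 1.
#'
#' @param model A `calibration_model`.
#' @param raw Samples x classes matrix of raw scores; columns must match
#'   the model's class order.
#' @return A samples x classes matrix of calibrated probabilities.
#' @export
calibrate <- function(model, raw) {
  raw <- as.matrix(raw)
  if (!identical(colnames(raw), model$classes)) {
    if (is.null(colnames(raw)) || !setequal(colnames(raw), model$classes)) {
      stop("raw score columns do not match calibration classes", call. = FALSE)
    }
    raw <- raw[, model$classes, drop = FALSE]
  }
  logits <- raw %*% model$coefficients +
    matrix(model$intercepts, nrow(raw), length(model$classes), byrow = TRUE)
  logits <- logits - apply(logits, 1, max) # overflow-safe softmax
  p <- exp(logits)
  p <- p / rowSums(p)
  dimnames(p) <- list(rownames(raw), model$classes)
  p
}

#' Final class call from calibrated probabilities
#'
#' Takes the argmax class per row; exact ties are broken by class order
#' (with a warning), so the outlier class -- always last in the canonical
#' order -- never wins a tie against a substantive class.
#'
#' @param calibrated Samples x classes probability matrix from
#'   [calibrate()].
#' @return A tibble with `sample_id`, `label`, `probability`.
#' @export
predict_class <- function(calibrated) {
  p <- as.matrix(calibrated)
  if (nrow(p) == 0) stop("empty score matrix", call. = FALSE)
  idx <- apply(p, 1, which.max) # first of tied maxima
  n_tied <- apply(p, 1, function(r) sum(r == max(r)))
  if (any(n_tied > 1)) {
    warning(sum(n_tied > 1), " tie(s) broken by class order", call. = FALSE)
  }
  tibble::tibble(
    sample_id = if (is.null(rownames(p))) as.character(seq_len(nrow(p))) else rownames(p),
    label = colnames(p)[idx],
    probability = p[cbind(seq_len(nrow(p)), idx)]
  )
}

#' @export
print.calibration_model <- function(x, ...) {
  cat("<calibration_model> ", length(x$classes), " classes, lambda = ",
    signif(x$lambda, 4), "\n",
    sep = ""
  )
  invisible(x)
}
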