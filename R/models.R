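# Model-family wrappers. SVMs come from e1071 (libsvm): per-class scores
# are one-vs-one decision values converted to probabilities by Platt
# scaling with pairwise coupling, so rows sum to 1 up to coupling
# tolerance. Random forests come from randomForest: scores are tree-vote
# fractions, which sum to 1 exactly.

fit_model <- function(X, y, params, classes, seed = 42L) {
  y <- factor(as.character(y), levels = classes)
  params <- as.list(params)
  fit <- withr::with_seed(seed, {
    if (params$family == "svm") {
      if (identical(params$kernel, "linear")) {
        e1071::svm(
          x = X, y = y, kernel = "linear", cost = params$cost,
          probability = TRUE, scale = FALSE
        )
      } else {
        e1071::svm(
          x = X, y = y, kernel = "radial", cost = params$cost,
          gamma = params$gamma, probability = TRUE, scale = FALSE
        )
      }
    } else if (params$family == "rf") {
      randomForest::randomForest(
        x = X, y = y, ntree = params$ntree,
        mtry = min(params$mtry, ncol(X))
      )
    } else {
      stop("unknown model family: ", params$family, call. = FALSE)
    }
  })
  structure(list(fit = fit, family = params$family, params = params),
    class = "methclass_fit"
  )
}

predict_model_scores <- function(model, X, classes) {
  if (model$family == "svm") {
    pred <- stats::predict(model$fit, X, probability = TRUE)
    p <- attr(pred, "probabilities")
  } else {
    p <- stats::predict(model$fit, X, type = "prob")
  }
  missing <- setdiff(classes, colnames(p))
  if (length(missing) > 0) {
    stop("score columns missing classes: ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  p <- p[, classes, drop = FALSE]
  rownames(p) <- rownames(X)
  p
}

#' Train the final model on the full training set
#'
#' Re-selects the top variant probes on the complete training set and
#' refits the winning hyperparameter combination from
#' [cv_grid_search()], with per-class score output enabled.
#'
#' @param ts A `training_set`.
#' @param winner One-row tibble of winning hyperparameters (the `winner`
#'   element of a `cv_result`).
#' @param k_features Number of variant probes to select.
#' @param seed Integer seed for the model fit.
#' @return A `methyl_model`: list with `family`, `params`, `fit`,
#'   `feature_set`, `classes`.
#' @export
train_final <- function(ts, winner, k_features = 20000, seed = 42L) {
  classes <- class_order(ts$sheet$label)
  fs <- select_top_variant(ts$beta, k = k_features)
  X <- t(project_features(ts$beta, fs)$values)
  fit <- fit_model(X, ts$sheet$label, winner, classes = classes, seed = seed)
  structure(
    list(
      family = fit$family, params = fit$params, fit = fit,
      feature_set = fs, classes = classes
    ),
    class = "methyl_model"
  )
}

#' Raw per-class scores for new samples
#'
#' Projects new samples onto the model's frozen feature list and returns
#' the model's per-class scores (SVM: Platt/pairwise-coupled
#' probabilities; RF: tree-vote fractions).
#'
#' @param model A `methyl_model` from [train_final()], or a
#'   `methyl_classifier`.
#' @param bm A [beta_matrix()] containing all model probes.
#' @return A samples x classes numeric matrix.
#' @export
predict_scores <- function(model, bm) {
  if (inherits(model, "methyl_classifier")) model <- model$model
  X <- t(project_features(bm, model$feature_set)$values)
  predict_model_scores(model$fit, X, classes = model$classes)
}

#' Train, calibrate and package a classifier end to end
#'
#' Convenience wrapper over the full supervised stage: grid-search
#' cross-validation under the class-balanced loss, final refit on all
#' samples with the winning hyperparameters, and ridge-multinomial
#' calibration fitted on the winner's out-of-fold scores.
#'
#' @inheritParams cv_grid_search
#' @param calibration_folds Internal CV folds for the ridge penalty path.
#' @return A `methyl_classifier`: list with `model` ([train_final()]
#'   output), `calibration` ([fit_calibration()] output), `cv`
#'   (`cv_result`), `classes`, and `schema_version`.
#' @export
build_classifier <- function(ts, grid = hyperparam_grid("svm"),
                             k_features = 20000, folds = 5,
                             calibration_folds = 10, seed = 42L) {
  cv <- cv_grid_search(ts, grid,
    k_features = k_features, folds = folds,
    seed = seed
  )
  model <- train_final(ts, cv$winner, k_features = k_features, seed = seed)
  calibration <- fit_calibration(cv$oof_scores, ts$sheet$label,
    nfolds = calibration_folds, seed = seed
  )
  structure(
    list(
      model = model, calibration = calibration, cv = cv,
      classes = model$classes, schema_version = 1L
    ),
    class = "methyl_classifier"
  )
}

#' Predict calibrated class probabilities for new samples
#'
#' @param object A `methyl_classifier` from [build_classifier()].
#' @param bm A [beta_matrix()] of new samples.
#' @param ... Unused.
#' @return A tibble with `sample_id`, one probability column per class
#'   (rows sum to 1), `label` (argmax class) and `probability` (its
#'   calibrated score).
#' @export
predict.methyl_classifier <- function(object, bm, ...) {
  raw <- predict_scores(object$model, bm)
  cal <- calibrate(object$calibration, raw)
  pred <- predict_class(cal)
  dplyr::bind_cols(
    tibble::tibble(sample_id = rownames(raw)),
    tibble::as_tibble(cal),
    pred[, c("label", "probability")]
  )
}

#' @export
print.methyl_classifier <- function(x, ...) {
  cat("<methyl_classifier> family=", x$model$family, ", ",
    length(x$classes), " classes (",
    paste(x$classes, collapse = ", "), ")\n",
    sep = ""
  )
  cat(nrow(x$model$feature_set), "features; schema", x$schema_version, "\n")
  invisible(x)
}
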