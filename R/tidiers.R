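#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the per-iteration correlations of a stability report
#'
#' @param x A `stability_report` from [stability_downsample()].
#' @param ... Unused.
#' @return A tibble `iteration`, `r`.
#' @export
tidy.stability_report <- function(x, ...) {
  tibble::tibble(
    iteration = seq_along(x$per_iteration_r),
    r = x$per_iteration_r
  )
}

#' @rdname tidy.stability_report
#' @export
glance.stability_report <- function(x, ...) {
  tibble::tibble(
    n_iterations = x$n_iterations,
    fraction = x$fraction,
    median_r = x$median_r,
    min_r = x$range_r[1],
    max_r = x$range_r[2]
  )
}

#' Tidy the grid-search leaderboard of a cross-validation result
#'
#' @param x A `cv_result` from [cv_grid_search()].
#' @param ... Unused.
#' @return The leaderboard tibble (one row per grid point, with
#'   `mean_loss`), sorted by loss.
#' @export
tidy.cv_result <- function(x, ...) {
  dplyr::arrange(x$leaderboard, .data$mean_loss)
}

#' @rdname tidy.cv_result
#' @export
glance.cv_result <- function(x, ...) {
  dplyr::mutate(x$winner,
    n_grid = nrow(x$leaderboard),
    n_folds = max(x$folds$fold),
    n_samples = nrow(x$folds),
    k_features = x$k_features
  )
}

#' Tidy a calibration model into per-class coefficients
#'
#' @param x A `calibration_model` from [fit_calibration()].
#' @param ... Unused.
#' @return A tibble `class`, `term`, `estimate` (terms are the raw-score
#'   columns plus `(Intercept)`).
#' @export
tidy.calibration_model <- function(x, ...) {
  co <- rbind(`(Intercept)` = x$intercepts, x$coefficients)
  rownames(co)[-1] <- paste0("score_", x$classes)
  tibble::as_tibble(co, rownames = "term") |>
    tidyr::pivot_longer(-"term", names_to = "class", values_to = "estimate") |>
    dplyr::arrange(.data$class, .data$term)
}

#' @rdname tidy.calibration_model
#' @export
glance.calibration_model <- function(x, ...) {
  tibble::tibble(lambda = x$lambda, n_classes = length(x$classes))
}

#' Tidy an evaluation report
#'
#' @param x An `evaluation_report` from [evaluation_report()].
#' @param ... Unused.
#' @return The per-category specificity tibble.
#' @export
tidy.evaluation_report <- function(x, ...) {
  x$per_category
}

#' @rdname tidy.evaluation_report
#' @export
glance.evaluation_report <- function(x, ...) {
  tibble::tibble(
    sensitivity = x$outlier$sensitivity,
    specificity = x$outlier$specificity,
    conditional_accuracy = x$conditional_accuracy,
    auc = x$auc
  )
}

#' Tidy a trained classifier into its frozen feature list
#'
#' @param x A `methyl_classifier` from [build_classifier()].
#' @param ... Unused.
#' @return The feature-set tibble (`probe_id`, `variance`).
#' @export
tidy.methyl_classifier <- function(x, ...) {
  tibble::as_tibble(x$model$feature_set[c("probe_id", "variance")])
}

#' @rdname tidy.methyl_classifier
#' @export
glance.methyl_classifier <- function(x, ...) {
  dplyr::mutate(x$cv$winner,
    n_classes = length(x$classes),
    n_features = nrow(x$model$feature_set),
    lambda = x$calibration$lambda,
    schema_version = x$schema_version
  )
}
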