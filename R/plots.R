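#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a t-SNE embedding, optionally colored by cluster or class
#'
#' @param object A `methyl_embedding` from [tsne_embed()].
#' @param labels Optional per-sample labels (a `cluster_assignment`, or a
#'   tibble with `sample_id` plus one label column, or a named vector).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.methyl_embedding <- function(object, labels = NULL, ...) {
  df <- tibble::as_tibble(object[c("sample_id", "x", "y")])
  if (!is.null(labels)) {
    if (inherits(labels, "cluster_assignment") || is.data.frame(labels)) {
      lab_tbl <- tibble::as_tibble(labels)
      lab_col <- setdiff(names(lab_tbl), "sample_id")[1]
      df$label <- lab_tbl[[lab_col]][match(df$sample_id, lab_tbl$sample_id)]
    } else {
      df$label <- labels[df$sample_id]
    }
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, colour = .data$label))
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y))
  }
  p +
    ggplot2::geom_point(size = 1.5, alpha = 0.8) +
    ggplot2::labs(x = "t-SNE 1", y = "t-SNE 2", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the per-iteration downsampling stability correlations
#'
#' @param object A `stability_report` from [stability_downsample()].
#' @param ... Unused.
#' @return A ggplot histogram of the per-iteration correlations with the
#'   median marked.
#' @export
autoplot.stability_report <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$r)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey40") +
    ggplot2::geom_vline(xintercept = object$median_r, colour = "firebrick") +
    ggplot2::labs(
      x = "Pearson r (reference vs downsampled embedding)",
      y = "iterations",
      title = sprintf("median r = %.3f", object$median_r)
    ) +
    ggplot2::theme_minimal()
}

#' Plot an outlier-detection ROC curve
#'
#' @param object A `methyl_roc` from [roc_auc()], or an
#'   `evaluation_report`.
#' @param ... Unused.
#' @return A ggplot of the ROC curve annotated with the AUC.
#' @export
autoplot.methyl_roc <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "false positive rate", y = "true positive rate",
      title = sprintf("AUC = %.4f", object$auc)
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.methyl_roc
#' @export
autoplot.evaluation_report <- function(object, ...) {
  if (is.null(object$roc)) stop("report has no ROC points", call. = FALSE)
  autoplot.methyl_roc(list(roc = object$roc, auc = object$auc))
}

#' Plot per-category outlier specificity
#'
#' @param report An `evaluation_report`.
#' @return A ggplot bar chart of per-category specificity.
#' @export
plot_category_specificity <- function(report) {
  df <- report$per_category
  ggplot2::ggplot(
    df,
    ggplot2::aes(stats::reorder(.data$category, .data$specificity), .data$specificity)
  ) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "fraction predicted Unknown") +
    ggplot2::theme_minimal()
}
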