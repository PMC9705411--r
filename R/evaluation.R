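#' Collapse multi-class predictions into the binary outlier-detection table
#'
#' All in-scope class predictions are combined into a single outcome and
#' contrasted with the outlier (`"Unknown"`) prediction, giving a 2x2 table
#' of truth (in-scope vs out-of-scope) by prediction (in-scope vs Unknown).
#'
#' @param predicted Character vector of predicted class labels (trained
#'   classes plus the outlier label).
#' @param in_scope Logical vector: is each sample truly an in-scope sample?
#' @param outlier_label Label of the outlier class.
#' @return A 2x2 integer matrix with rows `in_scope`, `out_of_scope` and
#'   columns `pred_in_scope`, `pred_unknown`.
#' @export
collapse_binary <- function(predicted, in_scope, outlier_label = "Unknown") {
  predicted <- as.character(predicted)
  if (length(predicted) == 0) stop("empty input", call. = FALSE)
  stopifnot(length(predicted) == length(in_scope), is.logical(in_scope))
  pred_unknown <- predicted == outlier_label
  tab <- matrix(
    c(
      sum(in_scope & !pred_unknown), sum(in_scope & pred_unknown),
      sum(!in_scope & !pred_unknown), sum(!in_scope & pred_unknown)
    ),
    nrow = 2, byrow = TRUE,
    dimnames = list(
      c("in_scope", "out_of_scope"),
      c("pred_in_scope", "pred_unknown")
    )
  )
  tab
}

#' Outlier-detection sensitivity and specificity
#'
#' Sensitivity is the fraction of truly in-scope samples predicted as any
#' in-scope class; specificity is the fraction of out-of-scope samples
#' predicted as the outlier class. Values are reported rounded half-up to
#' three decimals alongside the raw counts.
#'
#' @param tab A 2x2 table from [collapse_binary()].
#' @return A one-row tibble with `sensitivity`, `specificity` and the four
#'   underlying counts.
#' @export
outlier_metrics <- function(tab) {
  stopifnot(identical(dim(tab), c(2L, 2L)))
  n_in <- sum(tab["in_scope", ])
  n_out <- sum(tab["out_of_scope", ])
  if (n_in == 0 || n_out == 0) stop("zero margin in binary table", call. = FALSE)
  tibble::tibble(
    sensitivity = round_half_up(tab["in_scope", "pred_in_scope"] / n_in, 3),
    specificity = round_half_up(tab["out_of_scope", "pred_unknown"] / n_out, 3),
    tp = tab["in_scope", "pred_in_scope"],
    fn = tab["in_scope", "pred_unknown"],
    tn = tab["out_of_scope", "pred_unknown"],
    fp = tab["out_of_scope", "pred_in_scope"]
  )
}

#' Per-category outlier specificity
#'
#' For every category of out-of-scope samples, the fraction predicted as
#' the outlier class. Highlights which tumor categories the classifier
#' confuses with in-scope classes.
#'
#' @param predicted Predicted labels of the out-of-scope samples.
#' @param categories Category of each sample (same length).
#' @param outlier_label Label of the outlier class.
#' @return A tibble `category`, `n`, `n_unknown`, `specificity` (rounded
#'   half-up to 3 decimals), one row per category.
#' @export
per_category_specificity <- function(predicted, categories,
                                     outlier_label = "Unknown") {
  stopifnot(length(predicted) == length(categories))
  if (anyNA(categories)) stop("missing category", call. = FALSE)
  tibble::tibble(
    category = as.character(categories),
    unknown = as.character(predicted) == outlier_label
  ) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_unknown = sum(.data$unknown),
      specificity = round_half_up(sum(.data$unknown) / dplyr::n(), 3),
      .by = "category"
    ) |>
    dplyr::arrange(.data$category)
}

#' Conditional (in-scope) accuracy
#'
#' Accuracy over the truly in-scope test samples that were not predicted
#' as the outlier class: of the samples the classifier was willing to
#' classify, how many received the correct class.
#'
#' @param predicted Predicted labels of in-scope test samples.
#' @param truth True class labels (same length).
#' @param outlier_label Label of the outlier class.
#' @return A proportion in \[0, 1\], rounded half-up to 3 decimals.
#' @export
conditional_accuracy <- function(predicted, truth, outlier_label = "Unknown") {
  stopifnot(length(predicted) == length(truth))
  keep <- as.character(predicted) != outlier_label
  if (!any(keep)) stop("all samples predicted as outlier", call. = FALSE)
  round_half_up(mean(predicted[keep] == truth[keep]), 3)
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps a decision threshold over the unique scores (descending), records
#' (false positive rate, true positive rate) at each threshold, and
#' integrates the curve by the trapezoid rule. Tied scores move along the
#' curve diagonally, so the trapezoid AUC equals the Mann-Whitney
#' concordance probability with ties counted one half.
#'
#' @param truth Logical vector (TRUE = positive class).
#' @param score Numeric score, higher = more positive.
#' @return A list with `roc` (tibble `threshold`, `fpr`, `tpr`, starting at
#'   (0, 0) and ending at (1, 1)) and `auc`.
#' @export
roc_auc <- function(truth, score) {
  stopifnot(is.logical(truth), length(truth) == length(score))
  n_pos <- sum(truth)
  n_neg <- sum(!truth)
  if (n_pos == 0 || n_neg == 0) {
    stop("both classes must be present", call. = FALSE)
  }
  thr <- sort(unique(score), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(truth & score >= t), numeric(1))
  fp <- vapply(thr, function(t) sum(!truth & score >= t), numeric(1))
  roc <- tibble::tibble(
    threshold = c(Inf, thr),
    fpr = c(0, fp / n_neg),
    tpr = c(0, tp / n_pos)
  )
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
  res <- list(roc = roc, auc = auc)
  class(res) <- "methyl_roc"
  res
}

#' @export
print.methyl_roc <- function(x, ...) {
  cat(sprintf(
    "<methyl_roc> %d points, AUC = %.4f\n", nrow(x$roc), x$auc
  ))
  invisible(x)
}

#' Full evaluation report for a prediction set
#'
#' Assembles the evaluation protocol in one object: the confusion matrix of
#' true category by predicted class, outlier-detection sensitivity and
#' specificity after collapsing all in-scope predictions, per-category
#' specificity of the out-of-scope samples, conditional accuracy on the
#' classifiable in-scope samples, and the ROC/AUC of the binary outlier
#' score (1 - P(Unknown)).
#'
#' @param predictions Tibble from [predict.methyl_classifier()] (needs
#'   `sample_id`, `label`, and the per-class probability columns).
#' @param truth Tibble with `sample_id`, `label` (true class for in-scope
#'   samples; anything else for out-of-scope) and `category`.
#' @param classes Trained class order (incl. the outlier label last).
#' @param outlier_label Label of the outlier class.
#' @return An `evaluation_report` with elements `confusion`,
#'   `binary_table`, `outlier` (sensitivity/specificity tibble),
#'   `per_category`, `conditional_accuracy`, `roc`, `auc`.
#' @export
evaluation_report <- function(predictions, truth, classes,
                              outlier_label = "Unknown") {
  truth <- truth[match(predictions$sample_id, truth$sample_id), ]
  if (anyNA(truth$sample_id)) {
    stop("truth does not cover all predicted samples", call. = FALSE)
  }
  in_scope <- truth$label %in% setdiff(classes, outlier_label)
  predicted <- predictions$label

  tab <- collapse_binary(predicted, in_scope, outlier_label)
  outlier <- outlier_metrics(tab)
  per_cat <- per_category_specificity(
    predicted[!in_scope], truth$category[!in_scope], outlier_label
  )
  cond_acc <- conditional_accuracy(
    predicted[in_scope], truth$label[in_scope], outlier_label
  )
  true_cat <- ifelse(in_scope, truth$label, truth$category)
  confusion <- table(
    truth = true_cat,
    predicted = factor(predicted, levels = classes)
  )
  roc <- if (outlier_label %in% names(predictions)) {
    roc_auc(in_scope, 1 - predictions[[outlier_label]])
  } else {
    NULL
  }
  structure(
    list(
      confusion = confusion, binary_table = tab, outlier = outlier,
      per_category = per_cat, conditional_accuracy = cond_acc,
      roc = if (is.null(roc)) NULL else roc$roc,
      auc = if (is.null(roc)) NA_real_ else roc$auc
    ),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n")
  cat(sprintf(
    "outlier detection: sensitivity %.3f (%d/%d), specificity %.3f (%d/%d)\n",
    x$outlier$sensitivity, x$outlier$tp, x$outlier$tp + x$outlier$fn,
    x$outlier$specificity, x$outlier$tn, x$outlier$tn + x$outlier$fp
  ))
  cat(sprintf("conditional accuracy: %.3f\n", x$conditional_accuracy))
  if (!is.na(x$auc)) cat(sprintf("outlier ROC AUC: %.4f\n", x$auc))
  cat("per-category specificity:\n")
  print(as.data.frame(x$per_category))
  invisible(x)
}

# round half away from zero at `digits` decimals (matches reported
# proportions like 47/52 -> 0.904)
round_half_up <- function(x, digits = 3) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
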