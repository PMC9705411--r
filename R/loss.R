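#' Class-balanced multinomial cross-entropy loss
#'
#' Weighted multinomial log loss in which every class contributes equally
#' regardless of its size: with N samples over K classes, class c of size
#' n_c gets weight w_c = N / (K * n_c) (inverse class frequency, normalized
#' to mean 1), and
#' \deqn{L = \sum_i w_{y_i} (-\log \max(p_{i,y_i}, \epsilon)) / \sum_i w_{y_i}.}
#' With equal class sizes this reduces to the unweighted mean cross-entropy;
#' a perfect one-hot prediction scores 0 and uniform predictions score
#' log(K).
#'
#' @param scores Numeric matrix (or data frame) of per-class probabilities,
#'   one row per sample, columns named by class.
#' @param labels Character vector of true class labels, a subset of the
#'   score columns.
#' @param eps Floor inside the log, keeping the loss finite.
#' @return A non-negative scalar.
#' @export
balanced_log_loss <- function(scores, labels, eps = 1e-15) {
  scores <- as.matrix(scores)
  labels <- as.character(labels)
  if (is.null(colnames(scores))) stop("scores need class column names", call. = FALSE)
  bad <- setdiff(unique(labels), colnames(scores))
  if (length(bad) > 0) {
    stop("labels outside score columns: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (length(labels) != nrow(scores)) {
    stop("one label per score row required", call. = FALSE)
  }
  n_c <- table(labels)
  if (any(n_c == 0)) stop("class with zero samples", call. = FALSE)
  k <- length(n_c)
  w_class <- length(labels) / (k * n_c)
  w <- as.numeric(w_class[labels])
  p_true <- scores[cbind(seq_along(labels), match(labels, colnames(scores)))]
  sum(w * -log(pmax(p_true, eps))) / sum(w)
}
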