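#' Stratified cross-validation folds
#'
#' Assigns every sample to exactly one of `k` validation folds, stratified
#' by exact class label: within each class the (id-sorted) samples are
#' randomly permuted and dealt round-robin, so per-fold class counts differ
#' from perfect proportionality by at most one sample. Because samples are
#' sorted by id before the seeded draw, the assignment is invariant to the
#' input order of the samples.
#'
#' @param labels Character vector of class labels.
#' @param ids Character vector of sample ids (same length).
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return A tibble `sample_id`, `label`, `fold` in the input order.
#' @export
stratified_folds <- function(labels, ids, k = 5, seed = 42L) {
  stopifnot(length(labels) == length(ids), k >= 2)
  df <- tibble::tibble(sample_id = ids, label = as.character(labels))
  assign <- withr::with_seed(seed, {
    split(df$sample_id, df$label)[sort(unique(df$label))] |>
      purrr::imap(function(cls_ids, cls) {
        cls_ids <- sort(cls_ids)
        perm <- sample(cls_ids)
        tibble::tibble(
          sample_id = perm,
          fold = rep_len(seq_len(k), length(perm))
        )
      }) |>
      dplyr::bind_rows()
  })
  dplyr::left_join(df, assign, by = "sample_id")
}

#' Grid-search cross-validation under the class-balanced loss
#'
#' Runs k-fold stratified cross-validation over a hyperparameter grid. In
#' every fold the top variant probes are selected on the training portion
#' only and the held-out fold is projected onto that feature set, so no
#' information from held-out samples can enter feature selection. Each grid
#' point is scored by the mean across folds of the class-balanced
#' multinomial cross-entropy of its out-of-fold class probabilities; the
#' argmin wins (ties: first combination in grid enumeration order). The
#' winner's out-of-fold scores are retained for calibration.
#'
#' @param ts A `training_set` from [assemble_training_set()].
#' @param grid A grid tibble from [hyperparam_grid()].
#' @param k_features Number of variant probes selected per fold.
#' @param folds Number of CV folds; reduced with a warning when the
#'   smallest class has fewer members.
#' @param seed Integer seed for fold construction and model fitting.
#' @return A `cv_result` with elements `leaderboard` (grid + `mean_loss`),
#'   `winner` (one-row tibble), `oof_scores` (samples x classes matrix of
#'   out-of-fold probabilities at the winner), `folds` (assignment tibble),
#'   `classes`, `k_features`, `seed`.
#' @export
cv_grid_search <- function(ts, grid, k_features = 20000, folds = 5,
                           seed = 42L) {
  labels <- ts$sheet$label
  classes <- class_order(labels)
  if (length(classes) < 2) stop("need at least two classes", call. = FALSE)
  min_class <- min(table(labels))
  if (min_class < folds) {
    warning(
      "smallest class has ", min_class, " members; reducing folds to ",
      min_class,
      call. = FALSE
    )
    folds <- min_class
  }
  fold_tbl <- stratified_folds(labels, sample_ids(ts$beta), k = folds, seed = seed)

  n <- n_samples(ts$beta)
  n_grid <- nrow(grid)
  # all out-of-fold scores per grid point; modest size (combos x n x K)
  scores <- rep(list(matrix(
    NA_real_, n, length(classes),
    dimnames = list(sample_ids(ts$beta), classes)
  )), n_grid)
  fold_loss <- matrix(NA_real_, n_grid, folds)

  for (f in seq_len(folds)) {
    val_idx <- which(fold_tbl$fold == f)
    tr_idx <- setdiff(seq_len(n), val_idx)
    tr_bm <- bm_subset(ts$beta, samples = sample_ids(ts$beta)[tr_idx])
    fs <- select_top_variant(tr_bm, k = k_features)
    X_tr <- t(project_features(tr_bm, fs)$values)
    X_val <- t(project_features(
      bm_subset(ts$beta, samples = sample_ids(ts$beta)[val_idx]), fs
    )$values)
    y_tr <- labels[tr_idx]
    for (g in seq_len(n_grid)) {
      fit <- fit_model(X_tr, y_tr, grid[g, ], classes = classes, seed = seed + g)
      p <- predict_model_scores(fit, X_val, classes = classes)
      scores[[g]][val_idx, ] <- p
      fold_loss[g, f] <- balanced_log_loss(p, labels[val_idx])
    }
  }

  mean_loss <- rowMeans(fold_loss)
  win <- which.min(mean_loss) # which.min takes the first of tied minima
  leaderboard <- dplyr::mutate(grid, mean_loss = mean_loss)
  res <- list(
    leaderboard = leaderboard,
    winner = leaderboard[win, ],
    oof_scores = scores[[win]],
    fold_loss = fold_loss,
    folds = fold_tbl,
    classes = classes,
    k_features = k_features,
    seed = seed
  )
  class(res) <- "cv_result"
  res
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result> ", nrow(x$leaderboard), " grid points, ",
    max(x$folds$fold), " folds\nwinner:\n",
    sep = ""
  )
  print(x$winner)
  invisible(x)
}

# Canonical class order: alphabetical with "Unknown" forced last, so the
# outlier class is always the final score column and argmax tie-breaks
# prefer substantive classes.
class_order <- function(labels) {
  cls <- sort(unique(as.character(labels)))
  c(setdiff(cls, "Unknown"), intersect("Unknown", cls))
}
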