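#' Unsupervised class discovery on a reference cohort
#'
#' Chains the discovery stage: probe filtering, top-variant CpG selection,
#' t-SNE embedding, DBSCAN clustering and noise exclusion.
#'
#' @param bm Reference [beta_matrix()].
#' @param manifest Probe manifest (skip probe filtering when `NULL`).
#' @param k_features Number of top-variance CpGs.
#' @param perplexity,tsne_iterations,seed t-SNE parameters.
#' @param min_pts,eps DBSCAN parameters (`eps = "auto"` uses
#'   [estimate_eps()]).
#' @return A list with `feature_set`, `embedding`, `clusters` (all
#'   samples), `reference` (list `beta`, `clusters` after noise removal)
#'   and `filtered_beta` (probe-filtered full matrix).
#' @export
run_discovery <- function(bm, manifest = NULL, k_features = 20000,
                          perplexity = 20, tsne_iterations = 4000,
                          min_pts = 6, eps = "auto", seed = 42L) {
  if (!is.null(manifest)) bm <- filter_probes(bm, manifest)
  fs <- select_top_variant(bm, k = k_features)
  emb <- tsne_embed(project_features(bm, fs),
    perplexity = perplexity,
    iterations = tsne_iterations, seed = seed
  )
  ca <- dbscan_cluster(emb, min_pts = min_pts, eps = eps)
  ref <- exclude_noise(bm, ca)
  list(
    feature_set = fs, embedding = emb, clusters = ca,
    reference = ref, filtered_beta = bm
  )
}

#' Map discovered clusters to ground-truth classes by majority vote
#'
#' For simulation studies: each discovered cluster is matched to the
#' ground-truth class of the majority of its members, so that supervised
#' predictions over cluster labels can be scored against simulator truth.
#'
#' @param clusters A `cluster_assignment` (noise rows ignored).
#' @param truth Tibble with `sample_id`, `class`.
#' @return A tibble `cluster`, `class`, `n`, `purity_of_vote`.
#' @export
match_clusters_to_truth <- function(clusters, truth) {
  tibble::tibble(
    cluster = clusters$cluster,
    class = truth$class[match(clusters$sample_id, truth$sample_id)]
  ) |>
    dplyr::filter(.data$cluster != "NOISE") |>
    dplyr::count(.data$cluster, .data$class) |>
    dplyr::mutate(cluster_size = sum(.data$n), .by = "cluster") |>
    dplyr::slice_max(.data$n, n = 1, by = "cluster", with_ties = FALSE) |>
    dplyr::mutate(purity_of_vote = .data$n / .data$cluster_size) |>
    dplyr::select("cluster", "class", "n", "purity_of_vote")
}

#' Run the full discovery-to-evaluation pipeline on a simulated study
#'
#' End-to-end driver over a [simulate_split()] design: class discovery on
#' the reference partition, training-set assembly with the Unknown pool,
#' grid-search cross-validation, final fit, calibration, prediction on all
#' held-out samples (in-scope test, unseen-category outliers, and the pool
#' samples not drawn into the Unknown class) and the evaluation report.
#' In-scope test truth is expressed in discovered-cluster labels through
#' the majority-vote cluster/class matching.
#'
#' @param split Output of [simulate_split()].
#' @inheritParams run_discovery
#' @param grid Hyperparameter grid for [cv_grid_search()].
#' @param folds CV folds.
#' @param per_category_fraction Fraction of each pool category drawn into
#'   the Unknown class.
#' @param calibration_folds Internal folds of the calibration fit.
#' @return A list with `discovery`, `training_set`, `classifier`,
#'   `predictions`, `report`, `cluster_map`.
#' @export
run_pipeline <- function(split, k_features = 20000, perplexity = 20,
                         tsne_iterations = 4000, min_pts = 6, eps = "auto",
                         grid = hyperparam_grid("svm"), folds = 5,
                         per_category_fraction = 0.05,
                         calibration_folds = 10, seed = 42L) {
  disc <- run_discovery(split$reference$beta, split$manifest,
    k_features = k_features, perplexity = perplexity,
    tsne_iterations = tsne_iterations, min_pts = min_pts, eps = eps,
    seed = seed
  )
  pool_bm <- filter_probes(split$pool$beta, split$manifest)
  ts <- assemble_training_set(
    disc$reference$beta, disc$reference$clusters,
    pool_bm, split$pool$sheet,
    per_category_fraction = per_category_fraction, seed = seed
  )
  clf <- build_classifier(ts, grid,
    k_features = k_features, folds = folds,
    calibration_folds = calibration_folds, seed = seed
  )

  unknown_ids <- ts$sheet$sample_id[ts$sheet$label == "Unknown"]
  leftover_ids <- setdiff(sample_ids(pool_bm), unknown_ids)
  eval_bm <- merge_platforms(
    filter_probes(split$test_in_scope$beta, split$manifest),
    merge_platforms(
      filter_probes(split$test_outlier$beta, split$manifest),
      bm_subset(pool_bm, samples = leftover_ids)
    )
  )
  predictions <- stats::predict(clf, eval_bm)

  cluster_map <- match_clusters_to_truth(
    disc$reference$clusters, split$reference$truth
  )
  class_to_cluster <- stats::setNames(cluster_map$cluster, cluster_map$class)
  all_truth <- dplyr::bind_rows(
    split$test_in_scope$truth, split$test_outlier$truth,
    split$pool$truth[split$pool$truth$sample_id %in% leftover_ids, ]
  )
  all_sheet <- dplyr::bind_rows(
    split$test_in_scope$sheet, split$test_outlier$sheet,
    split$pool$sheet[split$pool$sheet$sample_id %in% leftover_ids, ]
  )
  truth_tbl <- tibble::tibble(
    sample_id = all_truth$sample_id,
    label = dplyr::if_else(
      all_sheet$category[match(all_truth$sample_id, all_sheet$sample_id)] == "in_scope",
      unname(class_to_cluster[all_truth$class]),
      "out_of_scope"
    ),
    category = all_sheet$category[match(all_truth$sample_id, all_sheet$sample_id)]
  )
  report <- evaluation_report(predictions, truth_tbl, classes = clf$classes)

  list(
    discovery = disc, training_set = ts, classifier = clf,
    predictions = predictions, report = report, cluster_map = cluster_map
  )
}
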