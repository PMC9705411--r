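test_that("balanced log loss matches closed forms and the hand-computed fixture", {
  # perfect one-hot predictions score zero (up to the eps floor)
  scores <- matrix(c(1, 0, 0, 1), 2, 2, dimnames = list(NULL, c("a", "b")))
  expect_lt(balanced_log_loss(scores, c("a", "b")), 1e-12)

  # uniform predictions score log K regardless of class sizes
  for (sizes in list(c(3, 3), c(5, 1), c(4, 2, 1))) {
    k <- length(sizes)
    labels <- rep(letters[seq_len(k)], times = sizes)
    unif <- matrix(1 / k, length(labels), k,
      dimnames = list(NULL, letters[seq_len(k)])
    )
    expect_equal(balanced_log_loss(unif, labels), log(k), tolerance = 1e-12)
  }

  # two classes, sizes (2, 1), true-class probabilities (.8, .6, .9):
  # weights w = (0.75, 0.75, 1.5), hand-computed weighted mean
  s <- matrix(c(0.8, 0.6, 0.1, 0.2, 0.4, 0.9), 3, 2,
    dimnames = list(NULL, c("a", "b"))
  )
  hand <- (0.75 * -log(0.8) + 0.75 * -log(0.6) + 1.5 * -log(0.9)) / 3
  expect_equal(balanced_log_loss(s, c("a", "a", "b")), hand, tolerance = 1e-12)
  expect_equal(hand, 0.2361726, tolerance = 1e-6)

  # equal class sizes: reduces to the unweighted mean cross-entropy
  s4 <- matrix(stats::runif(8, 0.1, 0.9), 4, 2,
    dimnames = list(NULL, c("a", "b"))
  )
  lab4 <- c("a", "a", "b", "b")
  p_true <- s4[cbind(1:4, match(lab4, colnames(s4)))]
  expect_equal(
    balanced_log_loss(s4, lab4), mean(-log(p_true)),
    tolerance = 1e-12
  )

  expect_error(balanced_log_loss(s, c("a", "a", "z")), "outside score columns")
})

test_that("hyperparameter grids enumerate the documented axes and order", {
  g <- hyperparam_grid("svm")
  expect_identical(
    unique(g$kernel), c("linear", "radial")
  )
  lin <- g[g$kernel == "linear", ]
  expect_identical(lin$cost, 2^(0:5))
  expect_true(all(is.na(lin$gamma)))
  rbf <- g[g$kernel == "radial", ]
  expect_identical(nrow(rbf), 6L * 7L)
  expect_setequal(unique(rbf$gamma), 2^(-3:3) / 20000)
  # enumeration order: kernel, then cost, then gamma
  expect_identical(rbf$cost[1:7], rep(1, 7))
  expect_identical(rbf$gamma[1:7], 2^(-3:3) / 20000)

  rf <- hyperparam_grid("rf")
  expect_setequal(unique(rf$ntree), c(500, 1000))
  expect_setequal(
    unique(rf$mtry),
    unique(pmax(1L, as.integer(round(2^(-5:5) * sqrt(20000)))))
  )
})

test_that("training-set assembly draws the per-category Unknown pool reproducibly", {
  split <- simulate_split(sim_config(
    n_classes = 2, samples_per_class = 10, n_probes = 1000,
    n_informative = 80, n_outlier_classes = 3, n_unseen_outlier = 1,
    outlier_class_size = 40, seed = 13
  ))
  labels <- dplyr::rename(split$reference$truth[, c("sample_id", "class")],
    label = "class"
  )
  ts <- assemble_training_set(
    split$reference$beta, labels,
    split$pool$beta, split$pool$sheet,
    per_category_fraction = 0.05, seed = 7
  )
  # 2 seen categories x 40 samples x 5% = 2 each
  expect_identical(sum(ts$sheet$label == "Unknown"), 4L)
  expect_identical(nrow(ts$sheet), 24L)
  expect_true(all(
    ts$sheet$provenance[ts$sheet$label == "Unknown"] == "unknown_pool"
  ))

  ts2 <- assemble_training_set(
    split$reference$beta, labels,
    split$pool$beta, split$pool$sheet,
    per_category_fraction = 0.05, seed = 7
  )
  expect_identical(ts$sheet, ts2$sheet)

  # at least one sample per non-empty category even below rounding
  ts3 <- assemble_training_set(
    split$reference$beta, labels,
    split$pool$beta, split$pool$sheet,
    per_category_fraction = 0.001, seed = 7
  )
  expect_identical(sum(ts3$sheet$label == "Unknown"), 2L)

  expect_warning(
    ref_only <- assemble_training_set(split$reference$beta, labels),
    "no Unknown"
  )
  expect_false("Unknown" %in% ref_only$sheet$label)
})

test_that("stratified folds cover every sample once with balanced classes", {
  labels <- rep(c("a", "b", "c"), times = c(20, 11, 35))
  ids <- sprintf("s%03d", seq_along(labels))
  f <- stratified_folds(labels, ids, k = 5, seed = 3)
  expect_identical(sort(f$sample_id), sort(ids))
  expect_identical(nrow(f), length(ids))
  expect_true(all(table(f$sample_id) == 1))
  # per-fold class counts within one of perfect proportionality
  per <- table(f$label, f$fold)
  for (cl in rownames(per)) {
    expect_lte(max(per[cl, ]) - min(per[cl, ]), 1)
  }
  # invariance to input order: same ids, shuffled positions
  perm <- withr::with_seed(1, sample(seq_along(ids)))
  f2 <- stratified_folds(labels[perm], ids[perm], k = 5, seed = 3)
  expect_identical(
    f$fold[match(ids, f$sample_id)],
    f2$fold[match(ids, f2$sample_id)]
  )
})

# one small separable training set shared by the CV tests
cv_fixture <- function(seed = 17) {
  split <- simulate_split(sim_config(
    n_classes = 3, samples_per_class = 15, n_probes = 1500,
    n_informative = 100, n_outlier_classes = 3, n_unseen_outlier = 1,
    outlier_class_size = 60, seed = seed
  ))
  labels <- dplyr::rename(split$reference$truth[, c("sample_id", "class")],
    label = "class"
  )
  assemble_training_set(
    split$reference$beta, labels,
    split$pool$beta, split$pool$sheet,
    per_category_fraction = 0.05, seed = seed
  )
}

test_that("grid-search CV honors its contracts and prefers fitting models", {
  ts <- cv_fixture()
  grid <- hyperparam_grid("svm",
    kernels = c("linear", "radial"),
    cost = c(1, 2^5), gamma = 2^3 / 20000
  )
  cv <- cv_grid_search(ts, grid, k_features = 300, folds = 5, seed = 5)

  # every sample in exactly one validation fold, with OOF scores filled
  expect_identical(sort(cv$folds$sample_id), sort(sample_ids(ts$beta)))
  expect_false(anyNA(cv$oof_scores))
  expect_identical(colnames(cv$oof_scores), cv$classes)
  expect_identical(cv$classes[length(cv$classes)], "Unknown")

  # single-point grid: forced winner
  cv1 <- cv_grid_search(ts, grid[1, ], k_features = 200, folds = 3, seed = 5)
  expect_identical(cv1$winner$cost, grid$cost[1])

  # winner beats the most-regularized corner on separable data
  corner <- grid[nrow(grid), ]
  corner_loss <- cv$leaderboard$mean_loss[nrow(cv$leaderboard)]
  expect_lte(min(cv$leaderboard$mean_loss), corner_loss)
  expect_identical(
    cv$winner$mean_loss, min(cv$leaderboard$mean_loss)
  )

  # folds shrink with a warning when a class is too small
  tiny <- cv_fixture(seed = 23)
  keep <- tiny$sheet$sample_id[c(
    which(tiny$sheet$label != "Unknown"),
    which(tiny$sheet$label == "Unknown")[1:3]
  )]
  tiny$beta <- bm_subset(tiny$beta, samples = keep)
  tiny$sheet <- tiny$sheet[match(keep, tiny$sheet$sample_id), ]
  expect_warning(
    cv_small <- cv_grid_search(tiny, grid[1, ], k_features = 100, folds = 5, seed = 5),
    "reducing folds"
  )
  expect_identical(max(cv_small$folds$fold), 3L)
})

test_that("per-fold feature selection cannot see held-out samples", {
  ts <- cv_fixture(seed = 29)
  # poison one sample with an extreme-variance probe pattern: a probe that
  # is constant everywhere except in the poisoned sample would top the
  # variance ranking only if that sample leaked into feature selection
  poison_probe <- probe_ids(ts$beta)[1]
  poison_sample <- sample_ids(ts$beta)[1]
  v <- ts$beta$values
  v[poison_probe, ] <- 0
  v[poison_probe, poison_sample] <- 1
  ts$beta <- beta_matrix(v, platform = ts$beta$platform)

  # k chosen so that leaked full-data selection would include the poison
  # probe (it ranks by its full-data variance), while the held-out fold's
  # training part sees a constant probe with zero variance
  all_fs <- select_top_variant(ts$beta, n_probes(ts$beta))
  k_leak <- which(all_fs$probe_id == poison_probe)
  expect_true(poison_probe %in% select_top_variant(ts$beta, k_leak)$probe_id)

  grid <- hyperparam_grid("svm", kernels = "linear", cost = 1)
  cv <- cv_grid_search(ts, grid, k_features = k_leak, folds = 5, seed = 5)
  poison_fold <- cv$folds$fold[cv$folds$sample_id == poison_sample]
  tr_ids <- cv$folds$sample_id[cv$folds$fold != poison_fold]
  fs <- select_top_variant(bm_subset(ts$beta, samples = tr_ids), k_leak)
  expect_false(poison_probe %in% fs$probe_id)
})

test_that("final model refits on all samples and survives archiving", {
  ts <- cv_fixture(seed = 41)
  grid <- hyperparam_grid("svm", kernels = "linear", cost = 1)
  clf <- suppressWarnings(build_classifier(ts, grid,
    k_features = 300, folds = 5,
    calibration_folds = 5, seed = 5
  )) # glmnet cautions about the small Unknown class
  # resubstitution accuracy on strongly separated data
  pred <- predict(clf, ts$beta)
  expect_gte(mean(pred$label == ts$sheet$label), 0.98)
  # one score column per training class incl. Unknown
  expect_true(all(clf$classes %in% names(pred)))
  raw <- predict_scores(clf, ts$beta)
  expect_identical(colnames(raw), clf$classes)
  # SVM rows are coupled probabilities: sum to 1 within coupling tolerance
  expect_lt(max(abs(rowSums(raw) - 1)), 1e-6)

  dir <- withr::local_tempdir()
  save_classifier(clf, dir)
  back <- load_classifier(dir)
  pred2 <- predict(back, ts$beta)
  expect_equal(pred, pred2, tolerance = 1e-12)

  # newer schema versions are refused
  meta <- jsonlite::read_json(file.path(dir, "archive.json"),
    simplifyVector = TRUE
  )
  meta$schema_version <- 99
  jsonlite::write_json(meta, file.path(dir, "archive.json"), auto_unbox = TRUE)
  expect_error(load_classifier(dir), "newer")
})

test_that("random-forest family returns exact vote-fraction scores", {
  ts <- cv_fixture(seed = 43)
  grid <- hyperparam_grid("rf", ntree = 100, mtry = 17)
  cv <- cv_grid_search(ts, grid, k_features = 200, folds = 3, seed = 5)
  expect_true(all(abs(rowSums(cv$oof_scores) - 1) < 1e-12))
  model <- train_final(ts, cv$winner, k_features = 200, seed = 5)
  raw <- predict_scores(model, ts$beta)
  expect_identical(colnames(raw), model$classes)
  expect_true(all(raw >= 0 & raw <= 1))
})
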