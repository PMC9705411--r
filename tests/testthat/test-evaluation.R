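test_that("binary collapse and outlier metrics reproduce the published contingencies", {
  # in-scope test set: 52 samples, 5 predicted as the outlier class
  pred_in <- c(rep("class_1", 47), rep("Unknown", 5))
  # out-of-scope test set: 7665 samples, 7524 predicted Unknown
  pred_out <- c(rep("Unknown", 7524), rep("class_2", 141))
  tab <- collapse_binary(
    c(pred_in, pred_out),
    c(rep(TRUE, 52), rep(FALSE, 7665))
  )
  expect_identical(tab["in_scope", "pred_in_scope"], 47L)
  expect_identical(tab["in_scope", "pred_unknown"], 5L)
  expect_identical(tab["out_of_scope", "pred_unknown"], 7524L)

  m <- outlier_metrics(tab)
  expect_identical(m$sensitivity, 0.904) # 47/52
  expect_identical(m$specificity, 0.982) # 7524/7665

  perfect <- collapse_binary(
    c("class_1", "Unknown"), c(TRUE, FALSE)
  )
  expect_identical(unname(perfect[cbind(1:2, 2:1)]), c(0L, 0L))
  expect_identical(outlier_metrics(perfect)$sensitivity, 1)
  expect_identical(outlier_metrics(perfect)$specificity, 1)

  expect_error(collapse_binary(character(0), logical(0)), "empty")
  one_sided <- collapse_binary(c("a", "b"), c(TRUE, TRUE))
  expect_error(outlier_metrics(one_sided), "zero margin")
})

test_that("per-category specificity counts match hand tallies and printed values", {
  # seen-diagnosis analog: 6492 samples, 6402 flagged Unknown -> 0.986
  pred <- c(
    rep("Unknown", 6402), rep("class_1", 90), # seen
    rep("Unknown", 763), rep("class_1", 237) # salivary-gland analog
  )
  cats <- c(rep("seen", 6492), rep("salivary", 1000))
  out <- per_category_specificity(pred, cats)
  expect_identical(out$specificity[out$category == "seen"], 0.986)
  expect_identical(out$specificity[out$category == "salivary"], 0.763)

  toy <- per_category_specificity(
    c("Unknown", "x", "Unknown", "Unknown"),
    c("cat1", "cat1", "cat2", "cat2")
  )
  expect_identical(toy$specificity, c(0.5, 1))
  expect_identical(toy$n_unknown, c(1L, 2L))
  expect_error(
    per_category_specificity(c("a"), c(NA_character_)),
    "missing category"
  )
})

test_that("conditional accuracy scores only the classifiable in-scope samples", {
  # 47 classifiable, all confirmed -> 1.0 (5 outlier calls excluded)
  pred <- c(rep("class_1", 47), rep("Unknown", 5))
  truth <- rep("class_1", 52)
  expect_identical(conditional_accuracy(pred, truth), 1)

  half <- conditional_accuracy(
    c("a", "a", "b", "b", "Unknown"),
    c("a", "b", "a", "b", "b")
  )
  expect_identical(half, 0.5)
  expect_error(
    conditional_accuracy(rep("Unknown", 3), rep("a", 3)),
    "all samples"
  )

  # permutation baseline sits near 1/K
  withr::with_seed(5, {
    k <- 4
    truth <- sample(letters[1:k], 4000, replace = TRUE)
    pred <- sample(truth)
    expect_lt(abs(conditional_accuracy(pred, truth) - 1 / k), 0.05)
  })
})

test_that("ROC/AUC by threshold sweep equals pair counting, with ties at one half", {
  pos <- c(0.9, 0.8, 0.4)
  neg <- c(0.7, 0.3, 0.2)
  res <- roc_auc(c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE), c(pos, neg))
  expect_equal(res$auc, 8 / 9, tolerance = 1e-12)
  expect_identical(res$roc$fpr[1], 0)
  expect_identical(res$roc$tpr[1], 0)
  expect_identical(res$roc$fpr[nrow(res$roc)], 1)
  expect_identical(res$roc$tpr[nrow(res$roc)], 1)

  sep <- roc_auc(c(TRUE, TRUE, FALSE), c(0.9, 0.8, 0.1))
  expect_identical(sep$auc, 1)
  flat <- roc_auc(c(TRUE, FALSE, TRUE, FALSE), rep(0.5, 4))
  expect_equal(flat$auc, 0.5, tolerance = 1e-12)
  expect_error(roc_auc(c(TRUE, TRUE), c(0.1, 0.2)), "both classes")

  # property: trapezoid AUC == Mann-Whitney pair counting on random sets
  withr::with_seed(77, {
    for (i in 1:100) {
      n <- sample(4:200, 1)
      truth <- sample(c(TRUE, FALSE), n, replace = TRUE)
      if (length(unique(truth)) < 2) truth[1:2] <- c(TRUE, FALSE)
      score <- round(stats::runif(n), sample(1:3, 1)) # force ties often
      expect_equal(
        roc_auc(truth, score)$auc, bf_auc(truth, score),
        tolerance = 1e-12
      )
    }
  })
})

test_that("AUC agrees with the external ROC reference implementation", {
  withr::with_seed(13, {
    truth <- sample(c(TRUE, FALSE), 150, replace = TRUE)
    score <- stats::runif(150) + 0.5 * truth
    ours <- roc_auc(truth, score)$auc
    ref <- as.numeric(pROC::auc(pROC::roc(
      factor(truth, levels = c(FALSE, TRUE)), score,
      direction = "<", quiet = TRUE
    )))
    expect_equal(ours, ref, tolerance = 1e-12)
  })
})

test_that("evaluation report is internally consistent and order-invariant", {
  withr::with_seed(21, {
    classes <- c("class_1", "class_2", "Unknown")
    n <- 120
    in_scope <- c(rep(TRUE, 40), rep(FALSE, 80))
    truth <- tibble::tibble(
      sample_id = sprintf("s%03d", 1:n),
      label = ifelse(in_scope, sample(classes[1:2], n, replace = TRUE), "out_of_scope"),
      category = ifelse(in_scope, "in_scope",
        sample(c("cat_a", "cat_b"), n, replace = TRUE)
      )
    )
    p_unknown <- ifelse(in_scope, stats::runif(n, 0, 0.3), stats::runif(n, 0.4, 1))
    rest <- 1 - p_unknown
    predictions <- tibble::tibble(
      sample_id = truth$sample_id,
      class_1 = rest * 0.7, class_2 = rest * 0.3, Unknown = p_unknown
    )
    predictions$label <- classes[max.col(as.matrix(predictions[classes]))]
    # force a few imperfections
    predictions$label[1:3] <- "Unknown"

    rep1 <- evaluation_report(predictions, truth, classes)
    # metrics recomputed from the stored binary table match the report
    m <- outlier_metrics(rep1$binary_table)
    expect_identical(m$sensitivity, rep1$outlier$sensitivity)
    expect_identical(m$specificity, rep1$outlier$specificity)
    # confusion row sums equal per-category truth counts
    expect_equal(
      as.numeric(rowSums(rep1$confusion)),
      as.numeric(table(ifelse(in_scope, truth$label, truth$category)))
    )
    # sample order invariance
    perm <- sample(n)
    rep2 <- evaluation_report(predictions[perm, ], truth, classes)
    expect_identical(rep1$outlier, rep2$outlier)
    expect_identical(rep1$conditional_accuracy, rep2$conditional_accuracy)
    expect_equal(rep1$auc, rep2$auc, tolerance = 1e-12)
    expect_identical(glance(rep1)$auc, rep1$auc)
  })
})
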