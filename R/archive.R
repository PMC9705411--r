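#' Save and load a classifier archive
#'
#' A classifier is persisted as a documented directory bundle: the frozen
#' feature list (`features.tsv`), the calibration coefficients
#' (`calibration.tsv`), the class order, winning hyperparameters and a
#' schema version (`archive.json`), plus the fitted model object
#' (`model.rds`). `load_classifier()` refuses archives written with a
#' newer schema than it understands.
#'
#' @param clf A `methyl_classifier` from [build_classifier()].
#' @param dir Archive directory (created if needed).
#' @return `save_classifier()` the directory, invisibly;
#'   `load_classifier()` a `methyl_classifier`.
#' @export
save_classifier <- function(clf, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_feature_set(clf$model$feature_set, file.path(dir, "features.tsv"))
  cal <- clf$calibration
  cal_tbl <- tibble::as_tibble(
    rbind(`(Intercept)` = cal$intercepts, cal$coefficients),
    rownames = "term"
  )
  readr::write_tsv(cal_tbl, file.path(dir, "calibration.tsv"))
  meta <- list(
    schema_version = clf$schema_version,
    family = clf$model$family,
    params = clf$model$params[setdiff(names(clf$model$params), "family")],
    classes = clf$classes,
    lambda = cal$lambda,
    package_version = as.character(utils::packageVersion("methclass"))
  )
  jsonlite::write_json(meta, file.path(dir, "archive.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  saveRDS(clf$model$fit, file.path(dir, "model.rds"))
  invisible(dir)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "archive.json"),
    simplifyVector = TRUE
  )
  if (meta$schema_version > 1) {
    stop(
      "archive schema ", meta$schema_version,
      " is newer than this package supports",
      call. = FALSE
    )
  }
  fs <- read_feature_set(file.path(dir, "features.tsv"))
  cal_tbl <- readr::read_tsv(file.path(dir, "calibration.tsv"),
    show_col_types = FALSE, progress = FALSE
  )
  classes <- meta$classes
  co <- as.matrix(cal_tbl[-1])[, classes, drop = FALSE]
  rownames(co) <- cal_tbl$term
  calibration <- new_calibration_model(
    coefficients = co[-1, , drop = FALSE],
    intercepts = co[1, ],
    classes = classes,
    lambda = meta$lambda
  )
  fit <- readRDS(file.path(dir, "model.rds"))
  model <- structure(
    list(
      family = meta$family,
      params = c(list(family = meta$family), meta$params),
      fit = fit, feature_set = fs, classes = classes
    ),
    class = "methyl_model"
  )
  structure(
    list(
      model = model, calibration = calibration, cv = NULL,
      classes = classes, schema_version = as.integer(meta$schema_version)
    ),
    class = "methyl_classifier"
  )
}
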