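#' Assemble a training set with an explicit Unknown outlier class
#'
#' Combines the labeled reference cohort with a random draw from a diverse
#' pool of out-of-scope samples. From every pool category a fraction
#' (default 5%) of samples is drawn without replacement (rounded to the
#' nearest integer, at least one per non-empty category) and labeled
#' `"Unknown"`; training on this class lets the classifier reject divergent
#' profiles instead of force-assigning them.
#'
#' @param reference_bm A [beta_matrix()] of the reference cohort.
#' @param reference_labels Tibble with columns `sample_id`, `label` (e.g. the
#'   `clusters` element of [exclude_noise()] with `cluster` renamed, or any
#'   per-sample class labels) covering all reference samples.
#' @param pool_bm A `beta_matrix` of the outlier pool, on a probe set
#'   compatible with `reference_bm` (merge platforms first if needed).
#' @param pool_sheet Sample sheet covering `pool_bm` with a `category`
#'   column.
#' @param per_category_fraction Fraction of each pool category to draw.
#' @param seed Integer seed for the draw.
#' @return A `training_set`: list with `beta` (merged matrix restricted to
#'   the shared probe set) and `sheet` (tibble `sample_id`, `label`,
#'   `provenance`).
#' @export
assemble_training_set <- function(reference_bm, reference_labels,
                                  pool_bm = NULL, pool_sheet = NULL,
                                  per_category_fraction = 0.05, seed = 42L) {
  lbl <- tibble::as_tibble(reference_labels)
  if ("cluster" %in% names(lbl) && !"label" %in% names(lbl)) {
    lbl <- dplyr::rename(lbl, label = "cluster")
  }
  missing <- setdiff(sample_ids(reference_bm), lbl$sample_id)
  if (length(missing) > 0) {
    stop("labels missing for reference samples", call. = FALSE)
  }
  lbl <- lbl[match(sample_ids(reference_bm), lbl$sample_id), c("sample_id", "label")]
  lbl$provenance <- "reference"

  if (is.null(pool_bm) || (n_samples(pool_bm) == 0) || per_category_fraction == 0) {
    warning("no Unknown pool: training set has no Unknown class", call. = FALSE)
    ts <- list(beta = reference_bm, sheet = lbl)
    class(ts) <- "training_set"
    return(validate_training_set(ts))
  }
  stopifnot(!is.null(pool_sheet))
  pool_sheet <- pool_sheet[match(sample_ids(pool_bm), pool_sheet$sample_id), ]
  if (anyNA(pool_sheet$sample_id)) {
    stop("pool sheet does not cover all pool samples", call. = FALSE)
  }

  picked <- withr::with_seed(seed, {
    split(pool_sheet$sample_id, pool_sheet$category) |>
      purrr::map(function(ids) {
        ids <- sort(ids) # draw depends on ids, not input order
        n_draw <- max(1L, round(per_category_fraction * length(ids)))
        sample(ids, n_draw)
      }) |>
      purrr::list_c()
  })
  pool_part <- bm_subset(pool_bm, samples = sort(picked))
  merged <- merge_platforms(reference_bm, pool_part)
  sheet <- dplyr::bind_rows(
    lbl,
    tibble::tibble(
      sample_id = sample_ids(pool_part),
      label = "Unknown",
      provenance = "unknown_pool"
    )
  )
  ts <- list(beta = merged, sheet = sheet)
  class(ts) <- "training_set"
  validate_training_set(ts)
}

#' @rdname assemble_training_set
#' @param ts A `training_set`.
#' @export
validate_training_set <- function(ts) {
  stopifnot(identical(sample_ids(ts$beta), ts$sheet$sample_id))
  sizes <- table(ts$sheet$label)
  small <- names(sizes)[sizes < 2]
  if (length(small) > 0) {
    stop(
      "every class needs >= 2 members; too small: ",
      paste(small, collapse = ", "),
      call. = FALSE
    )
  }
  unk <- ts$sheet$label == "Unknown"
  if (any(unk & ts$sheet$provenance != "unknown_pool")) {
    stop("Unknown members must come from the unknown pool", call. = FALSE)
  }
  ts
}

#' @export
print.training_set <- function(x, ...) {
  cat("<training_set> ", n_samples(x$beta), " samples, ",
    n_probes(x$beta), " probes\n",
    sep = ""
  )
  print(table(x$sheet$label))
  invisible(x)
}
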