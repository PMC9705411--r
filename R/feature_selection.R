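#' Select the most variant CpG probes
#'
#' Ranks probes by sample variance of their beta values (denominator n - 1)
#' and keeps the `k` most variant, the feature-selection step applied before
#' both class discovery and classifier training (default k = 20000). Ties
#' are broken by input probe order; if `k` is at least the number of probes,
#' all probes are returned in variance order.
#'
#' @param bm A [beta_matrix()] with at least two samples.
#' @param k Number of probes to keep (positive integer).
#' @return A `feature_set`: a tibble with columns `probe_id` and `variance`,
#'   ordered by non-increasing variance, carrying `k` as an attribute.
#' @examples
#' co <- simulate_cohort(sim_config(
#'   n_classes = 2, samples_per_class = 5, n_probes = 200,
#'   n_informative = 20, n_outlier_classes = 0
#' ))
#' fs <- select_top_variant(co$beta, k = 50)
#' head(fs)
#' @export
select_top_variant <- function(bm, k = 20000) {
  stopifnot(k >= 1)
  if (n_samples(bm) < 2) {
    stop("variance undefined for a single-sample matrix", call. = FALSE)
  }
  if (n_probes(bm) == 0) stop("empty beta matrix", call. = FALSE)
  v <- row_variances(bm$values)
  # order() with a single key is stable, so ties keep input probe order
  ord <- order(v, decreasing = TRUE)
  keep <- ord[seq_len(min(k, length(v)))]
  fs <- tibble::tibble(
    probe_id = probe_ids(bm)[keep],
    variance = unname(v[keep])
  )
  attr(fs, "k") <- as.integer(k)
  class(fs) <- c("feature_set", class(fs))
  fs
}

# rowwise sample variance without forming apply() overhead
row_variances <- function(m) {
  n <- ncol(m)
  mu <- rowMeans(m)
  (rowSums(m * m) - n * mu * mu) / (n - 1)
}

#' Project a beta matrix onto a feature set
#'
#' Restricts a matrix to the probes of a `feature_set`, in feature-set order.
#' Used to apply a training-fold feature selection to its validation fold and
#' to project new samples onto a frozen classifier feature list.
#'
#' @param bm A [beta_matrix()].
#' @param fs A `feature_set` from [select_top_variant()] (or a character
#'   vector of probe ids).
#' @return A `beta_matrix` with rows in feature-set order.
#' @export
project_features <- function(bm, fs) {
  probes <- if (is.character(fs)) fs else fs$probe_id
  missing <- setdiff(probes, probe_ids(bm))
  if (length(missing) > 0) {
    stop(
      "feature-set probes missing from matrix: ",
      paste(utils::head(missing, 10), collapse = ", "),
      if (length(missing) > 10) sprintf(" (and %d more)", length(missing) - 10),
      call. = FALSE
    )
  }
  bm_subset(bm, probes = probes)
}

#' @rdname select_top_variant
#' @param fs A `feature_set`.
#' @param path Output TSV path.
#' @export
write_feature_set <- function(fs, path) {
  readr::write_tsv(tibble::as_tibble(fs[c("probe_id", "variance")]), path)
  invisible(path)
}

#' @rdname select_top_variant
#' @export
read_feature_set <- function(path) {
  fs <- readr::read_tsv(path, col_types = readr::cols(
    probe_id = readr::col_character(),
    variance = readr::col_double()
  ), progress = FALSE)
  class(fs) <- c("feature_set", class(fs))
  fs
}
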