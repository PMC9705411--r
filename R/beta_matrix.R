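#' Construct a beta-value matrix
#'
#' The central data container of the package: a numeric matrix of methylation
#' beta values (rows = CpG probes, columns = samples, values in \[0, 1\]) with
#' a per-sample platform tag. All pipeline stages consume and produce this
#' object.
#'
#' @param values Numeric matrix with unique rownames (probe ids) and unique
#'   colnames (sample ids); all values finite and in \[0, 1\].
#' @param platform Character vector of per-sample platform tags, one of
#'   `"450k"`, `"EPIC"`, `"synthetic"`. Recycled if length 1.
#' @return A `beta_matrix` object.
#' @examples
#' m <- matrix(runif(6), 3, 2,
#'   dimnames = list(paste0("cg", 1:3), c("s1", "s2")))
#' bm <- beta_matrix(m)
#' n_probes(bm)
#' @export
beta_matrix <- function(values, platform = "synthetic") {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have probe rownames and sample colnames", call. = FALSE)
  }
  platform <- as.character(platform)
  if (length(platform) == 1L) platform <- rep(platform, ncol(values))
  if (length(platform) != ncol(values)) {
    stop("`platform` must have one tag per sample", call. = FALSE)
  }
  names(platform) <- colnames(values)
  bm <- structure(
    list(values = values, platform = platform),
    class = "beta_matrix"
  )
  validate_beta_matrix(bm)
}

#' @rdname beta_matrix
#' @param bm A `beta_matrix`.
#' @export
validate_beta_matrix <- function(bm) {
  v <- bm$values
  if (anyNA(v) || any(!is.finite(v))) {
    stop("beta values must all be finite", call. = FALSE)
  }
  if (any(v < 0 | v > 1)) {
    stop("beta out of range: values must lie in [0, 1]", call. = FALSE)
  }
  if (anyDuplicated(rownames(v))) stop("duplicate probe ids", call. = FALSE)
  if (anyDuplicated(colnames(v))) stop("duplicate sample ids", call. = FALSE)
  allowed <- c("450k", "EPIC", "synthetic")
  if (!all(bm$platform %in% allowed)) {
    stop("platform tags must be one of: ", paste(allowed, collapse = ", "),
      call. = FALSE
    )
  }
  bm
}

#' @rdname beta_matrix
#' @export
probe_ids <- function(bm) rownames(bm$values)

#' @rdname beta_matrix
#' @export
sample_ids <- function(bm) colnames(bm$values)

#' @rdname beta_matrix
#' @export
n_probes <- function(bm) nrow(bm$values)

#' @rdname beta_matrix
#' @export
n_samples <- function(bm) ncol(bm$values)

#' Subset a beta matrix by probe and/or sample ids
#'
#' Order of the result follows the requested id vectors, so the same helpers
#' serve both filtering (keep input order) and projection (impose an order).
#'
#' @param bm A `beta_matrix`.
#' @param probes,samples Character vectors of ids to retain (`NULL` = all).
#' @return A `beta_matrix`.
#' @export
bm_subset <- function(bm, probes = NULL, samples = NULL) {
  v <- bm$values
  if (!is.null(probes)) {
    missing <- setdiff(probes, rownames(v))
    if (length(missing) > 0) {
      stop(
        "probes absent from matrix: ",
        paste(utils::head(missing, 5), collapse = ", "),
        if (length(missing) > 5) sprintf(" (and %d more)", length(missing) - 5),
        call. = FALSE
      )
    }
    v <- v[probes, , drop = FALSE]
  }
  if (!is.null(samples)) {
    missing <- setdiff(samples, colnames(v))
    if (length(missing) > 0) {
      stop(
        "samples absent from matrix: ",
        paste(utils::head(missing, 5), collapse = ", "),
        call. = FALSE
      )
    }
    v <- v[, samples, drop = FALSE]
  }
  structure(
    list(values = v, platform = bm$platform[colnames(v)]),
    class = "beta_matrix"
  )
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat(
    "<beta_matrix> ", n_probes(x), " probes x ", n_samples(x), " samples\n",
    sep = ""
  )
  plat <- table(x$platform)
  cat("platforms:", paste(names(plat), plat, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.beta_matrix <- function(x) dim(x$values)

#' Convert a beta matrix to a long tibble
#'
#' @param x A `beta_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `probe_id`, `sample_id`, `beta`.
#' @importFrom tibble as_tibble
#' @export
as_tibble.beta_matrix <- function(x, ...) {
  tibble::tibble(
    probe_id = rep(rownames(x$values), times = ncol(x$values)),
    sample_id = rep(colnames(x$values), each = nrow(x$values)),
    beta = as.vector(x$values)
  )
}
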