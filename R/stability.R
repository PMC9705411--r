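#' Downsampling stability of a t-SNE embedding
#'
#' Quantifies how stable the 2-D structure of a cohort is under random
#' downsampling: in each iteration a fraction of the samples (default 80%)
#' is drawn without replacement and re-embedded, warm-started at the
#' reference coordinates of the retained samples so both embeddings share an
#' orientation frame, and the Pearson correlation between the concatenated
#' (x, y) reference coordinates and the re-embedded coordinates of the
#' retained samples is recorded. A tight distribution of correlations near 1
#' indicates stable classes.
#'
#' @param bm A [beta_matrix()] (already projected onto the analysis feature
#'   set) whose samples match `reference_emb`.
#' @param reference_emb A `methyl_embedding` of all samples of `bm`.
#' @param n_iterations Number of downsampling iterations (default 300).
#' @param fraction Fraction of samples retained per iteration, in (0, 1\].
#' @param seed Integer seed governing the downsampling draws.
#' @param iterations Gradient-descent iterations per re-embedding. Warm
#'   starts converge quickly, so this can be far below the reference
#'   embedding's iteration count.
#' @param perplexity Perplexity of the re-embeddings (defaults to the
#'   reference embedding's perplexity, reduced if the subsample is too small).
#' @return A `stability_report` with elements `per_iteration_r`, `median_r`,
#'   `range_r`, `fraction`, `n_iterations`; see [tidy.stability_report()].
#' @export
stability_downsample <- function(bm, reference_emb, n_iterations = 300,
                                 fraction = 0.8, seed = 42L,
                                 iterations = 300, perplexity = NULL) {
  if (fraction <= 0 || fraction > 1) {
    stop("fraction must be in (0, 1]", call. = FALSE)
  }
  ids <- sample_ids(bm)
  missing <- setdiff(ids, reference_emb$sample_id)
  if (length(missing) > 0) {
    stop("reference embedding does not cover all samples", call. = FALSE)
  }
  ref <- reference_emb[match(ids, reference_emb$sample_id), ]
  ref_coords <- as.matrix(ref[, c("x", "y")])
  rownames(ref_coords) <- ids
  n <- length(ids)
  n_keep <- floor(fraction * n)
  if (is.null(perplexity)) {
    p <- attr(reference_emb, "params")$perplexity
    perplexity <- if (is.null(p)) 20 else p
  }
  perplexity <- min(perplexity, floor((n_keep - 1) / 3) - 1e-9)

  r <- withr::with_seed(seed, {
    vapply(seq_len(n_iterations), function(i) {
      keep <- sort(sample.int(n, n_keep))
      sub <- bm_subset(bm, samples = ids[keep])
      emb <- tsne_embed(sub,
        perplexity = perplexity, iterations = iterations,
        init = ref_coords[keep, , drop = FALSE]
      )
      stats::cor(
        c(ref_coords[keep, 1], ref_coords[keep, 2]),
        c(emb$x, emb$y)
      )
    }, numeric(1))
  })

  structure(
    list(
      per_iteration_r = r,
      median_r = stats::median(r),
      range_r = range(r),
      fraction = fraction,
      n_iterations = n_iterations
    ),
    class = "stability_report"
  )
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf(
    "<stability_report> %d iterations at %.0f%% downsampling\nmedian r = %.3f (range %.3f to %.3f)\n",
    x$n_iterations, 100 * x$fraction, x$median_r, x$range_r[1], x$range_r[2]
  ))
  invisible(x)
}
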