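# Exact t-SNE (Student-t stochastic neighbor embedding), O(n^2) per
# iteration. Written for cohort-scale inputs (hundreds to low thousands of
# samples), with optional warm starting so that downsampled re-embeddings
# share the reference frame (raw t-SNE is rotation/sign unidentifiable).

# Per-point conditional probabilities at a fixed target perplexity, found by
# binary search on the Gaussian precision beta_i.
.tsne_input_probs <- function(D2, perplexity, tol = 1e-5, max_tries = 50L) {
  n <- nrow(D2)
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    beta <- 1
    beta_min <- -Inf
    beta_max <- Inf
    d <- D2[i, -i]
    for (tr in seq_len(max_tries)) {
      p <- exp(-d * beta)
      sum_p <- sum(p)
      if (sum_p == 0) {
        h <- 0
        p[] <- 0
      } else {
        h <- log(sum_p) + beta * sum(d * p) / sum_p
        p <- p / sum_p
      }
      diff <- h - target
      if (abs(diff) < tol) break
      if (diff > 0) {
        beta_min <- beta
        beta <- if (is.finite(beta_max)) (beta + beta_max) / 2 else beta * 2
      } else {
        beta_max <- beta
        beta <- if (is.finite(beta_min)) (beta + beta_min) / 2 else beta / 2
      }
    }
    P[i, -i] <- p
  }
  P
}

.squared_dists <- function(X) {
  s <- rowSums(X * X)
  D2 <- outer(s, s, "+") - 2 * tcrossprod(X)
  D2[D2 < 0] <- 0
  diag(D2) <- 0
  D2
}

# Core optimizer. X: samples x features. init: optional n x 2 warm-start
# coordinates (skips early exaggeration and random init).
.tsne <- function(X, perplexity, iterations, seed = 42L, init = NULL,
                  eta = 200, exaggeration = 12, exaggeration_stop = 250L,
                  momentum_start = 0.5, momentum_final = 0.8,
                  momentum_switch = 250L) {
  n <- nrow(X)
  if (n - 1 < 3 * perplexity) {
    stop("too few samples for perplexity ", perplexity,
      ": need n > 3 * perplexity",
      call. = FALSE
    )
  }
  P <- .tsne_input_probs(.squared_dists(X), perplexity)
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)

  warm <- !is.null(init)
  Y <- if (warm) {
    stopifnot(nrow(init) == n, ncol(init) == 2)
    as.matrix(init)
  } else {
    withr::with_seed(seed, matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2))
  }
  if (!warm) P_run <- P * exaggeration

  V <- matrix(0, n, 2)
  gains <- matrix(1, n, 2)
  for (it in seq_len(iterations)) {
    Peff <- if (!warm && it <= exaggeration_stop) P_run else P
    num <- 1 / (1 + .squared_dists(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (Peff - Q) * num
    G <- 4 * (diag(rowSums(L)) %*% Y - L %*% Y)
    mom <- if (it <= momentum_switch) momentum_start else momentum_final
    gains <- ifelse(sign(G) != sign(V), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    V <- mom * V - eta * gains * G
    Y <- Y + V
    if (!warm) Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}

#' Embed samples in two dimensions with t-SNE
#'
#' Computes a two-dimensional t-SNE embedding of the samples of a beta
#' matrix (probes as features, Euclidean distances). Defaults follow common
#' methylation-profiling practice: perplexity 20 and 4000 gradient-descent
#' iterations. The result is deterministic for a fixed seed.
#'
#' @param bm A [beta_matrix()], typically already projected onto the top
#'   variant probes with [project_features()].
#' @param perplexity t-SNE perplexity; requires `n_samples > 3 * perplexity`.
#' @param iterations Number of gradient-descent iterations.
#' @param seed Integer seed for the random initialization.
#' @param init Optional n x 2 matrix of warm-start coordinates (used by the
#'   downsampling stability loop to keep a shared orientation frame).
#' @return A `methyl_embedding`: tibble with columns `sample_id`, `x`, `y`;
#'   the parameters are stored in the `params` attribute.
#' @seealso [dbscan_cluster()], [stability_downsample()], [autoplot.methyl_embedding()]
#' @export
tsne_embed <- function(bm, perplexity = 20, iterations = 4000, seed = 42L,
                       init = NULL) {
  X <- t(bm$values)
  Y <- .tsne(X,
    perplexity = perplexity, iterations = iterations,
    seed = seed, init = init
  )
  emb <- tibble::tibble(sample_id = sample_ids(bm), x = Y[, 1], y = Y[, 2])
  attr(emb, "params") <- list(
    perplexity = perplexity, iterations = iterations, seed = seed,
    warm_start = !is.null(init)
  )
  class(emb) <- c("methyl_embedding", class(emb))
  emb
}

#' @rdname tsne_embed
#' @param emb A `methyl_embedding`.
#' @param path Output TSV path.
#' @export
write_embedding <- function(emb, path) {
  readr::write_tsv(tibble::as_tibble(emb[c("sample_id", "x", "y")]), path)
  invisible(path)
}
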