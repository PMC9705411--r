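# Independent brute-force oracles, deliberately written with different
# algorithms than the package implementations they check.

# DBSCAN by transitive closure of the core-point adjacency matrix.
# Clusters are numbered by their minimal core index (the package's
# discovery order); border points go to the lowest-numbered cluster with a
# core point in range, noise stays 0.
bf_dbscan <- function(coords, eps, min_pts) {
  n <- nrow(coords)
  D <- as.matrix(stats::dist(coords))
  A <- D <= eps
  core <- rowSums(A) >= min_pts # self counted (diagonal TRUE)
  labels <- integer(n)
  if (any(core)) {
    # reachability among cores: repeated boolean multiplication
    Acc <- A & outer(core, core, "&")
    reach <- Acc
    repeat {
      nxt <- reach | ((reach %*% Acc) > 0)
      if (identical(nxt, reach)) break
      reach <- nxt
    }
    comp_of <- rep(NA_integer_, n)
    cl <- 0L
    for (i in which(core)) {
      if (is.na(comp_of[i])) {
        cl <- cl + 1L
        comp_of[reach[i, ] & core] <- cl
        comp_of[i] <- cl
      }
    }
    labels[core] <- comp_of[core]
    for (j in which(!core)) {
      near_cores <- which(core & A[j, ])
      if (length(near_cores) > 0) labels[j] <- min(comp_of[near_cores])
    }
  }
  labels
}

# AUC as the Mann-Whitney concordance probability over all pos/neg pairs,
# ties counted one half.
bf_auc <- function(truth, score) {
  pos <- score[truth]
  neg <- score[!truth]
  pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(pairs)
}

# top-k probes by variance, stable ties, via apply + order
bf_top_variant <- function(m, k) {
  v <- apply(m, 1, stats::var)
  rownames(m)[order(-v)][seq_len(min(k, nrow(m)))]
}

# tiny labeled beta matrix from an explicit value matrix
toy_bm <- function(values, probe_prefix = "cg", sample_prefix = "s") {
  if (is.null(rownames(values))) {
    rownames(values) <- paste0(probe_prefix, seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- paste0(sample_prefix, seq_len(ncol(values)))
  }
  beta_matrix(values)
}

# wrap raw coordinates as a methyl_embedding
toy_embedding <- function(coords, ids = NULL) {
  if (is.null(ids)) ids <- paste0("s", seq_len(nrow(coords)))
  emb <- tibble::tibble(sample_id = ids, x = coords[, 1], y = coords[, 2])
  class(emb) <- c("methyl_embedding", class(emb))
  emb
}

# small well-separated cohort for discovery tests (cheap defaults)
small_cohort <- function(seed = 11, n_classes = 3, samples_per_class = 25,
                         n_probes = 3000, n_informative = NULL,
                         n_outlier_classes = 0, ...) {
  if (is.null(n_informative)) {
    n_informative <- min(150, floor(0.5 * n_probes / (n_classes + n_outlier_classes + 1)))
  }
  simulate_cohort(sim_config(
    n_classes = n_classes, samples_per_class = samples_per_class,
    n_probes = n_probes, n_informative = n_informative,
    n_outlier_classes = n_outlier_classes,
    n_outlier_shared = n_informative, seed = seed, ...
  ))
}

# adjusted Rand index (mclust's implementation is used as the external
# reference where tests need partition agreement)
ari <- function(a, b) mclust::adjustedRandIndex(a, b)
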