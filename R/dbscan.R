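# Density-based spatial clustering (DBSCAN) on 2-D embedding coordinates.
# Classic semantics: a point is a core point when at least min_pts points
# (itself included) lie within distance eps; clusters grow by expanding core
# points; non-core points within eps of a core point become border points of
# that cluster; everything else is noise.

.dbscan_labels <- function(coords, eps, min_pts) {
  n <- nrow(coords)
  D <- as.matrix(stats::dist(coords))
  nbrs <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  core <- vapply(nbrs, length, integer(1)) >= min_pts
  labels <- integer(n) # 0 = unvisited/noise
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- setdiff(nbrs[[i]], i)
    while (length(queue) > 0) {
      j <- queue[[1]]
      queue <- queue[-1]
      if (labels[j] == 0L) {
        labels[j] <- cl
        if (core[j]) queue <- c(queue, setdiff(nbrs[[j]], j))
      }
    }
  }
  labels
}

#' Estimate the DBSCAN eps radius from the k-nearest-neighbor distances
#'
#' Computes the distance of every point to its `min_pts`-th nearest
#' neighbor (self included) and derives a density threshold from the
#' distribution. The default `"fence"` method returns the Tukey upper
#' fence (Q3 + 3 IQR, capped at the curve maximum): points whose
#' neighborhood is wider than the fence are density outliers, everything
#' below stays core. On t-SNE coordinates this is markedly more robust
#' than the classical maximum-curvature knee of the sorted distance curve
#' (`method = "knee"`), which undershoots on smooth curves and fragments
#' genuine clusters; the knee is kept for comparison.
#'
#' @param emb A `methyl_embedding` (or a two-column coordinate matrix).
#' @param min_pts Minimum cluster size used by DBSCAN.
#' @param method `"fence"` (default) or `"knee"`.
#' @return A positive scalar eps.
#' @export
estimate_eps <- function(emb, min_pts = 6, method = c("fence", "knee")) {
  method <- match.arg(method)
  coords <- .emb_coords(emb)
  D <- as.matrix(stats::dist(coords))
  kdist <- apply(D, 1, function(d) sort(d)[min_pts]) # self at rank 1
  y <- sort(kdist)
  n <- length(y)
  if (n < 3 || y[n] == y[1]) {
    return(max(y[n], .Machine$double.eps))
  }
  eps <- if (method == "fence") {
    q <- stats::quantile(y, c(0.25, 0.75), names = FALSE)
    min(y[n], q[2] + 3 * (q[2] - q[1]))
  } else {
    # distance below the end-to-end chord, on axes normalized to [0, 1];
    # the maximum marks the elbow where the curve starts its steep rise
    u <- (seq_len(n) - 1) / (n - 1)
    v <- (y - y[1]) / (y[n] - y[1])
    y[which.max(u - v)]
  }
  max(eps, .Machine$double.eps)
}

#' Cluster an embedding with DBSCAN
#'
#' Runs density-based clustering on the 2-D t-SNE coordinates with the
#' minimum-cluster-size parameter `min_pts` (default 6). Samples in no dense
#' region are labeled `"NOISE"`; clusters are labeled `class_1, class_2, ...`
#' in order of discovery. When `eps = "auto"` the radius is estimated with
#' [estimate_eps()].
#'
#' @param emb A `methyl_embedding` from [tsne_embed()].
#' @param min_pts Minimum number of points (self included) within `eps` for
#'   a core point; also the minimum cluster size.
#' @param eps Neighborhood radius, or `"auto"`.
#' @return A `cluster_assignment`: tibble with columns `sample_id`,
#'   `cluster`; `eps` and `min_pts` are stored as attributes.
#' @export
dbscan_cluster <- function(emb, min_pts = 6, eps = "auto") {
  coords <- .emb_coords(emb)
  if (identical(eps, "auto")) eps <- estimate_eps(emb, min_pts = min_pts)
  stopifnot(is.numeric(eps), eps > 0)
  labels <- .dbscan_labels(coords, eps = eps, min_pts = min_pts)
  ca <- tibble::tibble(
    sample_id = emb$sample_id,
    cluster = ifelse(labels == 0L, "NOISE", paste0("class_", labels))
  )
  attr(ca, "eps") <- eps
  attr(ca, "min_pts") <- min_pts
  class(ca) <- c("cluster_assignment", class(ca))
  ca
}

#' Drop noise samples from a beta matrix and its cluster assignment
#'
#' Samples labeled `"NOISE"` by [dbscan_cluster()] are excluded from both
#' the matrix and the assignment, producing the final reference set used for
#' classifier training. Class labels of the retained samples are unchanged.
#'
#' @param bm A [beta_matrix()].
#' @param ca A `cluster_assignment` covering all samples of `bm`.
#' @return A list with elements `beta` and `clusters`.
#' @export
exclude_noise <- function(bm, ca) {
  missing <- setdiff(sample_ids(bm), ca$sample_id)
  if (length(missing) > 0) {
    stop("cluster assignment does not cover all samples", call. = FALSE)
  }
  ca <- ca[match(sample_ids(bm), ca$sample_id), ]
  keep <- ca$cluster != "NOISE"
  if (!any(keep)) warning("all samples labeled NOISE", call. = FALSE)
  list(
    beta = bm_subset(bm, samples = sample_ids(bm)[keep]),
    clusters = ca[keep, ]
  )
}

#' @rdname dbscan_cluster
#' @param ca A `cluster_assignment`.
#' @param path Output TSV path.
#' @export
write_clusters <- function(ca, path) {
  readr::write_tsv(tibble::as_tibble(ca[c("sample_id", "cluster")]), path)
  invisible(path)
}

.emb_coords <- function(emb) {
  if (is.matrix(emb)) {
    stopifnot(ncol(emb) == 2)
    return(emb)
  }
  as.matrix(emb[, c("x", "y")])
}
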