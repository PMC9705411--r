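#' Remove sex-chromosome, SNP-associated and cross-reactive probes
#'
#' Mirrors the standard pre-analysis cleanup of Illumina methylation arrays:
#' probes on chrX/chrY, probes overlapping common SNPs, and probes with
#' reported cross-reactivity are dropped. Probe order of the retained set is
#' preserved, which keeps downstream variance tie-breaking deterministic.
#'
#' @param bm A [beta_matrix()].
#' @param manifest Probe-manifest tibble annotating every probe of `bm`.
#' @return A `beta_matrix` restricted to clean autosomal probes.
#' @export
filter_probes <- function(bm, manifest) {
  manifest <- validate_probe_manifest(manifest)
  missing <- setdiff(probe_ids(bm), manifest$probe_id)
  if (length(missing) > 0) {
    stop(
      "probes missing from manifest: ",
      paste(utils::head(missing, 5), collapse = ", "),
      call. = FALSE
    )
  }
  man <- manifest[match(probe_ids(bm), manifest$probe_id), ]
  drop <- man$chromosome %in% c("chrX", "chrY") |
    man$snp_flag | man$cross_reactive_flag
  keep <- probe_ids(bm)[!drop]
  if (length(keep) == 0) {
    warning("all probes removed by filtering", call. = FALSE)
  }
  bm_subset(bm, probes = keep)
}

#' Remove samples failing detection-p QC
#'
#' A sample is removed when the fraction of its probes with detection
#' p-value at or above `detection_p_threshold` strictly exceeds
#' `sample_fail_fraction` (default 0.05, i.e. the conventional perc = 5
#' rule). The boundary is a strict inequality: a sample with exactly the
#' threshold fraction of failing probes is retained.
#'
#' @param bm A [beta_matrix()].
#' @param detection_p Numeric matrix of detection p-values, same shape and
#'   dimnames as `bm$values`.
#' @param sample_fail_fraction Maximum tolerated fraction of failing probes,
#'   in (0, 1).
#' @param detection_p_threshold Detection p-value above which a probe call
#'   fails, in (0, 1).
#' @return A `beta_matrix` with failing samples removed.
#' @export
qc_filter_samples <- function(bm, detection_p,
                              sample_fail_fraction = 0.05,
                              detection_p_threshold = 0.05) {
  stopifnot(
    sample_fail_fraction > 0, sample_fail_fraction < 1,
    detection_p_threshold > 0, detection_p_threshold < 1
  )
  if (!identical(dim(detection_p), dim(bm$values))) {
    stop("detection_p must have the same shape as the beta matrix", call. = FALSE)
  }
  fail_frac <- colMeans(detection_p >= detection_p_threshold)
  keep <- sample_ids(bm)[fail_frac <= sample_fail_fraction]
  if (length(keep) < n_samples(bm)) {
    message(
      n_samples(bm) - length(keep),
      " sample(s) removed by detection-p QC"
    )
  }
  bm_subset(bm, samples = keep)
}

#' Merge two beta matrices across array platforms
#'
#' Restricts both inputs to their shared probe set (as when combining 450k
#' and EPIC arrays, which share a large probe subset) and concatenates the
#' samples, keeping per-sample platform tags. Probe order follows the first
#' input; sample order is first input then second.
#'
#' @param a,b [beta_matrix()] objects, already probe-filtered.
#' @return A merged `beta_matrix` over the probe intersection.
#' @export
merge_platforms <- function(a, b) {
  shared <- intersect(probe_ids(a), probe_ids(b))
  if (length(shared) == 0) stop("empty probe intersection", call. = FALSE)
  dup <- intersect(sample_ids(a), sample_ids(b))
  if (length(dup) > 0) {
    stop(
      "duplicate sample ids across inputs: ",
      paste(utils::head(dup, 5), collapse = ", "),
      call. = FALSE
    )
  }
  va <- a$values[shared, , drop = FALSE]
  vb <- b$values[shared, , drop = FALSE]
  beta_matrix(
    cbind(va, vb),
    platform = c(a$platform, b$platform)
  )
}
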