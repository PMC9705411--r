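#' Read and write beta matrices, probe manifests and sample sheets
#'
#' Beta matrices are delimited text with a header row of sample ids and a
#' first column of probe ids (the public methylation-matrix convention);
#' `orientation = "samples_by_probes"` accepts transposed input. Manifests are
#' TSV with columns `probe_id, chromosome, position, snp_flag,
#' cross_reactive_flag` (flags 0/1). Sample sheets are CSV with columns
#' `sample_id, label, cohort, category`.
#'
#' @param path File path.
#' @param orientation `"probes_by_samples"` (default) or `"samples_by_probes"`.
#' @param platform Per-sample platform tags (recycled if length 1).
#' @return `read_beta_matrix()` a [beta_matrix()]; `read_probe_manifest()` and
#'   `read_sample_sheet()` tibbles.
#' @name methyl_io
NULL

#' @rdname methyl_io
#' @export
read_beta_matrix <- function(path,
                             orientation = c("probes_by_samples", "samples_by_probes"),
                             platform = "synthetic") {
  orientation <- match.arg(orientation)
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
    name_repair = "minimal"
  )
  if (ncol(df) < 2) stop("malformed header: need id column plus data", call. = FALSE)
  if (anyDuplicated(names(df))) stop("malformed header: duplicate ids", call. = FALSE)
  ids <- as.character(df[[1]])
  vals <- df[, -1, drop = FALSE]
  numeric_cols <- vapply(vals, is.numeric, logical(1))
  if (!all(numeric_cols)) {
    stop("non-numeric beta values in column(s): ",
      paste(names(vals)[!numeric_cols], collapse = ", "),
      call. = FALSE
    )
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  if (orientation == "samples_by_probes") m <- t(m)
  beta_matrix(m, platform = platform)
}

#' @rdname methyl_io
#' @param bm A `beta_matrix`.
#' @export
write_beta_matrix <- function(bm, path) {
  df <- tibble::as_tibble(bm$values, rownames = "probe_id")
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname methyl_io
#' @export
read_probe_manifest <- function(path) {
  man <- readr::read_tsv(path, col_types = readr::cols(
    probe_id = readr::col_character(),
    chromosome = readr::col_character(),
    position = readr::col_integer(),
    snp_flag = readr::col_integer(),
    cross_reactive_flag = readr::col_integer()
  ), progress = FALSE)
  man$snp_flag <- as.logical(man$snp_flag)
  man$cross_reactive_flag <- as.logical(man$cross_reactive_flag)
  validate_probe_manifest(man)
}

#' @rdname methyl_io
#' @param manifest A probe-manifest tibble.
#' @export
write_probe_manifest <- function(manifest, path) {
  out <- manifest
  out$snp_flag <- as.integer(out$snp_flag)
  out$cross_reactive_flag <- as.integer(out$cross_reactive_flag)
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname methyl_io
#' @export
validate_probe_manifest <- function(manifest) {
  req <- c("probe_id", "chromosome", "position", "snp_flag", "cross_reactive_flag")
  if (!all(req %in% names(manifest))) {
    stop("manifest must have columns: ", paste(req, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(manifest$probe_id)) stop("duplicate probe ids in manifest", call. = FALSE)
  allowed <- c(paste0("chr", 1:22), "chrX", "chrY")
  bad <- setdiff(unique(manifest$chromosome), allowed)
  if (length(bad) > 0) {
    stop("chromosome outside chr1..chr22/chrX/chrY: ", paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  if (any(manifest$position < 0)) stop("negative probe position", call. = FALSE)
  tibble::as_tibble(manifest)
}

#' @rdname methyl_io
#' @export
read_sample_sheet <- function(path) {
  sheet <- readr::read_csv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    label = readr::col_character(),
    cohort = readr::col_character(),
    category = readr::col_character()
  ), progress = FALSE)
  validate_sample_sheet(sheet)
}

#' @rdname methyl_io
#' @param sheet A sample-sheet tibble.
#' @export
write_sample_sheet <- function(sheet, path) {
  readr::write_csv(sheet, path)
  invisible(path)
}

#' @rdname methyl_io
#' @export
validate_sample_sheet <- function(sheet) {
  req <- c("sample_id", "label", "cohort", "category")
  if (!all(req %in% names(sheet))) {
    stop("sample sheet must have columns: ", paste(req, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(sheet$sample_id)) stop("duplicate sample ids in sheet", call. = FALSE)
  allowed <- c("reference", "unknown_pool", "test")
  bad <- setdiff(unique(sheet$cohort), allowed)
  if (length(bad) > 0) {
    stop("cohort must be one of reference/unknown_pool/test, got: ",
      paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  tibble::as_tibble(sheet)
}

#' Load a methylation cohort from disk
#'
#' Reads a beta matrix, probe manifest and sample sheet and cross-validates
#' them: every manifest probe id is checked against the matrix and every
#' sheet sample must be present in the matrix.
#'
#' @inheritParams methyl_io
#' @param manifest_path,sheet_path Paths to the manifest TSV and sheet CSV.
#' @return A list with elements `beta`, `manifest`, `sheet`.
#' @export
load_methyl_cohort <- function(path, manifest_path, sheet_path,
                               orientation = "probes_by_samples",
                               platform = "synthetic") {
  bm <- read_beta_matrix(path, orientation = orientation, platform = platform)
  manifest <- read_probe_manifest(manifest_path)
  sheet <- read_sample_sheet(sheet_path)
  missing <- setdiff(sheet$sample_id, sample_ids(bm))
  if (length(missing) > 0) {
    stop(
      "samples in sheet missing from matrix: ",
      paste(utils::head(missing, 5), collapse = ", "),
      call. = FALSE
    )
  }
  list(beta = bm, manifest = manifest, sheet = sheet)
}
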