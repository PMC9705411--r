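test_that("beta matrix round-trips through TSV with ids and values intact", {
  co <- small_cohort(seed = 3, n_probes = 300, samples_per_class = 4)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_beta_matrix(co$beta, path)
  back <- read_beta_matrix(path)
  expect_identical(probe_ids(back), probe_ids(co$beta))
  expect_identical(sample_ids(back), sample_ids(co$beta))
  expect_lt(max(abs(back$values - co$beta$values)), 1e-12)

  # transposed orientation reads back to the same object
  tpath <- withr::local_tempfile(fileext = ".tsv")
  tdf <- tibble::as_tibble(t(co$beta$values), rownames = "sample_id")
  readr::write_tsv(tdf, tpath)
  back_t <- read_beta_matrix(tpath, orientation = "samples_by_probes")
  expect_equal(back_t$values, co$beta$values, tolerance = 1e-12)
})

test_that("toy matrix loads with expected shape and manifest/sheet cross-checks run", {
  m <- matrix(c(0.1, 0.5, 0.9, 0.2, 0.6, 0.8), nrow = 3,
    dimnames = list(paste0("cg", 1:3), c("s1", "s2"))
  )
  dir <- withr::local_tempdir()
  write_beta_matrix(toy_bm(m), file.path(dir, "beta.tsv"))
  man <- tibble::tibble(
    probe_id = paste0("cg", 1:3), chromosome = "chr1",
    position = 1:3, snp_flag = FALSE, cross_reactive_flag = FALSE
  )
  write_probe_manifest(man, file.path(dir, "man.tsv"))
  sheet <- tibble::tibble(
    sample_id = c("s1", "s2"), label = "a", cohort = "reference",
    category = "in_scope"
  )
  write_sample_sheet(sheet, file.path(dir, "sheet.csv"))
  co <- load_methyl_cohort(
    file.path(dir, "beta.tsv"), file.path(dir, "man.tsv"),
    file.path(dir, "sheet.csv")
  )
  expect_identical(dim(co$beta), c(3L, 2L))
  expect_s3_class(co$manifest, "tbl_df")

  # sheet referencing a missing sample is rejected
  bad_sheet <- dplyr::add_row(sheet,
    sample_id = "s3", label = "a", cohort = "test", category = "in_scope"
  )
  write_sample_sheet(bad_sheet, file.path(dir, "bad.csv"))
  expect_error(
    load_methyl_cohort(
      file.path(dir, "beta.tsv"), file.path(dir, "man.tsv"),
      file.path(dir, "bad.csv")
    ),
    "missing from matrix"
  )
})

test_that("out-of-range and malformed beta values error instead of clipping", {
  m <- matrix(c(0.1, 1.2), 1, 2, dimnames = list("cg1", c("s1", "s2")))
  expect_error(beta_matrix(m), "beta out of range")
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("probe_id\ts1\ts2", "cg1\t0.1\t1.2"), path)
  expect_error(read_beta_matrix(path), "beta out of range")
  expect_error(
    beta_matrix(matrix(c(0.1, NA), 1, 2,
      dimnames = list("cg1", c("s1", "s2"))
    )),
    "finite"
  )
  expect_error(
    toy_bm(matrix(0.5, 2, 2, dimnames = list(c("cg1", "cg1"), c("s1", "s2")))),
    "duplicate probe"
  )
})

test_that("probe filtering removes sex/SNP/cross-reactive probes and keeps order", {
  m <- matrix(stats::runif(10), 5, 2,
    dimnames = list(paste0("cg", 1:5), c("s1", "s2"))
  )
  man <- tibble::tibble(
    probe_id = paste0("cg", 1:5),
    chromosome = c("chrX", "chr2", "chr3", "chr4", "chr5"),
    position = 1:5,
    snp_flag = c(FALSE, TRUE, FALSE, FALSE, FALSE),
    cross_reactive_flag = c(FALSE, FALSE, TRUE, FALSE, FALSE)
  )
  out <- filter_probes(toy_bm(m), man)
  # brute-force flag scan: exactly the two clean autosomal probes survive
  expect_identical(probe_ids(out), c("cg4", "cg5"))

  clean_man <- dplyr::mutate(man,
    chromosome = "chr1", snp_flag = FALSE, cross_reactive_flag = FALSE
  )
  expect_identical(filter_probes(toy_bm(m), clean_man)$values, m)

  all_flagged <- dplyr::mutate(man, snp_flag = TRUE)
  expect_warning(res <- filter_probes(toy_bm(m), all_flagged), "all probes")
  expect_identical(n_probes(res), 0L)

  expect_error(filter_probes(toy_bm(m), man[-1, ]), "missing from manifest")
  # idempotence on own output
  expect_identical(filter_probes(out, man)$values, out$values)
})

test_that("detection-p QC removes samples above the failure fraction, strict boundary", {
  m <- matrix(0.5, 100, 3,
    dimnames = list(sprintf("cg%03d", 1:100), c("clean", "edge", "fail"))
  )
  dp <- matrix(0, 100, 3, dimnames = dimnames(m))
  dp[1:5, "edge"] <- 0.5 # exactly 5% failing -> retained
  dp[1:10, "fail"] <- 0.5 # 10% failing -> removed
  expect_message(
    out <- qc_filter_samples(toy_bm(m), dp),
    "1 sample"
  )
  expect_identical(sample_ids(out), c("clean", "edge"))

  expect_identical(
    sample_ids(qc_filter_samples(toy_bm(m), matrix(0, 100, 3))),
    c("clean", "edge", "fail")
  )
  expect_error(qc_filter_samples(toy_bm(m), dp[1:50, ]), "same shape")
})

test_that("platform merge intersects probes, concatenates samples, keeps tags", {
  a <- beta_matrix(
    matrix(stats::runif(6), 3, 2,
      dimnames = list(c("A", "B", "C"), c("s1", "s2"))
    ),
    platform = "450k"
  )
  b <- beta_matrix(
    matrix(stats::runif(3), 3, 1,
      dimnames = list(c("B", "C", "D"), "s3")
    ),
    platform = "EPIC"
  )
  out <- merge_platforms(a, b)
  expect_identical(probe_ids(out), c("B", "C"))
  expect_identical(sample_ids(out), c("s1", "s2", "s3"))
  expect_identical(unname(out$platform), c("450k", "450k", "EPIC"))

  # identical probe sets: values pass through unchanged
  b2 <- beta_matrix(
    matrix(stats::runif(3), 3, 1,
      dimnames = list(c("A", "B", "C"), "s3")
    ),
    platform = "EPIC"
  )
  same <- merge_platforms(a, b2)
  expect_identical(same$values[, c("s1", "s2")], a$values)

  d <- beta_matrix(
    matrix(0.5, 1, 1, dimnames = list("Z", "s9")),
    platform = "EPIC"
  )
  expect_error(merge_platforms(a, d), "empty probe intersection")
  expect_error(merge_platforms(a, a), "duplicate sample ids")

  # symmetry: same (probe, sample, value) triples either way round
  rev <- merge_platforms(b, a)
  expect_identical(
    out$values[sort(probe_ids(out)), sort(sample_ids(out))],
    rev$values[sort(probe_ids(rev)), sort(sample_ids(rev))]
  )
  # idempotence: re-merging the two halves of the result reproduces it
  again <- merge_platforms(
    bm_subset(out, samples = c("s1", "s2")),
    bm_subset(out, samples = "s3")
  )
  expect_identical(again$values, out$values)
  expect_identical(again$platform, out$platform)
})
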