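#' Configuration for the synthetic methylation-cohort simulator
#'
#' Defines a synthetic multi-class methylation study. Each probe has a
#' bimodal background mean (a mixture of low-methylated Beta(2, 10) and
#' high-methylated Beta(10, 2) archetypes, the classic two-peak beta-value
#' landscape); each class owns a disjoint set of informative CpGs whose
#' mean is shifted on the logit scale (clipping-free squashing keeps means
#' inside (0, 1)); per-sample tumor purity mixes the class profile with a
#' shared normal profile before beta-distributed sampling around the mean
#' with concentration `noise_precision`. Outlier classes (each its own
#' category) supply the Unknown training pool and held-out unseen
#' categories.
#'
#' @param n_classes Number of in-scope classes.
#' @param samples_per_class In-scope samples per class (scalar or vector).
#' @param n_probes Total probes on the synthetic array.
#' @param n_informative Informative CpGs per class.
#' @param effect Mean beta shift of informative probes at the logit
#'   midpoint: a background mean of 0.5 moves to 0.5 + effect (hyper) or
#'   0.5 - effect (hypo); shifts elsewhere are logistic-squashed.
#' @param noise_precision Concentration of the beta sampling noise (larger
#'   = tighter around the mean).
#' @param purity_range Per-sample tumor purity is drawn uniformly from this
#'   range and mixes the class mean with the normal profile.
#' @param n_normal Number of normal-tissue control samples (drawn from the
#'   background profile itself, labeled `normal`).
#' @param n_outlier_classes Number of out-of-scope classes (categories).
#' @param outlier_class_size Samples per outlier class.
#' @param n_outlier_shared Number of CpGs forming a shared out-of-scope
#'   signature present in every outlier class (on top of each category's
#'   own informative set). Models the compartment-level signal that
#'   out-of-scope tumors share, which is what lets an Unknown class
#'   trained on some categories generalize to unseen ones.
#' @param n_unseen_outlier How many outlier categories are held out of the
#'   Unknown pool and appear only in the test partition.
#' @param test_per_class Held-out in-scope test samples per class (used by
#'   [simulate_split()]).
#' @param platform_split Fraction of samples tagged EPIC; EPIC samples use
#'   a probe subset (`epic_probe_fraction` of all probes).
#' @param epic_probe_fraction Fraction of probes present on the synthetic
#'   EPIC mask.
#' @param frac_sex,frac_snp,frac_crossreactive Fractions of probes flagged
#'   as sex-chromosomal, SNP-associated, cross-reactive in the manifest
#'   (never informative, so filtering does not destroy planted structure).
#' @param informative_overlap Fraction of each class's informative set
#'   shared with a common pool (0 = disjoint planted structure).
#' @param seed Integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_classes = 5, samples_per_class = 40,
                       n_probes = 30000, n_informative = 300,
                       effect = 0.45, noise_precision = 50,
                       purity_range = c(0.6, 1), n_normal = 0,
                       n_outlier_classes = 4, outlier_class_size = 100,
                       n_outlier_shared = 300,
                       n_unseen_outlier = min(2, n_outlier_classes),
                       test_per_class = 10,
                       platform_split = 0, epic_probe_fraction = 0.9,
                       frac_sex = 0.02, frac_snp = 0.01,
                       frac_crossreactive = 0.01,
                       informative_overlap = 0, seed = 42L) {
  cfg <- list(
    n_classes = n_classes, samples_per_class = samples_per_class,
    n_probes = n_probes, n_informative = n_informative, effect = effect,
    noise_precision = noise_precision, purity_range = purity_range,
    n_normal = n_normal,
    n_outlier_classes = n_outlier_classes,
    outlier_class_size = outlier_class_size,
    n_outlier_shared = n_outlier_shared,
    n_unseen_outlier = n_unseen_outlier, test_per_class = test_per_class,
    platform_split = platform_split,
    epic_probe_fraction = epic_probe_fraction,
    frac_sex = frac_sex, frac_snp = frac_snp,
    frac_crossreactive = frac_crossreactive,
    informative_overlap = informative_overlap, seed = as.integer(seed)
  )
  stopifnot(
    cfg$n_classes >= 1, all(cfg$samples_per_class >= 1), cfg$n_probes >= 1,
    cfg$n_informative >= 1, cfg$effect > 0, cfg$effect < 0.5,
    cfg$noise_precision > 0,
    length(cfg$purity_range) == 2,
    cfg$purity_range[1] >= 0, cfg$purity_range[2] <= 1,
    cfg$n_unseen_outlier <= cfg$n_outlier_classes
  )
  total_info <- (cfg$n_classes + cfg$n_outlier_classes) * cfg$n_informative +
    (cfg$n_outlier_classes > 0) * cfg$n_outlier_shared
  if (total_info > cfg$n_probes * (1 - cfg$frac_sex - cfg$frac_snp - cfg$frac_crossreactive)) {
    stop("not enough clean probes for the requested informative sets", call. = FALSE)
  }
  class(cfg) <- "sim_config"
  cfg
}

# Probe-level world shared by all samples of a study: manifest, background
# means, per-class informative sets and shifted class means.
.sim_world <- function(cfg) {
  p <- cfg$n_probes
  all_classes <- c(
    paste0("class_", seq_len(cfg$n_classes)),
    if (cfg$n_outlier_classes > 0) {
      paste0("outlier_", seq_len(cfg$n_outlier_classes))
    }
  )
  withr::with_seed(cfg$seed, {
    probe_id <- sprintf("cg%07d", seq_len(p))
    n_sex <- round(cfg$frac_sex * p)
    n_snp <- round(cfg$frac_snp * p)
    n_cross <- round(cfg$frac_crossreactive * p)
    flagged <- sample.int(p, n_sex + n_snp + n_cross)
    sex_idx <- flagged[seq_len(n_sex)]
    snp_idx <- flagged[n_sex + seq_len(n_snp)]
    cross_idx <- flagged[n_sex + n_snp + seq_len(n_cross)]
    chromosome <- sample(paste0("chr", 1:22), p, replace = TRUE)
    chromosome[sex_idx] <- sample(c("chrX", "chrY"), n_sex, replace = TRUE)
    manifest <- tibble::tibble(
      probe_id = probe_id,
      chromosome = chromosome,
      position = sample.int(2e8, p, replace = TRUE),
      snp_flag = seq_len(p) %in% snp_idx,
      cross_reactive_flag = seq_len(p) %in% cross_idx
    )

    # bimodal background: low- and high-methylated probe archetypes
    archetype_high <- stats::runif(p) < 0.5
    mu0 <- ifelse(archetype_high,
      stats::rbeta(p, 10, 2), stats::rbeta(p, 2, 10)
    )

    clean <- setdiff(seq_len(p), flagged)
    n_info <- cfg$n_informative
    shared_n <- round(cfg$informative_overlap * n_info)
    own_n <- n_info - shared_n
    shared_pool <- if (shared_n > 0) sample(clean, shared_n) else integer(0)
    remaining <- setdiff(clean, shared_pool)
    # shared out-of-scope signature, carried by every outlier class
    out_shared <- if (cfg$n_outlier_classes > 0 && cfg$n_outlier_shared > 0) {
      sample(remaining, cfg$n_outlier_shared)
    } else {
      integer(0)
    }
    remaining <- setdiff(remaining, out_shared)
    picks <- sample(remaining, own_n * length(all_classes))
    info_sets <- lapply(seq_along(all_classes), function(i) {
      own <- c(shared_pool, picks[(i - 1) * own_n + seq_len(own_n)])
      if (startsWith(all_classes[i], "outlier_")) c(own, out_shared) else own
    })
    names(info_sets) <- all_classes

    # class means: logit-shift informative probes toward the farther
    # boundary; shift size calibrated so a 0.5 background moves by `effect`
    delta <- stats::qlogis(0.5 + cfg$effect)
    class_mu <- lapply(info_sets, function(idx) {
      mu <- mu0
      dir <- ifelse(mu0[idx] < 0.5, 1, -1)
      mu[idx] <- stats::plogis(stats::qlogis(pmin(pmax(mu0[idx], 1e-6), 1 - 1e-6)) + dir * delta)
      mu
    })

    epic_mask <- sort(sample.int(p, round(cfg$epic_probe_fraction * p)))

    list(
      manifest = manifest, mu0 = mu0, info_sets = info_sets,
      class_mu = class_mu, classes = all_classes, probe_id = probe_id,
      epic_mask = epic_mask
    )
  })
}

# Draw beta values for a sample plan: tibble(sample_id, class, cohort,
# category). class "normal" uses the background profile directly.
.sim_samples <- function(world, plan, cfg, seed) {
  p <- length(world$mu0)
  n <- nrow(plan)
  withr::with_seed(seed, {
    purity <- stats::runif(n, cfg$purity_range[1], cfg$purity_range[2])
    vals <- vapply(seq_len(n), function(i) {
      cls <- plan$class[i]
      mu_t <- if (cls == "normal") world$mu0 else world$class_mu[[cls]]
      mu <- purity[i] * mu_t + (1 - purity[i]) * world$mu0
      mu <- pmin(pmax(mu, 1e-4), 1 - 1e-4)
      stats::rbeta(p, mu * cfg$noise_precision, (1 - mu) * cfg$noise_precision)
    }, numeric(p))
    dimnames(vals) <- list(world$probe_id, plan$sample_id)
    n_epic <- round(cfg$platform_split * n)
    platform <- rep("synthetic", n)
    if (n_epic > 0) platform[sample.int(n, n_epic)] <- "EPIC"
    list(values = vals, purity = purity, platform = platform)
  })
}

#' Simulate a synthetic methylation cohort
#'
#' Generates a single cohort: in-scope classes (cohort `reference`) plus,
#' when configured, outlier classes (cohort `unknown_pool`, one category
#' per outlier class). Deterministic for a fixed config seed.
#'
#' @param cfg A [sim_config()].
#' @return A list with `beta` ([beta_matrix()]), `sheet` (sample sheet
#'   tibble), `manifest` (probe manifest tibble) and `truth` (tibble
#'   `sample_id`, `class`, `purity`, plus the per-class informative probe
#'   sets in attribute `info_sets`).
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  world <- .sim_world(cfg)
  spc <- rep_len(cfg$samples_per_class, cfg$n_classes)
  plan <- dplyr::bind_rows(
    purrr::map2(
      paste0("class_", seq_len(cfg$n_classes)), spc,
      function(cls, m) {
        tibble::tibble(
          class = cls, cohort = "reference", category = "in_scope", n = m
        )
      }
    ),
    if (cfg$n_normal > 0) {
      tibble::tibble(
        class = "normal", cohort = "reference", category = "normal",
        n = cfg$n_normal
      )
    },
    if (cfg$n_outlier_classes > 0) {
      purrr::map(seq_len(cfg$n_outlier_classes), function(j) {
        tibble::tibble(
          class = paste0("outlier_", j), cohort = "unknown_pool",
          category = paste0("category_", j), n = cfg$outlier_class_size
        )
      })
    }
  ) |>
    tidyr::uncount(.data$n)
  plan$sample_id <- sprintf("s%04d", seq_len(nrow(plan)))

  draws <- .sim_samples(world, plan, cfg, seed = cfg$seed + 1L)
  bm <- beta_matrix(draws$values, platform = draws$platform)
  sheet <- tibble::tibble(
    sample_id = plan$sample_id,
    label = ifelse(plan$cohort == "reference", plan$class, "Unknown-pool"),
    cohort = plan$cohort,
    category = plan$category
  )
  truth <- tibble::tibble(
    sample_id = plan$sample_id, class = plan$class, purity = draws$purity
  )
  attr(truth, "info_sets") <- lapply(world$info_sets, function(i) world$probe_id[i])
  list(
    beta = bm, sheet = sheet, manifest = world$manifest, truth = truth,
    epic_probes = world$probe_id[world$epic_mask]
  )
}

#' Simulate a full train/test study design
#'
#' Generates the partitions of a classifier-development study from one
#' probe-level world: a reference cohort for class discovery and training,
#' a held-out in-scope test set from the same classes, an outlier pool of
#' "seen" categories from which the Unknown training class may be drawn,
#' and an outlier test set containing fresh samples of the seen categories
#' together with entirely unseen categories that never contribute to
#' training.
#'
#' @param cfg A [sim_config()]; `n_unseen_outlier` of the
#'   `n_outlier_classes` categories are test-exclusive.
#' @return A list with `reference`, `test_in_scope`, `pool`,
#'   `test_outlier` (each a list `beta`, `sheet`, `truth`), plus `manifest`
#'   and `info_sets`.
#' @export
simulate_split <- function(cfg = sim_config()) {
  if (cfg$n_outlier_classes < 1 || cfg$n_outlier_classes <= cfg$n_unseen_outlier) {
    stop("need outlier classes beyond the unseen hold-outs", call. = FALSE)
  }
  world <- .sim_world(cfg)
  spc <- rep_len(cfg$samples_per_class, cfg$n_classes)
  seen <- seq_len(cfg$n_outlier_classes - cfg$n_unseen_outlier)
  unseen <- setdiff(seq_len(cfg$n_outlier_classes), seen)

  make_plan <- function(cls, cohort, category, n) {
    tibble::tibble(class = cls, cohort = cohort, category = category, n = n)
  }
  plan <- dplyr::bind_rows(
    purrr::map2(paste0("class_", seq_len(cfg$n_classes)), spc, function(cls, m) {
      make_plan(cls, "reference", "in_scope", m)
    }),
    purrr::map(seq_len(cfg$n_classes), function(j) {
      make_plan(paste0("class_", j), "test", "in_scope", cfg$test_per_class)
    }),
    purrr::map(seen, function(j) {
      make_plan(
        paste0("outlier_", j), "unknown_pool", paste0("category_", j),
        cfg$outlier_class_size
      )
    }),
    purrr::map(unseen, function(j) {
      make_plan(
        paste0("outlier_", j), "test", paste0("category_", j),
        cfg$outlier_class_size
      )
    })
  ) |>
    tidyr::uncount(.data$n)
  plan$sample_id <- sprintf("s%04d", seq_len(nrow(plan)))

  draws <- .sim_samples(world, plan, cfg, seed = cfg$seed + 1L)
  bm <- beta_matrix(draws$values, platform = draws$platform)
  truth <- tibble::tibble(
    sample_id = plan$sample_id, class = plan$class, purity = draws$purity
  )
  sheet <- tibble::tibble(
    sample_id = plan$sample_id,
    label = dplyr::case_when(
      plan$category == "in_scope" ~ plan$class,
      plan$cohort == "unknown_pool" ~ "Unknown-pool",
      TRUE ~ "Unknown-pool"
    ),
    cohort = plan$cohort,
    category = plan$category
  )

  part <- function(idx) {
    ids <- plan$sample_id[idx]
    list(
      beta = bm_subset(bm, samples = ids),
      sheet = sheet[idx, ],
      truth = truth[idx, ]
    )
  }
  list(
    reference = part(plan$cohort == "reference"),
    test_in_scope = part(plan$cohort == "test" & plan$category == "in_scope"),
    pool = part(plan$cohort == "unknown_pool"),
    test_outlier = part(plan$cohort == "test" & plan$category != "in_scope"),
    manifest = world$manifest,
    info_sets = lapply(world$info_sets, function(i) world$probe_id[i]),
    epic_probes = world$probe_id[world$epic_mask]
  )
}
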