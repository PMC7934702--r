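#' Default end-to-end study configuration
#'
#' Bundles the synthetic study conditions: a 20/26 wildtype/mutant cohort
#' over the planted feature panel of [default_feature_specs()], a retest
#' replicate at the planted per-feature concordances, and a 24-lesion
#' phantom imaged under the 8 default scanning conditions. Thresholds are
#' the conventional screening values (CCC 0.85, correlation 0.85, AUC 0.7,
#' alpha 0.05).
#'
#' @param seed integer master seed; sub-seeds for the cohort, retest and
#'   phantom stages are derived deterministically from it.
#' @return A named list understood by [run_pipeline()].
#' @export
default_study_config <- function(seed = 1L) {
  list(seed = seed,
       n_wildtype = 20L, n_mutant = 26L,
       feature_specs = default_feature_specs(),
       n_lesions = 24L,
       conditions = default_scan_conditions(),
       ccc_threshold = 0.85,
       corr_threshold = 0.85,
       min_auc = 0.7,
       alpha = 0.05)
}

#' Run the full screening and robustness pipeline
#'
#' Executes the three stages in order on synthetic data drawn from the
#' configuration: (1) reproducibility screen of the test-retest pair by
#' CCC, (2) redundancy clustering of the kept features by Spearman
#' correlation with AUC-based representative selection, (3) robustness
#' classification of every selected feature by comparing its normalized
#' biological signal against per-condition-pair phantom noise signals.
#' Fully reproducible from the configuration seed.
#'
#' @param config list as returned by [default_study_config()].
#' @param out_dir optional directory; when given, the report is written as
#'   `report.json` plus CSV tables.
#' @return list with elements `ccc` (screen results), `clusters`, `aucs`,
#'   `selected`, `robustness` (one [robustness_matrix()] per selected
#'   feature), `summary` (per-feature aggregate verdicts) and the input
#'   tables.
#' @export
run_pipeline <- function(config = default_study_config(), out_dir = NULL) {
  fs <- config$feature_specs
  cohort <- generate_cohort_table(cohort_config(
    n_wildtype = config$n_wildtype, n_mutant = config$n_mutant,
    feature_specs = fs, seed = derive_seed(config$seed, 1L)))
  target_ccc <- if ("retest_ccc" %in% names(fs)) {
    stats::setNames(fs$retest_ccc, fs$feature)
  } else 0.95
  retest <- generate_retest_table(cohort, target_ccc = target_ccc,
                                  seed = derive_seed(config$seed, 2L))
  scr <- screen_reproducible(cohort, retest, threshold = config$ccc_threshold)
  kept <- scr$feature[scr$kept]

  selected <- character(0)
  clusters <- NULL
  aucs <- NULL
  if (length(kept) >= 1L) {
    sub <- cohort[, c("sample_id", "group", kept), drop = FALSE]
    sub <- as_feature_table(sub, "cohort")
    aucs <- data.frame(feature = kept,
                       auc = vapply(kept, function(f) {
                         univariate_auc(sub[[f]], sub$group)$auc
                       }, numeric(1)),
                       stringsAsFactors = FALSE, row.names = NULL)
    clusters <- if (length(kept) >= 2L) {
      cluster_features(spearman_matrix(sub), threshold = config$corr_threshold)
    } else {
      data.frame(feature = kept, cluster = 1L, stringsAsFactors = FALSE)
    }
    selected <- select_representatives(clusters, aucs, min_auc = config$min_auc)
  }

  noise_scale <- if ("phantom_noise_sd" %in% names(fs)) {
    stats::setNames(fs$phantom_noise_sd, fs$feature)
  } else {
    stats::setNames(rep(0.1, nrow(fs)), fs$feature)
  }
  phantom <- generate_phantom_table(
    n_lesions = config$n_lesions, conditions = config$conditions,
    noise_scale = noise_scale, seed = derive_seed(config$seed, 3L))

  robustness <- lapply(selected, function(f) {
    robustness_matrix(f, cohort, phantom, alpha = config$alpha)
  })
  names(robustness) <- selected
  summary <- data.frame(
    feature = selected,
    mean_bs = vapply(robustness, function(m) attr(m, "mean_bs"), numeric(1)),
    fraction_robust = vapply(robustness,
                             function(m) aggregate_robustness(m)$fraction,
                             numeric(1)),
    robust = vapply(robustness, function(m) aggregate_robustness(m)$robust,
                    logical(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  report <- list(config_seed = config$seed, ccc = scr, clusters = clusters,
                 aucs = aucs, selected = selected, robustness = robustness,
                 summary = summary, cohort = cohort, retest = retest,
                 phantom = phantom)
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_feature_table(report$cohort, file.path(out_dir, "cohort.csv"))
  write_feature_table(report$phantom, file.path(out_dir, "phantom.csv"))
  utils::write.csv(report$ccc, file.path(out_dir, "ccc.csv"), row.names = FALSE)
  if (!is.null(report$aucs)) {
    utils::write.csv(report$aucs, file.path(out_dir, "auc.csv"), row.names = FALSE)
  }
  rob_rows <- do.call(rbind, lapply(names(report$robustness), function(f) {
    m <- report$robustness[[f]]
    cbind(feature = f, as.data.frame(m), mean_bs = attr(m, "mean_bs"))
  }))
  if (!is.null(rob_rows)) {
    utils::write.csv(rob_rows, file.path(out_dir, "robustness.csv"),
                     row.names = FALSE)
  }
  json <- list(seed = report$config_seed,
               ccc = report$ccc,
               clusters = report$clusters,
               aucs = report$aucs,
               selected = report$selected,
               summary = report$summary)
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Generate one planted feature for robustness benchmarking
#'
#' Creates a minimal cohort/phantom pair carrying a single feature with a
#' known biological-to-noise signal ratio: the cohort groups are Gaussian
#' with unit spread and mean separation `delta`, and the phantom noise has
#' standard deviation `tau` under every condition. Used to measure how the
#' robustness classifier responds to the planted ratio `delta / tau`.
#'
#' @param delta group-mean separation of the cohort feature.
#' @param tau phantom per-condition noise standard deviation.
#' @param n_wildtype,n_mutant cohort group sizes (defaults 20 and 26).
#' @param n_lesions phantom lesion count (default 24).
#' @param conditions scanning conditions (default 8).
#' @param seed integer seed.
#' @return list with `cohort` and `phantom` feature tables holding one
#'   feature named `planted`.
#' @export
generate_planted_feature <- function(delta, tau, n_wildtype = 20L,
                                     n_mutant = 26L, n_lesions = 24L,
                                     conditions = default_scan_conditions(),
                                     seed = 1L) {
  fs <- data.frame(feature = "planted", mean_wildtype = 0,
                   mean_mutant = delta, sd = 1, stringsAsFactors = FALSE)
  cohort <- generate_cohort_table(cohort_config(
    n_wildtype = n_wildtype, n_mutant = n_mutant, feature_specs = fs,
    seed = derive_seed(seed, 11L)))
  phantom <- generate_phantom_table(
    n_lesions = n_lesions, conditions = conditions,
    noise_scale = c(planted = tau), condition_inflation = "none",
    seed = derive_seed(seed, 12L))
  list(cohort = cohort, phantom = phantom)
}
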