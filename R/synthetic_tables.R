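#' Configure a synthetic two-group cohort
#'
#' Describes a wildtype/mutant cohort and the per-feature sampling model
#' used by [generate_cohort_table()]. Each feature is Gaussian within group,
#' with a group-mean separation expressed in units of the common spread.
#' Group sizes default to 20 wildtype and 26 mutant lesions.
#'
#' @param n_wildtype,n_mutant group sizes (each >= 1).
#' @param feature_specs data.frame with columns `feature`, `mean_wildtype`,
#'   `mean_mutant`, `sd` (common within-group spread, > 0). Defaults to
#'   [default_feature_specs()].
#' @param seed integer RNG seed.
#' @return A `cohort_config` object.
#' @export
cohort_config <- function(n_wildtype = 20L, n_mutant = 26L,
                          feature_specs = default_feature_specs(),
                          seed = 1L) {
  if (n_wildtype < 1L || n_mutant < 1L) {
    stop("invalid config: both group sizes must be >= 1", call. = FALSE)
  }
  req <- c("feature", "mean_wildtype", "mean_mutant", "sd")
  if (!is.data.frame(feature_specs) || !all(req %in% names(feature_specs))) {
    stop("feature_specs needs columns feature, mean_wildtype, mean_mutant, sd",
         call. = FALSE)
  }
  if (any(feature_specs$sd <= 0)) {
    stop("invalid config: feature spreads must be > 0", call. = FALSE)
  }
  structure(list(n_wildtype = as.integer(n_wildtype),
                 n_mutant = as.integer(n_mutant),
                 feature_specs = feature_specs, seed = seed),
            class = "cohort_config")
}

#' Default planted delta-feature panel
#'
#' Eight synthetic delta-radiomics features forming the default study
#' conditions. The four named features mirror the archetypes of a
#' size/boundary/texture panel; their group-mean separations (in units of
#' the within-group spread) are back-calculated from target discrimination
#' (AUC approximately 0.87, 0.82, 0.76, 0.74 via
#' `AUC = pnorm(delta / (sd * sqrt(2)))`). `tumor_mass_dup` is a
#' near-duplicate of `tumor_mass` used to exercise redundancy clustering;
#' the `noise_*` features carry no group signal. `retest_ccc` is the
#' test-retest concordance planted for each feature and `phantom_noise_sd`
#' the lesion-level acquisition-noise scale used by the phantom table
#' generator: small for the mass/boundary features, large for the wavelet
#' energy so that its noise signal overwhelms its biological signal.
#'
#' @return data.frame of feature specifications.
#' @export
default_feature_specs <- function() {
  data.frame(
    feature = c("tumor_mass", "dwt_energy", "sigmoid_offset_mean",
                "gabor_energy", "tumor_mass_dup",
                "noise_flat", "noise_unstable", "noise_weak"),
    mean_wildtype = c(0, 0, 0, 0, 0, 0, 0, 0),
    mean_mutant = c(1.56, 1.30, 1.00, 0.90, 1.56, 0, 0, 0.2),
    sd = rep(1, 8),
    retest_ccc = c(0.95, 0.95, 0.95, 0.95, 0.95, 0.92, 0.50, 0.92),
    phantom_noise_sd = c(0.05, 2.0, 0.10, 0.20, 0.05, 0.30, 0.30, 0.30),
    duplicate_of = c(NA, NA, NA, NA, "tumor_mass", NA, NA, NA),
    stringsAsFactors = FALSE
  )
}

#' Generate a two-group cohort feature table
#'
#' Draws one row per lesion with group labels `wildtype` / `mutant` and one
#' column per configured feature. A feature marked as `duplicate_of` another
#' is generated as that feature plus a small independent jitter (10% of the
#' spread), yielding a near-perfectly rank-correlated redundant pair.
#'
#' @param config a [cohort_config].
#' @return A cohort-schema feature table (data.frame with `sample_id`,
#'   `group`, then feature columns).
#' @export
generate_cohort_table <- function(config = cohort_config()) {
  if (!inherits(config, "cohort_config")) {
    stop("`config` must be a cohort_config", call. = FALSE)
  }
  fs <- config$feature_specs
  n <- config$n_wildtype + config$n_mutant
  group <- c(rep("wildtype", config$n_wildtype), rep("mutant", config$n_mutant))
  tab <- data.frame(sample_id = sprintf("P%03d", seq_len(n)), group = group,
                    stringsAsFactors = FALSE)
  has_dup <- "duplicate_of" %in% names(fs)
  with_seed(config$seed, {
    for (i in seq_len(nrow(fs))) {
      parent <- if (has_dup) fs$duplicate_of[i] else NA
      if (!is.na(parent)) {
        if (!parent %in% names(tab)) {
          stop("duplicate_of refers to an ungenerated feature: ", parent,
               call. = FALSE)
        }
        tab[[fs$feature[i]]] <- tab[[parent]] +
          stats::rnorm(n, 0, 0.1 * fs$sd[i])
      } else {
        mu <- ifelse(group == "wildtype", fs$mean_wildtype[i], fs$mean_mutant[i])
        tab[[fs$feature[i]]] <- stats::rnorm(n, mu, fs$sd[i])
      }
    }
  })
  as_feature_table(tab, schema = "cohort")
}

#' Generate a test-retest replicate of a feature table
#'
#' Produces a second measurement of every feature by adding independent
#' zero-mean Gaussian noise with variance `2 * var(x) * (1 - c) / c`, the
#' value for which the expected concordance correlation between base and
#' retest equals the target `c` (variances use the 1/n convention, matching
#' the CCC estimator). A target of exactly 1 adds no noise.
#'
#' @param base a cohort- or retest-schema feature table.
#' @param target_ccc single value in (0, 1] or named per-feature vector.
#' @param seed integer RNG seed.
#' @return A feature table with the same annotation columns and perturbed
#'   feature values.
#' @export
generate_retest_table <- function(base, target_ccc = 0.85, seed = 1L) {
  feats <- feature_columns(base)
  cc <- if (length(target_ccc) == 1L && is.null(names(target_ccc))) {
    stats::setNames(rep(target_ccc, length(feats)), feats)
  } else {
    target_ccc
  }
  missing <- setdiff(feats, names(cc))
  if (length(missing) > 0L) {
    stop("no target CCC for feature(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(cc[feats] <= 0 | cc[feats] > 1)) {
    stop("invalid target: target_ccc must lie in (0, 1]", call. = FALSE)
  }
  out <- base
  with_seed(seed, {
    for (f in feats) {
      c0 <- cc[[f]]
      if (c0 >= 1) next
      sx2 <- mean((base[[f]] - mean(base[[f]]))^2)
      se <- sqrt(2 * sx2 * (1 - c0) / c0)
      out[[f]] <- base[[f]] + stats::rnorm(nrow(base), 0, se)
    }
  })
  attr(out, "schema") <- "retest"
  out
}

#' Generate a phantom feature table across scanning conditions
#'
#' Tabular shortcut for the imaging pipeline: each lesion has a fixed
#' underlying feature value (`base_values`), and each scanning condition
#' adds independent zero-mean Gaussian noise whose standard deviation is the
#' feature's `noise_scale` inflated by `sqrt(mas_ref / effective_mas)` for
#' that condition, mirroring the quantum-noise law of the image simulator.
#' Lesion identity is preserved across conditions.
#'
#' @param n_lesions number of phantom lesions (>= 1); default 24.
#' @param conditions list of >= 2 [scan_condition]; default
#'   [default_scan_conditions()].
#' @param base_values per-lesion matrix or data.frame (lesions x features)
#'   of noise-free feature values, or `NULL` to draw standard-normal lesion
#'   values for the features named in `noise_scale`.
#' @param noise_scale named per-feature noise standard deviation at the
#'   reference mAs.
#' @param mas_ref reference effective mAs for the noise inflation; default
#'   276.5.
#' @param condition_inflation `"mas"` (default) scales the noise per
#'   condition by `sqrt(mas_ref / effective_mas)`; `"none"` applies
#'   `noise_scale` identically under every condition.
#' @param seed integer RNG seed.
#' @return A phantom-schema feature table with columns `lesion_id`,
#'   `condition_id`, then features; `n_lesions * length(conditions)` rows.
#' @export
generate_phantom_table <- function(n_lesions = 24L,
                                   conditions = default_scan_conditions(),
                                   base_values = NULL,
                                   noise_scale = c(feature = 0.1),
                                   mas_ref = 276.5,
                                   condition_inflation = c("mas", "none"),
                                   seed = 1L) {
  condition_inflation <- match.arg(condition_inflation)
  if (n_lesions < 1L) stop("invalid config: n_lesions must be >= 1", call. = FALSE)
  if (length(conditions) < 2L) {
    stop("invalid config: at least 2 scanning conditions are required", call. = FALSE)
  }
  if (is.null(names(noise_scale)) || any(names(noise_scale) == "")) {
    stop("`noise_scale` must be a named per-feature vector", call. = FALSE)
  }
  feats <- names(noise_scale)
  if (is.null(base_values)) {
    base_values <- with_seed(derive_seed(seed, 0L), {
      m <- matrix(stats::rnorm(n_lesions * length(feats)), nrow = n_lesions)
      colnames(m) <- feats
      m
    })
  } else {
    base_values <- as.matrix(base_values)
    if (nrow(base_values) != n_lesions) {
      stop("base_values must have one row per lesion", call. = FALSE)
    }
    if (!all(feats %in% colnames(base_values))) {
      stop("base_values is missing columns for some features", call. = FALSE)
    }
  }
  cond_ids <- vapply(conditions, function(cn) cn$condition_id, character(1))
  mas <- vapply(conditions, function(cn) cn$effective_mas, numeric(1))
  rows <- vector("list", length(conditions))
  for (ci in seq_along(conditions)) {
    infl <- if (condition_inflation == "mas") sqrt(mas_ref / mas[ci]) else 1
    block <- data.frame(lesion_id = sprintf("L%02d", seq_len(n_lesions)),
                        condition_id = cond_ids[ci], stringsAsFactors = FALSE)
    noise <- with_seed(derive_seed(seed, ci), {
      matrix(stats::rnorm(n_lesions * length(feats)), nrow = n_lesions)
    })
    for (fi in seq_along(feats)) {
      block[[feats[fi]]] <- base_values[, feats[fi]] +
        noise[, fi] * noise_scale[[feats[fi]]] * infl
    }
    rows[[ci]] <- block
  }
  as_feature_table(do.call(rbind, rows), schema = "phantom")
}
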