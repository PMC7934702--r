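#' Construct a signal set
#'
#' A signal set is a collection of non-negative absolute feature-value
#' differences together with its mean and standard deviation. Biological
#' signal sets hold all cross-group pairwise differences; noise signal sets
#' hold per-lesion differences between two scanning conditions.
#'
#' @param values non-negative numeric values.
#' @param kind `"biological"` or `"noise"`.
#' @param provenance free-form description (group pair or condition pair).
#' @param var_convention `"population"` (1/n, default, matching the CCC
#'   estimator) or `"sample"` (1/(n-1)) for the standard deviation.
#' @return A `signal_set` with fields `values`, `mu`, `sigma`.
#' @export
signal_set <- function(values, kind = c("biological", "noise"),
                       provenance = NULL,
                       var_convention = c("population", "sample")) {
  kind <- match.arg(kind)
  var_convention <- match.arg(var_convention)
  if (length(values) < 1L || any(!is.finite(values)) || any(values < 0)) {
    stop("signal values must be finite and non-negative", call. = FALSE)
  }
  sigma <- if (var_convention == "population") sd_pop(values) else {
    if (length(values) > 1L) stats::sd(values) else 0
  }
  structure(list(kind = kind, values = as.numeric(values),
                 mu = mean(values), sigma = sigma,
                 provenance = provenance, var_convention = var_convention),
            class = "signal_set")
}

#' @export
print.signal_set <- function(x, ...) {
  cat(sprintf("<signal_set:%s> n=%d mu=%.4g sigma=%.4g (%s)\n", x$kind,
              length(x$values), x$mu, x$sigma,
              paste(x$provenance %||% "", collapse = " vs ")))
  invisible(x)
}

#' Biological signal of a feature
#'
#' All absolute cross-group pairwise differences
#' `{|x_r - x_s|}` between the wildtype and mutant values of one feature;
#' the set has `n_r * n_s` elements and is invariant under swapping the
#' group labels.
#'
#' @param wildtype_values,mutant_values non-empty numeric vectors.
#' @inheritParams signal_set
#' @return A biological [signal_set()].
#' @export
biological_signal <- function(wildtype_values, mutant_values,
                              var_convention = "population") {
  if (length(wildtype_values) == 0L || length(mutant_values) == 0L) {
    stop("invalid input: both groups must be non-empty", call. = FALSE)
  }
  d <- abs(outer(wildtype_values, mutant_values, "-"))
  signal_set(as.numeric(d), kind = "biological",
             provenance = c("wildtype", "mutant"),
             var_convention = var_convention)
}

#' Noise signal of a feature between two conditions
#'
#' Per-lesion absolute differences `{|p_si - p_sj|}` of one feature between
#' two scanning conditions of a phantom table; the set has one element per
#' lesion and is symmetric in (i, j).
#'
#' @param phantom a phantom-schema feature table.
#' @param feature feature column name.
#' @param condition_i,condition_j condition ids present in the table.
#' @inheritParams signal_set
#' @return A noise [signal_set()].
#' @export
noise_signal <- function(phantom, feature, condition_i, condition_j,
                         var_convention = "population") {
  if (!feature %in% feature_columns(phantom)) {
    stop("unknown feature: ", feature, call. = FALSE)
  }
  bi <- phantom[phantom$condition_id == condition_i, c("lesion_id", feature)]
  bj <- phantom[phantom$condition_id == condition_j, c("lesion_id", feature)]
  if (nrow(bi) == 0L || nrow(bj) == 0L) {
    stop("incomplete design: condition not present in phantom table", call. = FALSE)
  }
  if (!setequal(bi$lesion_id, bj$lesion_id)) {
    stop("incomplete design: lesions missing under one condition", call. = FALSE)
  }
  bj <- bj[match(bi$lesion_id, bj$lesion_id), , drop = FALSE]
  d <- abs(bi[[feature]] - bj[[feature]])
  signal_set(d, kind = "noise", provenance = c(condition_i, condition_j),
             var_convention = var_convention)
}

#' Normalize signal sets by the biological scale
#'
#' Divides every value of the biological set and of every noise set by the
#' same constant `mu_BS + sigma_BS`, so the normalized biological mean is
#' `mu_BS / (mu_BS + sigma_BS)` and noise means are directly comparable to
#' it on a unitless scale.
#'
#' @param bs a biological [signal_set()].
#' @param ns_sets list of noise [signal_set()]s (may be empty).
#' @return list with elements `bs`, `ns` (both renormalised signal sets)
#'   and `denominator`.
#' @export
normalize_signals <- function(bs, ns_sets = list()) {
  if (!inherits(bs, "signal_set") || bs$kind != "biological") {
    stop("`bs` must be a biological signal_set", call. = FALSE)
  }
  denom <- bs$mu + bs$sigma
  if (denom <= 0) {
    stop("degenerate signal: mu_BS + sigma_BS is zero (all-zero biological signal)",
         call. = FALSE)
  }
  rescale <- function(s) {
    signal_set(s$values / denom, kind = s$kind, provenance = s$provenance,
               var_convention = s$var_convention)
  }
  list(bs = rescale(bs), ns = lapply(ns_sets, rescale), denominator = denom)
}

#' Compare biological against noise signal
#'
#' Two-sided two-sample t-test between the normalized biological and noise
#' values (pooled equal-variance by default, Welch optionally). The feature
#' is robust for the condition pair iff the distributions differ
#' significantly AND the biological mean exceeds the noise mean: a
#' significant test with noise above biology must not count as robustness.
#' When both sets are constant the p-value is defined as 1 for equal means
#' and 0 otherwise (degenerate case).
#'
#' @param bs_norm,ns_norm normalized signal sets (each >= 2 values).
#' @param alpha significance level (default 0.05).
#' @param welch use the Welch test instead of pooled variance.
#' @return list with `t`, `p`, `robust`, `mean_bs`, `mean_ns`.
#' @export
compare_signals <- function(bs_norm, ns_norm, alpha = 0.05, welch = FALSE) {
  a <- bs_norm$values
  b <- ns_norm$values
  if (length(a) < 2L || length(b) < 2L) {
    stop("each signal set needs at least 2 values", call. = FALSE)
  }
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    p <- if (mean(a) == mean(b)) 1 else 0
    tt <- if (mean(a) == mean(b)) 0 else Inf * sign(mean(a) - mean(b))
  } else {
    ht <- stats::t.test(a, b, var.equal = !welch)
    tt <- unname(ht$statistic)
    p <- ht$p.value
  }
  list(t = tt, p = p,
       robust = (p < alpha) && (mean(a) > mean(b)),
       mean_bs = mean(a), mean_ns = mean(b))
}

#' Robustness matrix of one feature
#'
#' Builds the biological signal once from the cohort, then for every
#' unordered pair of scanning conditions builds the noise signal, applies
#' the shared normalization and runs [compare_signals()]. With `n_c`
#' conditions the grid has `n_c * (n_c - 1) / 2` cells.
#'
#' @param feature feature column name present in both tables.
#' @param cohort a cohort-schema feature table (both groups present).
#' @param phantom a phantom-schema feature table (>= 2 conditions).
#' @param alpha significance level (default 0.05).
#' @param welch use Welch's test.
#' @param var_convention standard-deviation convention for signal sets.
#' @param p_adjust multiple-testing correction applied across the cells
#'   (`"none"` default, or any [stats::p.adjust] method).
#' @return data.frame of class `robustness_matrix` with one row per
#'   condition pair (`condition_i`, `condition_j`, `mean_ns`, `t`, `p`,
#'   `robust`) and attributes `feature`, `mean_bs`, `denominator`.
#' @export
robustness_matrix <- function(feature, cohort, phantom, alpha = 0.05,
                              welch = FALSE, var_convention = "population",
                              p_adjust = "none") {
  if (!feature %in% feature_columns(cohort)) {
    stop("feature not in cohort table: ", feature, call. = FALSE)
  }
  wt <- cohort[[feature]][cohort$group == "wildtype"]
  mu <- cohort[[feature]][cohort$group == "mutant"]
  if (length(wt) == 0L || length(mu) == 0L) {
    stop("cohort must contain both wildtype and mutant rows", call. = FALSE)
  }
  conds <- unique(phantom$condition_id)
  if (length(conds) < 2L) {
    stop("phantom table must contain at least 2 conditions", call. = FALSE)
  }
  bs <- biological_signal(wt, mu, var_convention = var_convention)
  pairs <- utils::combn(seq_along(conds), 2L)
  ns_sets <- lapply(seq_len(ncol(pairs)), function(k) {
    noise_signal(phantom, feature, conds[pairs[2, k]], conds[pairs[1, k]],
                 var_convention = var_convention)
  })
  nrm <- normalize_signals(bs, ns_sets)
  cmp <- lapply(nrm$ns, function(ns) compare_signals(nrm$bs, ns, alpha = alpha,
                                                     welch = welch))
  out <- data.frame(
    condition_i = conds[pairs[2, ]],
    condition_j = conds[pairs[1, ]],
    mean_ns = vapply(cmp, `[[`, numeric(1), "mean_ns"),
    t = vapply(cmp, `[[`, numeric(1), "t"),
    p = vapply(cmp, `[[`, numeric(1), "p"),
    stringsAsFactors = FALSE
  )
  out$p_adjusted <- stats::p.adjust(out$p, method = p_adjust)
  out$robust <- (out$p_adjusted < alpha) & (nrm$bs$mu > out$mean_ns)
  attr(out, "feature") <- feature
  attr(out, "mean_bs") <- nrm$bs$mu
  attr(out, "denominator") <- nrm$denominator
  class(out) <- c("robustness_matrix", "data.frame")
  out
}

#' Aggregate a robustness matrix to one verdict
#'
#' A feature is robust overall iff strictly more than half of its
#' condition-pair cells are robust.
#'
#' @param matrix a [robustness_matrix()].
#' @return list with `robust` (logical), `fraction` robust and `n_cells`.
#' @export
aggregate_robustness <- function(matrix) {
  n <- nrow(matrix)
  frac <- sum(matrix$robust) / n
  list(robust = frac > 0.5, fraction = frac, n_cells = n)
}
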