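#' Spearman correlation matrix of a feature table
#'
#' Pairwise Spearman rank correlations between feature columns, with ties
#' handled by average ranks. Constant features have undefined correlations;
#' these entries are set to 0 (so a constant feature clusters alone) and a
#' warning names the feature.
#'
#' @param table a feature table with >= 3 rows and >= 2 feature columns.
#' @return symmetric matrix with unit diagonal.
#' @export
spearman_matrix <- function(table) {
  feats <- feature_columns(table)
  if (length(feats) < 2L) stop("need at least 2 features", call. = FALSE)
  x <- as.matrix(table[, feats, drop = FALSE])
  if (nrow(x) < 3L) stop("need at least 3 samples", call. = FALSE)
  const <- apply(x, 2L, function(col) stats::sd(col) == 0)
  rho <- suppressWarnings(stats::cor(x, method = "spearman"))
  if (any(const)) {
    warning("constant feature(s) with undefined correlations treated as 0: ",
            paste(feats[const], collapse = ", "))
    rho[const, ] <- 0
    rho[, const] <- 0
  }
  diag(rho) <- 1
  rho
}

#' Cluster features by correlation
#'
#' Average-linkage hierarchical clustering on the distance `1 - |rho|`,
#' with the tree cut at height `1 - threshold`, so features whose absolute
#' correlation exceeds the threshold land in the same cluster
#' (anti-correlated features are treated as equally redundant).
#'
#' @param corr symmetric correlation matrix with named dimensions.
#' @param threshold correlation above which features are considered
#'   redundant (default 0.85).
#' @return data.frame with columns `feature`, `cluster`.
#' @export
cluster_features <- function(corr, threshold = 0.85) {
  if (is.null(rownames(corr))) stop("correlation matrix must be named", call. = FALSE)
  feats <- rownames(corr)
  if (length(feats) == 1L) {
    return(data.frame(feature = feats, cluster = 1L, stringsAsFactors = FALSE))
  }
  d <- stats::as.dist(1 - abs(corr))
  tree <- stats::hclust(d, method = "average")
  cl <- stats::cutree(tree, h = 1 - threshold)
  out <- data.frame(feature = feats, cluster = unname(cl[feats]),
                    stringsAsFactors = FALSE)
  attr(out, "tree") <- tree
  out
}

#' Univariate discrimination by AUC
#'
#' Area under the ROC curve from the Mann-Whitney statistic,
#' `A = U / (n1 * n2)` with ties counted one half. The reported AUC is
#' orientation-free, `max(A, 1 - A)`, since no positive class direction is
#' assumed. An optional percentile bootstrap confidence interval resamples
#' within groups.
#'
#' @param values numeric feature values.
#' @param labels two-level group labels parallel to `values`.
#' @param ci if `TRUE`, add a bootstrap percentile CI.
#' @param n_boot bootstrap resamples (default 2000).
#' @param conf confidence level (default 0.95).
#' @param seed RNG seed for the bootstrap.
#' @return list with `auc` (in `[0.5, 1]`), `a` (oriented statistic), and
#'   optionally `ci_lower`, `ci_upper`.
#' @export
univariate_auc <- function(values, labels, ci = FALSE, n_boot = 2000L,
                           conf = 0.95, seed = 1L) {
  labels <- as.character(labels)
  lev <- unique(labels)
  if (length(lev) != 2L || any(table(labels) == 0L)) {
    stop("invalid labels: exactly two non-empty groups required", call. = FALSE)
  }
  a <- auc_stat(values, labels, lev)
  out <- list(auc = max(a, 1 - a), a = a)
  if (ci) {
    i1 <- which(labels == lev[1]); i2 <- which(labels == lev[2])
    boots <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
      j1 <- sample(i1, length(i1), replace = TRUE)
      j2 <- sample(i2, length(i2), replace = TRUE)
      ab <- auc_stat(c(values[j1], values[j2]),
                     c(labels[j1], labels[j2]), lev)
      max(ab, 1 - ab)
    }, numeric(1)))
    alpha <- 1 - conf
    qs <- stats::quantile(boots, c(alpha / 2, 1 - alpha / 2), names = FALSE)
    out$ci_lower <- qs[1]
    out$ci_upper <- qs[2]
  }
  out
}

# Oriented Mann-Whitney A = P(X_group1 > X_group2) + 0.5 P(=), via ranks.
auc_stat <- function(values, labels, lev) {
  x1 <- values[labels == lev[1]]
  x2 <- values[labels == lev[2]]
  r <- rank(c(x1, x2))
  u <- sum(r[seq_along(x1)]) - length(x1) * (length(x1) + 1) / 2
  u / (length(x1) * length(x2))
}

#' Select non-redundant informative representatives
#'
#' Within each cluster, take the feature with the highest AUC, and keep it
#' only if its AUC strictly exceeds `min_auc`. AUC ties break
#' lexicographically by feature name.
#'
#' @param clusters output of [cluster_features()].
#' @param aucs data.frame with columns `feature`, `auc` covering every
#'   clustered feature.
#' @param min_auc minimum AUC for a representative (default 0.7, strict).
#' @return character vector of selected feature names (sorted).
#' @export
select_representatives <- function(clusters, aucs, min_auc = 0.7) {
  missing <- setdiff(clusters$feature, aucs$feature)
  if (length(missing) > 0L) {
    stop("schema error: no AUC for feature(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  auc_map <- stats::setNames(aucs$auc, aucs$feature)
  picks <- character(0)
  for (cl in sort(unique(clusters$cluster))) {
    members <- sort(clusters$feature[clusters$cluster == cl])
    best <- members[which.max(auc_map[members])]
    if (auc_map[[best]] > min_auc) picks <- c(picks, best)
  }
  sort(picks)
}
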