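make_table <- function(mat, groups = NULL) {
  df <- data.frame(sample_id = sprintf("S%03d", seq_len(nrow(mat))),
                   group = groups %||% rep(c("wildtype", "mutant"),
                                           length.out = nrow(mat)),
                   stringsAsFactors = FALSE)
  for (j in seq_len(ncol(mat))) df[[colnames(mat)[j]]] <- mat[, j]
  as_feature_table(df, "cohort")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("Spearman matrix matches hand values and the rank oracle", {
  x <- c(1, 2, 3, 4)
  tab <- make_table(cbind(f1 = x, f2 = 2 * x, f3 = -x, f4 = c(1, 3, 2, 4)))
  rho <- spearman_matrix(tab)
  expect_equal(rho["f1", "f2"], 1)
  expect_equal(rho["f1", "f3"], -1)
  expect_equal(rho["f1", "f4"], 0.8)  # 1 - 6*2/(4*15)
  expect_true(isSymmetric(rho))
  expect_equal(unname(diag(rho)), rep(1, 4))
  set.seed(71)
  for (i in 1:30) {
    n <- sample(4:20, 1)
    a <- rnorm(n); b <- rnorm(n, 0.5 * a)
    t2 <- make_table(cbind(a = a, b = b))
    expect_equal(spearman_matrix(t2)["a", "b"], oracle_spearman(a, b),
                 tolerance = 1e-12)
  }
})

test_that("constant features get zeroed correlations with a warning", {
  tab <- make_table(cbind(f1 = c(1, 2, 3, 4), flat = c(2, 2, 2, 2)))
  expect_warning(rho <- spearman_matrix(tab), "flat")
  expect_equal(rho["f1", "flat"], 0)
  expect_equal(rho["flat", "flat"], 1)
})

test_that("correlation clustering groups redundant features", {
  set.seed(41)
  x <- rnorm(500)
  tab <- make_table(cbind(f1 = x, f2 = x + rnorm(500, 0, 0.01),
                          f3 = rnorm(500)))
  cl <- cluster_features(spearman_matrix(tab))
  expect_equal(cl$cluster[cl$feature == "f1"], cl$cluster[cl$feature == "f2"])
  expect_false(cl$cluster[cl$feature == "f3"] == cl$cluster[cl$feature == "f1"])
  # all weakly correlated: every feature its own cluster
  set.seed(42)
  indep <- make_table(matrix(rnorm(500 * 4), ncol = 4,
                             dimnames = list(NULL, paste0("g", 1:4))))
  cl2 <- cluster_features(spearman_matrix(indep))
  expect_equal(length(unique(cl2$cluster)), 4L)
  # single feature: one cluster
  single <- cluster_features(matrix(1, 1, 1, dimnames = list("only", "only")))
  expect_equal(single$cluster, 1L)
})

test_that("AUC matches enumeration and is orientation-free", {
  expect_equal(univariate_auc(c(1, 2, 3, 4),
                              c("a", "a", "b", "b"))$auc, 1.0)
  r <- univariate_auc(c(1, 3, 2, 4), c("a", "a", "b", "b"))
  expect_equal(r$auc, 0.75)
  # all ties
  expect_equal(univariate_auc(rep(1, 6), rep(c("a", "b"), 3))$auc, 0.5)
  set.seed(81)
  for (i in 1:40) {
    n1 <- sample(2:10, 1); n2 <- sample(2:10, 1)
    v <- c(rnorm(n1, 1), rnorm(n2))
    v[sample(length(v), 2)] <- v[1]  # inject ties
    lab <- c(rep("g1", n1), rep("g2", n2))
    a <- oracle_auc(v[lab == "g1"], v[lab == "g2"])
    res <- univariate_auc(v, lab)
    expect_equal(res$a, a, tolerance = 1e-12)
    expect_equal(res$auc, max(a, 1 - a), tolerance = 1e-12)
    expect_gte(res$auc, 0.5)
  }
  expect_error(univariate_auc(1:3, rep("a", 3)), "two non-empty groups")
})

test_that("bootstrap CI brackets the point AUC and is reproducible", {
  set.seed(5)
  v <- c(rnorm(20, 1.5), rnorm(26))
  lab <- c(rep("mutant", 20), rep("wildtype", 26))
  r1 <- univariate_auc(v, lab, ci = TRUE, n_boot = 500L, seed = 2)
  r2 <- univariate_auc(v, lab, ci = TRUE, n_boot = 500L, seed = 2)
  expect_identical(r1, r2)
  expect_lte(r1$ci_lower, r1$auc)
  expect_gte(r1$ci_upper, r1$auc)
})

test_that("representative selection applies argmax then the AUC floor", {
  clusters <- data.frame(feature = c("f1", "f2", "f3"),
                         cluster = c(1L, 1L, 2L))
  aucs <- data.frame(feature = c("f1", "f2", "f3"),
                     auc = c(0.80, 0.75, 0.72))
  expect_equal(select_representatives(clusters, aucs), c("f1", "f3"))
  aucs$auc <- c(0.80, 0.75, 0.65)
  expect_equal(select_representatives(clusters, aucs), "f1")
  # floor is strict: exactly 0.7 is not informative enough
  aucs$auc <- c(0.70, 0.65, 0.65)
  expect_equal(select_representatives(clusters, aucs), character(0))
  # lexicographic tie-break
  aucs$auc <- c(0.8, 0.8, 0.65)
  expect_equal(select_representatives(clusters, aucs), "f1")
  expect_error(select_representatives(clusters, aucs[1:2, ]), "schema")
})

test_that("pipeline selects the planted informative non-redundant pair", {
  hits <- 0L
  for (s in 1:50) {
    set.seed(s)
    n <- 200
    grp <- rep(c("wildtype", "mutant"), each = 100)
    delta_a <- ifelse(grp == "mutant", 1.47, 0)  # AUC ~ 0.85
    base <- rnorm(n, delta_a)
    mat <- cbind(inf_a = base,
                 inf_a_dup = base + rnorm(n, 0, 0.05),
                 inf_b = rnorm(n, ifelse(grp == "mutant", 1.19, 0)),  # AUC ~ 0.8
                 noise1 = rnorm(n), noise2 = rnorm(n), noise3 = rnorm(n),
                 noise4 = rnorm(n), noise5 = rnorm(n))
    tab <- make_table(mat, groups = grp)
    cl <- cluster_features(spearman_matrix(tab))
    feats <- feature_columns(tab)
    aucs <- data.frame(feature = feats,
                       auc = vapply(feats, function(f) {
                         univariate_auc(tab[[f]], tab$group)$auc
                       }, numeric(1)))
    sel <- select_representatives(cl, aucs)
    if (length(sel) == 2L && "inf_b" %in% sel &&
        any(c("inf_a", "inf_a_dup") %in% sel)) hits <- hits + 1L
  }
  expect_gte(hits, 45L)  # >= 90% of seeds
})
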