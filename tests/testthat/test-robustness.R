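phantom_from_matrix <- function(m) {
  # lesions x conditions matrix of one feature -> phantom table
  df <- do.call(rbind, lapply(seq_len(ncol(m)), function(ci) {
    data.frame(lesion_id = sprintf("L%02d", seq_len(nrow(m))),
               condition_id = sprintf("C%d", ci), f = m[, ci],
               stringsAsFactors = FALSE)
  }))
  as_feature_table(df, "phantom")
}

test_that("biological signal enumerates all cross-group absolute differences", {
  bs <- biological_signal(c(0, 1), c(2))
  expect_setequal(bs$values, c(2, 1))
  expect_equal(length(biological_signal(rnorm(20), rnorm(26))$values), 520L)
  expect_equal(biological_signal(c(3), c(3))$values, 0)
  expect_error(biological_signal(numeric(0), 1), "non-empty")
  # invariant under swapping group labels
  set.seed(3)
  a <- rnorm(5); b <- rnorm(7)
  expect_equal(sort(biological_signal(a, b)$values),
               sort(biological_signal(b, a)$values))
})

test_that("noise signal is the per-lesion difference, symmetric in conditions", {
  m <- cbind(c(1, 2), c(3, 2))
  ph <- phantom_from_matrix(m)
  ns <- noise_signal(ph, "f", "C1", "C2")
  expect_setequal(ns$values, c(2, 0))
  expect_equal(sort(noise_signal(ph, "f", "C2", "C1")$values),
               sort(ns$values))
  same <- noise_signal(phantom_from_matrix(cbind(c(1, 2), c(1, 2))), "f",
                       "C1", "C2")
  expect_true(all(same$values == 0))
  ph24 <- phantom_from_matrix(matrix(rnorm(48), 24))
  expect_equal(length(noise_signal(ph24, "f", "C1", "C2")$values), 24L)
  bad <- ph[-1, ]
  expect_error(noise_signal(as_feature_table(bad, "phantom"), "f", "C1", "C2"),
               "incomplete design")
})

test_that("normalization divides by mu + sigma and satisfies the mean identity", {
  # {2, 1} under the sample (1/(n-1)) convention: denom = 1.5 + 0.7071
  bs <- signal_set(c(2, 1), "biological", var_convention = "sample")
  nrm <- normalize_signals(bs)
  expect_equal(nrm$denominator, 1.5 + sqrt(0.5), tolerance = 1e-12)
  expect_equal(sort(nrm$bs$values), c(0.4531, 0.9062), tolerance = 1e-4)
  # population convention on the same set
  bsp <- signal_set(c(2, 1), "biological")
  expect_equal(normalize_signals(bsp)$denominator, 2.0)
  # constant biological signal: sigma 0, values map to 1
  cst <- normalize_signals(signal_set(c(1, 1), "biological"))
  expect_equal(cst$bs$values, c(1, 1))
  expect_error(normalize_signals(signal_set(c(0, 0), "biological")),
               "degenerate")
  # identity mean(normalized BS) = mu/(mu+sigma), random sets
  set.seed(13)
  for (i in 1:50) {
    v <- abs(rnorm(sample(3:40, 1)))
    s <- signal_set(v, "biological")
    got <- mean(normalize_signals(s)$bs$values)
    expect_equal(got, s$mu / (s$mu + s$sigma), tolerance = 1e-12)
    expect_gt(got, 0); expect_lte(got, 1)
  }
})

test_that("signal comparison runs a pooled two-sided t-test with a direction rule", {
  a <- signal_set(c(1, 2, 3), "biological")
  b <- signal_set(c(5, 6, 7), "noise")
  r <- compare_signals(a, b)
  # closed form: t = -4/sqrt(2/3) = -sqrt(24), df = 4
  expect_equal(r$t, -sqrt(24), tolerance = 1e-10)
  expect_equal(r$p, 2 * pt(-sqrt(24), df = 4), tolerance = 1e-10)
  # significant but noise above biology: not robust
  expect_false(r$robust)
  r2 <- compare_signals(b_big <- signal_set(c(5, 6, 7), "biological"),
                        signal_set(c(1, 2, 3), "noise"))
  expect_true(r2$robust)
  same <- compare_signals(a, signal_set(c(1, 2, 3), "noise"))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_false(same$robust)
  # degenerate zero-variance sets
  dg <- compare_signals(signal_set(c(1, 1), "biological"),
                        signal_set(c(1, 1), "noise"))
  expect_equal(dg$p, 1)
  dg2 <- compare_signals(signal_set(c(2, 2), "biological"),
                         signal_set(c(1, 1), "noise"))
  expect_equal(dg2$p, 0)
})

test_that("t statistics match the closed-form pooled oracle", {
  set.seed(29)
  for (i in 1:100) {
    a <- abs(rnorm(sample(3:20, 1), 1))
    b <- abs(rnorm(sample(3:20, 1), 0.5))
    got <- compare_signals(signal_set(a, "biological"), signal_set(b, "noise"))
    exp_ <- oracle_pooled_t(a, b)
    expect_equal(got$t, exp_$t, tolerance = 1e-10)
    expect_equal(got$p, exp_$p, tolerance = 1e-10)
  }
})

test_that("robustness matrix has one cell per unordered condition pair", {
  set.seed(61)
  planted <- generate_planted_feature(delta = 2, tau = 0.2, seed = 3)
  m <- robustness_matrix("planted", planted$cohort, planted$phantom)
  expect_equal(nrow(m), 28L)  # 8 conditions
  expect_true(all(!duplicated(paste(pmin(m$condition_i, m$condition_j),
                                    pmax(m$condition_i, m$condition_j)))))
  two <- generate_planted_feature(delta = 2, tau = 0.2,
                                  conditions = default_scan_conditions()[1:2],
                                  seed = 3)
  expect_equal(nrow(robustness_matrix("planted", two$cohort, two$phantom)), 1L)
  # strong separation, tiny noise: all cells robust
  expect_true(all(m$robust))
})

test_that("whole pipeline agrees with a brute-force double-loop on a micro-instance", {
  set.seed(97)
  wt <- rnorm(4, 1)
  mu <- rnorm(6, 2)
  pv <- matrix(rnorm(15, 0, 0.5), nrow = 5)  # 5 lesions x 3 conditions
  cohort <- as_feature_table(
    data.frame(sample_id = sprintf("S%d", 1:10),
               group = rep(c("wildtype", "mutant"), c(4, 6)),
               f = c(wt, mu), stringsAsFactors = FALSE), "cohort")
  phantom <- phantom_from_matrix(pv)
  got <- robustness_matrix("f", cohort, phantom)
  exp_ <- oracle_robustness(wt, mu, pv)
  expect_equal(nrow(got), length(exp_))
  for (k in seq_along(exp_)) {
    row <- got[got$condition_i == sprintf("C%d", exp_[[k]]$i) &
                 got$condition_j == sprintf("C%d", exp_[[k]]$j), ]
    expect_equal(nrow(row), 1L)
    expect_equal(row$t, exp_[[k]]$t, tolerance = 1e-10)
    expect_equal(row$p, exp_[[k]]$p, tolerance = 1e-10)
    expect_identical(row$robust, exp_[[k]]$robust)
  }
})

test_that("planted signal-to-noise ratio controls the robust fraction monotonically", {
  frac_at <- function(ratio, seed) {
    p <- generate_planted_feature(delta = 2, tau = 2 / ratio, seed = seed)
    aggregate_robustness(robustness_matrix("planted", p$cohort, p$phantom))$fraction
  }
  ratios <- c(0.1, 0.316, 1, 3.16, 10)
  mean_frac <- vapply(ratios, function(r) {
    mean(vapply(1:20, function(s) frac_at(r, s), numeric(1)))
  }, numeric(1))
  expect_lte(mean_frac[1], 0.10)
  expect_gte(mean_frac[5], 0.95)
  expect_true(all(diff(mean_frac) >= -1e-9))
})

test_that("aggregation requires a strict majority of robust cells", {
  fake <- function(k, n = 28L) {
    m <- data.frame(condition_i = as.character(seq_len(n)),
                    condition_j = "x",
                    mean_ns = 0, t = 0, p = 1,
                    robust = c(rep(TRUE, k), rep(FALSE, n - k)))
    class(m) <- c("robustness_matrix", "data.frame")
    m
  }
  expect_true(aggregate_robustness(fake(28L))$robust)
  expect_equal(aggregate_robustness(fake(28L))$fraction, 1.0)
  expect_false(aggregate_robustness(fake(3L))$robust)
  expect_false(aggregate_robustness(fake(14L))$robust)  # boundary: not strict majority
  expect_true(aggregate_robustness(fake(15L))$robust)
})
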