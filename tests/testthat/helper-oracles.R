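# Independent brute-force oracles, written directly from the defining
# formulas with explicit loops. They deliberately share no code with the
# package implementations they check.

oracle_ccc <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sx2 <- 0; sy2 <- 0; sxy <- 0
  for (i in seq_len(n)) {
    sx2 <- sx2 + (x[i] - mx)^2
    sy2 <- sy2 + (y[i] - my)^2
    sxy <- sxy + (x[i] - mx) * (y[i] - my)
  }
  sx2 <- sx2 / n; sy2 <- sy2 / n; sxy <- sxy / n
  2 * sxy / (sx2 + sy2 + (mx - my)^2)
}

# average ranks computed by counting, then the plain Pearson formula
oracle_spearman <- function(x, y) {
  avg_rank <- function(v) {
    n <- length(v)
    r <- numeric(n)
    for (i in seq_len(n)) {
      less <- sum(v < v[i])
      eq <- sum(v == v[i])
      r[i] <- less + (eq + 1) / 2
    }
    r
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# pairwise enumeration of the probability interpretation, ties as 1/2
oracle_auc <- function(x1, x2) {
  wins <- 0
  for (a in x1) for (b in x2) {
    wins <- wins + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  wins / (length(x1) * length(x2))
}

oracle_pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- sum((a - mean(a))^2) / (na - 1)
  vb <- sum((b - mean(b))^2) / (nb - 1)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = t, p = 2 * stats::pt(-abs(t), df))
}

oracle_biological_signal <- function(wt, mu) {
  out <- numeric(0)
  for (a in wt) for (b in mu) out <- c(out, abs(a - b))
  out
}

oracle_noise_signal <- function(pi_vals, pj_vals) {
  out <- numeric(length(pi_vals))
  for (s in seq_along(pi_vals)) out[s] <- abs(pi_vals[s] - pj_vals[s])
  out
}

# Whole robustness pipeline for one feature, as direct double loops.
oracle_robustness <- function(wt, mu, phantom_values, alpha = 0.05) {
  # phantom_values: lesions x conditions matrix
  bs <- oracle_biological_signal(wt, mu)
  mu_bs <- mean(bs)
  sd_bs <- sqrt(sum((bs - mu_bs)^2) / length(bs))
  denom <- mu_bs + sd_bs
  nc <- ncol(phantom_values)
  res <- list()
  for (i in seq_len(nc)) for (j in seq_len(nc)) {
    if (i <= j) next
    ns <- oracle_noise_signal(phantom_values[, i], phantom_values[, j])
    a <- bs / denom
    b <- ns / denom
    ht <- oracle_pooled_t(a, b)
    res[[length(res) + 1]] <- list(
      i = i, j = j, t = ht$t, p = ht$p,
      robust = ht$p < alpha && mean(a) > mean(b))
  }
  res
}

# --- lesion builders -------------------------------------------------------

# Sphere of radius R (mm) with intensity following a radial sigmoid profile
# centred at R + shift; mask is the exact R-sphere.
make_sigmoid_sphere <- function(R = 7, shift = 0, slope = 0.8,
                                spacing = c(0.7, 0.7, 0.7),
                                inside_hu = -50, outside_hu = -850) {
  half <- R + 8
  n <- 2 * ceiling(half / spacing) + 1
  ctr <- (n - 1) / 2 * spacing
  xs <- (seq_len(n[1]) - 1) * spacing[1] - ctr[1]
  ys <- (seq_len(n[2]) - 1) * spacing[2] - ctr[2]
  zs <- (seq_len(n[3]) - 1) * spacing[3] - ctr[3]
  gx <- array(rep(xs, times = n[2] * n[3]), n)
  gy <- array(rep(rep(ys, each = n[1]), times = n[3]), n)
  gz <- array(rep(zs, each = n[1] * n[2]), n)
  r <- sqrt(gx^2 + gy^2 + gz^2)
  A <- inside_hu - outside_hu
  v <- A / (1 + exp((r - (R + shift)) / slope)) + outside_hu
  list(volume = ct_volume(v, spacing), mask = lesion_mask(r <= R, spacing))
}

make_ball_mask <- function(R = 7, spacing = c(0.7, 0.7, 0.7), centre_off = c(0, 0, 0)) {
  half <- R + 3 * max(spacing)
  n <- 2 * ceiling(half / spacing) + 1
  ctr <- (n - 1) / 2 * spacing + centre_off
  xs <- (seq_len(n[1]) - 1) * spacing[1] - ctr[1]
  ys <- (seq_len(n[2]) - 1) * spacing[2] - ctr[2]
  zs <- (seq_len(n[3]) - 1) * spacing[3] - ctr[3]
  gx <- array(rep(xs, times = n[2] * n[3]), n)
  gy <- array(rep(rep(ys, each = n[1]), times = n[3]), n)
  gz <- array(rep(zs, each = n[1] * n[2]), n)
  r <- sqrt(gx^2 + gy^2 + gz^2)
  lesion_mask(r <= R, spacing)
}

const_volume <- function(mask, hu) {
  ct_volume(array(hu, dim(mask$membership)), mask$spacing)
}
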