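# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
#' Run an expression under a temporary RNG state so that callers' streams are
#' not disturbed and results are reproducible given `seed`.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic sub-seed for (seed, index) pairs; stays inside 32-bit range.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(index) * 104729) %% 2147483647)
}

# Population (1/n) standard deviation; the convention used by Lin's CCC and,
# by default, by the signal-set normalization.
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be positive", name), call. = FALSE)
  }
  invisible(x)
}

# Vectorized trilinear interpolation of a 3D array at world coordinates (mm).
# Grid point i along axis k sits at (i - 1) * spacing[k]. Points outside the
# grid are clamped to the boundary.
interp_trilinear <- function(arr, spacing, xyz) {
  d <- dim(arr)
  stopifnot(length(d) == 3L, ncol(xyz) == 3L)
  out <- numeric(nrow(xyz))
  idx <- sweep(xyz, 2L, spacing, "/") + 1  # fractional 1-based indices
  for (k in 1:3) idx[, k] <- pmin(pmax(idx[, k], 1), d[k])
  i0 <- floor(idx)
  for (k in 1:3) i0[, k] <- pmin(i0[, k], d[k] - 1L)
  i0[i0 < 1] <- 1
  fr <- idx - i0
  # handle degenerate axes of length 1
  for (k in 1:3) if (d[k] == 1L) { i0[, k] <- 1; fr[, k] <- 0 }
  g <- function(di, dj, dk) {
    ii <- pmin(i0[, 1] + di, d[1]); jj <- pmin(i0[, 2] + dj, d[2])
    kk <- pmin(i0[, 3] + dk, d[3])
    arr[cbind(ii, jj, kk)]
  }
  w <- function(di, dj, dk) {
    (if (di == 0) 1 - fr[, 1] else fr[, 1]) *
      (if (dj == 0) 1 - fr[, 2] else fr[, 2]) *
      (if (dk == 0) 1 - fr[, 3] else fr[, 3])
  }
  for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
    out <- out + w(di, dj, dk) * g(di, dj, dk)
  }
  out
}

# Separable 3D Gaussian smoothing; sigma is given in voxels per axis.
# sigma of 0 along an axis skips that axis.
gauss_smooth3 <- function(arr, sigma) {
  sigma <- rep(sigma, length.out = 3L)
  out <- arr
  d <- dim(arr)
  for (ax in 1:3) {
    s <- sigma[ax]
    if (s <= 0 || d[ax] == 1L) next
    r <- max(1L, ceiling(3 * s))
    k <- exp(-((-r:r)^2) / (2 * s^2))
    k <- k / sum(k)
    out <- convolve_axis(out, k, ax)
  }
  out
}

# 1D convolution of a 3D array along one axis with replicate padding.
convolve_axis <- function(arr, kernel, axis) {
  d <- dim(arr)
  r <- (length(kernel) - 1L) / 2L
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  a <- aperm(arr, perm)
  da <- dim(a)
  m <- matrix(a, nrow = da[1])
  pad_top <- m[rep(1L, r), , drop = FALSE]
  pad_bot <- m[rep(nrow(m), r), , drop = FALSE]
  mp <- rbind(pad_top, m, pad_bot)
  res <- apply(mp, 2L, function(col) {
    stats::filter(col, kernel, method = "convolution", sides = 2)[(r + 1):(r + da[1])]
  })
  out <- array(res, dim = da)
  aperm(out, order(perm))
}
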