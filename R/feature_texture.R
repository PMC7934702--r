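#' Gabor filter-bank energy
#'
#' Measures line-like intratumoral pattern by convolving each axial slice
#' with a bank of zero-mean, unit-L2-norm real Gabor kernels (default 4
#' orientations at 0/45/90/135 degrees times 2 wavelengths of 4 and 8
#' in-plane voxels) and summing squared responses over mask voxels and bank
#' elements, normalised by the mask voxel count. The bank is applied
#' slice-wise because thoracic CT voxels are strongly anisotropic. Voxels
#' outside the mask are replaced by the in-mask mean before filtering so
#' that the segmentation edge does not masquerade as texture; a constant
#' lesion therefore has (numerically) zero energy, and scaling intensities
#' by `c` scales the energy by `c^2`.
#'
#' @param volume a [ct_volume].
#' @param mask a [lesion_mask], non-empty.
#' @param wavelengths Gabor wavelengths in in-plane voxels.
#' @param orientations orientations in radians.
#' @return energy (squared-HU units per voxel).
#' @export
compute_gabor_energy <- function(volume, mask,
                                 wavelengths = c(4, 8),
                                 orientations = pi * c(0, 1, 2, 3) / 4) {
  check_aligned(volume, mask)
  check_nonempty_mask(mask)
  bank <- lapply(wavelengths, function(lam) {
    lapply(orientations, function(th) gabor_kernel(lam, th))
  })
  bank <- unlist(bank, recursive = FALSE)
  arr <- volume$intensities
  m <- mask$membership
  mu <- mean(arr[m])
  filled <- arr
  filled[!m] <- mu
  total <- 0
  nvox <- sum(m)
  zs <- which(apply(m, 3L, any))
  for (z in zs) {
    sl <- filled[, , z]
    msl <- m[, , z]
    for (k in bank) {
      resp <- EBImage::filter2(sl, k, boundary = "replicate")
      total <- total + sum(resp[msl]^2)
    }
  }
  total / nvox
}

# Real (cosine-phase) Gabor kernel: Gaussian envelope of width 0.5*lambda,
# zero-mean then L2-normalised so that white noise of unit variance yields
# unit expected squared response.
gabor_kernel <- function(lambda, theta, sigma_ratio = 0.5) {
  sigma <- sigma_ratio * lambda
  r <- ceiling(3 * sigma)
  xs <- -r:r
  gx <- outer(xs, rep(1, length(xs)))
  gy <- outer(rep(1, length(xs)), xs)
  xr <- gx * cos(theta) + gy * sin(theta)
  yr <- -gx * sin(theta) + gy * cos(theta)
  k <- exp(-(xr^2 + yr^2) / (2 * sigma^2)) * cos(2 * pi * xr / lambda)
  k <- k - mean(k)
  k / sqrt(sum(k^2))
}

#' Discrete wavelet detail energy
#'
#' Measures intratumoral heterogeneity as the mean squared detail
#' coefficient of a separable 3D Daubechies-4 (4-tap) wavelet decomposition
#' of the lesion's bounding-box intensities. Voxels outside the mask are
#' replaced by the in-mask mean, the box is zero-phase padded to even
#' dimensions per level (periodized transform), and energy is the sum of
#' squared coefficients over every detail subband of every level divided by
#' the bounding-box voxel count. A constant lesion has exactly zero detail
#' energy; scaling intensities by `c` scales the energy by `c^2` exactly.
#'
#' @param volume a [ct_volume].
#' @param mask a [lesion_mask], non-empty.
#' @param levels number of decomposition levels (default 2).
#' @return energy (squared-HU units per voxel).
#' @export
compute_dwt_energy <- function(volume, mask, levels = 2L) {
  check_aligned(volume, mask)
  check_nonempty_mask(mask)
  idx <- which(mask$membership, arr.ind = TRUE)
  lo <- apply(idx, 2L, min)
  hi <- apply(idx, 2L, max)
  arr <- volume$intensities
  m <- mask$membership
  mu <- mean(arr[m])
  box <- arr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  mbox <- m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  box[!mbox] <- mu
  dim(box) <- hi - lo + 1L
  # pad each axis (with the in-mask mean) to a multiple of 2^levels
  mult <- 2L^levels
  newd <- as.integer(ceiling(dim(box) / mult) * mult)
  if (!identical(newd, dim(box))) {
    padded <- array(mu, dim = newd)
    padded[seq_len(dim(box)[1]), seq_len(dim(box)[2]), seq_len(dim(box)[3])] <- box
    box <- padded
  }
  nvox <- prod(dim(box))
  energy <- 0
  approx <- box
  for (lev in seq_len(levels)) {
    sub <- dwt3_once(approx)
    energy <- energy + sum(vapply(sub$detail, function(s) sum(s^2), numeric(1)))
    approx <- sub$approx
    if (any(dim(approx) < 2L)) break
  }
  energy / nvox
}

# D4 analysis filters (orthonormal; wavelet filter by quadrature mirror).
d4_filters <- function() {
  s3 <- sqrt(3)
  h <- c(1 + s3, 3 + s3, 3 - s3, 1 - s3) / (4 * sqrt(2))
  g <- rev(h) * c(1, -1, 1, -1)
  list(h = h, g = g)
}

# One periodized DWT step along a vector of even length.
dwt1 <- function(x, h, g) {
  n <- length(x)
  xp <- c(x, x[seq_len(min(3L, n))])
  while (length(xp) < n + 3L) xp <- c(xp, xp[seq_len(n + 3L - length(xp))])
  starts <- seq(1L, n - 1L, by = 2L)
  a <- vapply(starts, function(s) sum(h * xp[s:(s + 3L)]), numeric(1))
  d <- vapply(starts, function(s) sum(g * xp[s:(s + 3L)]), numeric(1))
  list(a = a, d = d)
}

# Apply the analysis pair along one axis of a 3D array, returning the
# low-pass and high-pass halves.
dwt_axis <- function(arr, axis, h, g) {
  d <- dim(arr)
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  a <- aperm(arr, perm)
  da <- dim(a)
  m <- matrix(a, nrow = da[1])
  half <- da[1] %/% 2L
  lo <- matrix(0, nrow = half, ncol = ncol(m))
  hi <- matrix(0, nrow = half, ncol = ncol(m))
  for (j in seq_len(ncol(m))) {
    w <- dwt1(m[, j], h, g)
    lo[, j] <- w$a
    hi[, j] <- w$d
  }
  dl <- da; dl[1] <- half
  list(lo = aperm(array(lo, dim = dl), order(perm)),
       hi = aperm(array(hi, dim = dl), order(perm)))
}

# One level of the separable 3D transform: returns the LLL approximation
# and the 7 detail subbands.
dwt3_once <- function(arr) {
  f <- d4_filters()
  s1 <- dwt_axis(arr, 1L, f$h, f$g)
  out <- list()
  approx <- NULL
  for (tag1 in c("lo", "hi")) {
    s2 <- dwt_axis(s1[[tag1]], 2L, f$h, f$g)
    for (tag2 in c("lo", "hi")) {
      s3 <- dwt_axis(s2[[tag2]], 3L, f$h, f$g)
      for (tag3 in c("lo", "hi")) {
        key <- paste0(tag1, tag2, tag3)
        if (key == "lololo") approx <- s3[[tag3]]
        else out[[key]] <- s3[[tag3]]
      }
    }
  }
  list(approx = approx, detail = out)
}
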