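#' Mean sigmoid boundary offset
#'
#' Quantifies boundary sharpness/position by fitting a sigmoid to the HU
#' profile across the lesion surface. For each surface voxel, the outward
#' surface normal is taken from the (negated, smoothed) gradient of the
#' mask, the intensity profile is sampled by trilinear interpolation along
#' that normal over `[-profile_length, +profile_length]` mm (t = 0 at the
#' surface voxel centre, positive outward), and
#' `f(t) = A / (1 + exp((t - offset) / slope)) + B` is fitted by nonlinear
#' least squares. The feature is the mean fitted `offset` (mm) over surface
#' points; profiles whose fit fails are dropped. Lower values correspond to
#' transitions that sit closer to (or inside) the segmented surface, i.e.
#' sharper boundaries; lesions whose density fades outward beyond the mask
#' get positive offsets.
#'
#' @param volume a [ct_volume].
#' @param mask a [lesion_mask] with at least 2 foreground voxels so surface
#'   normals are defined.
#' @param profile_length half-length of the sampled profile in mm.
#' @param step sampling step along the profile in mm.
#' @param max_profiles cap on the number of surface points fitted (points
#'   are subsampled deterministically and evenly when the surface is
#'   larger); keeps cost bounded on large lesions.
#' @return mean fitted offset in mm.
#' @export
compute_sigmoid_offset_mean <- function(volume, mask, profile_length = 6,
                                        step = 0.35, max_profiles = 200L) {
  check_aligned(volume, mask)
  check_nonempty_mask(mask)
  if (sum(mask$membership) < 2L) {
    stop("degenerate mask: surface normals require at least 2 voxels",
         call. = FALSE)
  }
  stopifnot_scalar_number(profile_length, "profile_length", positive = TRUE)
  stopifnot_scalar_number(step, "step", positive = TRUE)
  sp <- volume$spacing
  bnd <- boundary_voxels(mask$membership)
  if (nrow(bnd) == 0L) {
    stop("degenerate mask: no surface voxels found", call. = FALSE)
  }
  if (nrow(bnd) > max_profiles) {
    keep <- unique(round(seq(1L, nrow(bnd), length.out = max_profiles)))
    bnd <- bnd[keep, , drop = FALSE]
  }
  # outward normal = negated gradient of the smoothed indicator
  smooth_m <- gauss_smooth3(mask$membership * 1, sigma = c(1.5, 1.5, 1.5))
  grads <- numeric_gradient(smooth_m, sp)
  ts <- seq(-profile_length, profile_length, by = step)
  offsets <- numeric(0)
  n_attempt <- 0L
  for (i in seq_len(nrow(bnd))) {
    v <- bnd[i, ]
    g <- c(grads$gx[v[1], v[2], v[3]], grads$gy[v[1], v[2], v[3]],
           grads$gz[v[1], v[2], v[3]])
    gn <- sqrt(sum(g^2))
    if (gn < 1e-8) next
    nrm <- -g / gn
    p0 <- (v - 1) * sp
    pts <- cbind(p0[1] + ts * nrm[1], p0[2] + ts * nrm[2], p0[3] + ts * nrm[3])
    prof <- interp_trilinear(volume$intensities, sp, pts)
    n_attempt <- n_attempt + 1L
    off <- fit_sigmoid_offset(ts, prof)
    if (is.finite(off)) offsets <- c(offsets, off)
  }
  if (n_attempt == 0L) {
    stop("degenerate mask: no usable surface normals", call. = FALSE)
  }
  if (length(offsets) < 0.5 * n_attempt) {
    stop(sprintf("unstable fit: sigmoid fit failed on %d of %d profiles",
                 n_attempt - length(offsets), n_attempt), call. = FALSE)
  }
  mean(offsets)
}

# Least-squares fit of A / (1 + exp((t - offset)/slope)) + B.
# Returns the fitted offset, or NA on failure / non-informative profiles.
fit_sigmoid_offset <- function(ts, prof) {
  rng <- range(prof)
  if (!all(is.finite(prof)) || diff(rng) < 1e-6) return(NA_real_)
  df <- data.frame(t = ts, v = prof)
  start <- list(A = rng[2] - rng[1], B = rng[1], offset = 0, slope = 1)
  fit <- tryCatch(
    suppressWarnings(
      minpack.lm::nlsLM(v ~ A / (1 + exp((t - offset) / slope)) + B,
                        data = df, start = start,
                        lower = c(A = -Inf, B = -Inf,
                                  offset = min(ts), slope = 0.05),
                        upper = c(A = Inf, B = Inf,
                                  offset = max(ts), slope = max(ts)),
                        control = minpack.lm::nls.lm.control(maxiter = 100))),
    error = function(e) NULL)
  if (is.null(fit)) return(NA_real_)
  co <- stats::coef(fit)
  # reject fits that degenerate to a flat line (amplitude below noise floor)
  if (abs(co[["A"]]) < 0.05 * diff(rng)) return(NA_real_)
  co[["offset"]]
}

# Central-difference gradient of a 3D array in world (mm) units.
numeric_gradient <- function(arr, spacing) {
  d <- dim(arr)
  gx <- gy <- gz <- array(0, dim = d)
  if (d[1] > 2L) gx[2:(d[1] - 1), , ] <- (arr[3:d[1], , ] - arr[1:(d[1] - 2), , ]) / (2 * spacing[1])
  if (d[2] > 2L) gy[, 2:(d[2] - 1), ] <- (arr[, 3:d[2], ] - arr[, 1:(d[2] - 2), ]) / (2 * spacing[2])
  if (d[3] > 2L) gz[, , 2:(d[3] - 1)] <- (arr[, , 3:d[3]] - arr[, , 1:(d[3] - 2)]) / (2 * spacing[3])
  list(gx = gx, gy = gy, gz = gz)
}
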