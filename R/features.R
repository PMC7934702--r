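#' Tumor mass (water-equivalent)
#'
#' Integrates water-equivalent density over the lesion:
#' `mass = sum((HU + 1000)/1000 * voxel_volume)` in mg (1 mg/mm^3 for
#' water, 0 for air at -1000 HU). Given equal volumes, a partial-solid
#' (low-HU) lesion therefore has smaller mass than a solid one.
#'
#' @param volume a [ct_volume].
#' @param mask a [lesion_mask] on the same grid, non-empty.
#' @return mass in mg-equivalent.
#' @export
compute_tumor_mass <- function(volume, mask) {
  check_aligned(volume, mask)
  check_nonempty_mask(mask)
  voxvol <- prod(volume$spacing)
  hu <- volume$intensities[mask$membership]
  sum((hu + 1000) / 1000) * voxvol
}

#' Lesion volume and largest diameter
#'
#' Volume is foreground voxel count times voxel volume. The largest
#' diameter follows the axial-plane (RECIST-style) convention: the maximum
#' in-plane distance between boundary voxel centres, maximised over slices,
#' plus one in-plane voxel to account for voxel extent. A 3D variant (the
#' maximum pairwise distance over all boundary voxels) is available via
#' `plane = "3d"`.
#'
#' @param volume a [ct_volume].
#' @param mask a [lesion_mask], non-empty.
#' @param plane `"axial"` (default) or `"3d"` diameter convention.
#' @return list with `volume_mm3` and `largest_diameter_mm`.
#' @export
compute_size <- function(volume, mask, plane = c("axial", "3d")) {
  plane <- match.arg(plane)
  check_aligned(volume, mask)
  check_nonempty_mask(mask)
  sp <- mask$spacing
  vol <- sum(mask$membership) * prod(sp)
  bnd <- boundary_voxels(mask$membership)
  if (nrow(bnd) == 0L) bnd <- which(mask$membership, arr.ind = TRUE)
  if (plane == "axial") {
    diam <- 0
    for (z in unique(bnd[, 3])) {
      pts <- bnd[bnd[, 3] == z, , drop = FALSE]
      xy <- cbind((pts[, 1] - 1) * sp[1], (pts[, 2] - 1) * sp[2])
      diam <- max(diam, max_pairwise_distance(xy) + sp[1])
    }
  } else {
    xyz <- sweep(bnd - 1, 2L, sp, "*")
    diam <- max_pairwise_distance(xyz) + sp[1]
  }
  list(volume_mm3 = vol, largest_diameter_mm = diam)
}

# Foreground voxels with at least one 6-neighbour outside the mask (or on
# the grid border).
boundary_voxels <- function(m) {
  d <- dim(m)
  shifted <- function(ax, dir) {
    out <- array(FALSE, dim = d)
    take <- put <- lapply(d, seq_len)
    if (dir > 0) { take[[ax]] <- 1:(d[ax] - 1); put[[ax]] <- 2:d[ax] }
    else { take[[ax]] <- 2:d[ax]; put[[ax]] <- 1:(d[ax] - 1) }
    out[put[[1]], put[[2]], put[[3]]] <- m[take[[1]], take[[2]], take[[3]]]
    out
  }
  interior <- array(TRUE, dim = d)
  for (ax in 1:3) {
    if (d[ax] == 1L) { interior[] <- FALSE; next }
    for (dir in c(-1, 1)) interior <- interior & shifted(ax, dir)
  }
  which(m & !interior, arr.ind = TRUE)
}

# Exact maximum pairwise Euclidean distance via the convex hull when the
# point set is large; brute force otherwise.
max_pairwise_distance <- function(pts) {
  if (nrow(pts) < 2L) return(0)
  if (ncol(pts) == 2L && nrow(pts) > 60L) {
    hull <- grDevices::chull(pts[, 1], pts[, 2])
    pts <- pts[hull, , drop = FALSE]
  } else if (nrow(pts) > 400L) {
    # keep extremal points along many directions (sufficient for diameters)
    keep <- integer(0)
    for (i in 1:26) {
      u <- as.numeric(arrayInd(i, c(3, 3, 3))) - 2
      if (all(u == 0)) next
      proj <- as.matrix(pts) %*% u[seq_len(ncol(pts))]
      keep <- c(keep, which.min(proj), which.max(proj))
    }
    pts <- pts[unique(keep), , drop = FALSE]
  }
  max(stats::dist(pts))
}

#' Extract the full feature vector from a lesion
#'
#' Bundles [compute_tumor_mass()], [compute_sigmoid_offset_mean()],
#' [compute_gabor_energy()], [compute_dwt_energy()] and [compute_size()]
#' into one named numeric vector.
#'
#' @param volume a [ct_volume].
#' @param mask a [lesion_mask], non-empty.
#' @param ... passed through to the individual feature functions.
#' @return Named numeric vector with elements `tumor_mass`,
#'   `sigmoid_offset_mean`, `gabor_energy`, `dwt_energy`, `volume_mm3`,
#'   `largest_diameter_mm`.
#' @export
extract_features <- function(volume, mask, ...) {
  size <- compute_size(volume, mask)
  c(tumor_mass = compute_tumor_mass(volume, mask),
    sigmoid_offset_mean = compute_sigmoid_offset_mean(volume, mask),
    gabor_energy = compute_gabor_energy(volume, mask),
    dwt_energy = compute_dwt_energy(volume, mask),
    volume_mm3 = size$volume_mm3,
    largest_diameter_mm = size$largest_diameter_mm)
}

#' Delta features between timepoints
#'
#' Per-feature subtraction, baseline minus follow-up, so lesions that grow
#' or gain density between baseline and follow-up produce negative deltas.
#'
#' @param baseline,followup named numeric feature vectors with identical
#'   names.
#' @return Named numeric vector of deltas.
#' @export
delta_features <- function(baseline, followup) {
  if (is.null(names(baseline)) || is.null(names(followup)) ||
      !setequal(names(baseline), names(followup)) ||
      length(baseline) != length(followup)) {
    stop("schema error: baseline and follow-up feature names must match",
         call. = FALSE)
  }
  baseline - followup[names(baseline)]
}
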