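#' CT volume container
#'
#' A minimal container for a 3D grid of CT numbers (Hounsfield Units) with
#' per-axis voxel spacing in millimetres. Axis order is (x, y, z) with z the
#' slice (axial) direction; voxel indices are 1-based in R, and voxel `i`
#' along an axis is centred at `(i - 1) * spacing` in world millimetres.
#'
#' @param intensities numeric 3D array of HU values.
#' @param spacing numeric length-3 vector of voxel spacings in mm, all > 0.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(intensities, spacing) {
  if (!is.array(intensities) || length(dim(intensities)) != 3L) {
    stop("`intensities` must be a 3D array", call. = FALSE)
  }
  if (length(intensities) == 0L) stop("volume grid is empty", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be 3 positive finite numbers (mm)", call. = FALSE)
  }
  structure(list(intensities = intensities, spacing = spacing),
            class = "ct_volume")
}

#' Lesion mask container
#'
#' A binary 3D grid aligned voxel-for-voxel with a [ct_volume]. Masks must
#' share the image grid exactly; no resampling is ever performed silently.
#'
#' @param membership logical or 0/1 numeric 3D array.
#' @param spacing numeric length-3 voxel spacing in mm.
#' @return An object of class `lesion_mask`.
#' @export
lesion_mask <- function(membership, spacing) {
  if (!is.array(membership) || length(dim(membership)) != 3L) {
    stop("`membership` must be a 3D array", call. = FALSE)
  }
  m <- membership != 0
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be 3 positive finite numbers (mm)", call. = FALSE)
  }
  structure(list(membership = m, spacing = spacing), class = "lesion_mask")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf("<ct_volume> %s voxels @ %s mm, HU range [%.0f, %.0f]\n",
              paste(dim(x$intensities), collapse = "x"),
              paste(format(x$spacing, digits = 3), collapse = "x"),
              min(x$intensities), max(x$intensities)))
  invisible(x)
}

#' @export
print.lesion_mask <- function(x, ...) {
  cat(sprintf("<lesion_mask> %s voxels @ %s mm, %d foreground\n",
              paste(dim(x$membership), collapse = "x"),
              paste(format(x$spacing, digits = 3), collapse = "x"),
              sum(x$membership)))
  invisible(x)
}

check_aligned <- function(volume, mask) {
  if (!inherits(volume, "ct_volume")) stop("`volume` must be a ct_volume", call. = FALSE)
  if (!inherits(mask, "lesion_mask")) stop("`mask` must be a lesion_mask", call. = FALSE)
  if (!identical(dim(volume$intensities), dim(mask$membership))) {
    stop("mask grid does not match volume grid", call. = FALSE)
  }
  if (max(abs(volume$spacing - mask$spacing)) > 1e-9) {
    stop("mask spacing does not match volume spacing", call. = FALSE)
  }
  invisible(TRUE)
}

check_nonempty_mask <- function(mask) {
  if (sum(mask$membership) < 1L) {
    stop("empty lesion mask: feature computation requires >= 1 foreground voxel",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a CT volume or mask from NIfTI
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param as one of `"volume"` or `"mask"`.
#' @return A [ct_volume] or [lesion_mask].
#' @export
read_nifti_volume <- function(path, as = c("volume", "mask")) {
  as <- match.arg(as)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  spacing <- RNifti::pixdim(img)[seq_len(3)]
  if (identical(as, "volume")) ct_volume(arr, spacing) else lesion_mask(arr, spacing)
}

#' Write a CT volume or mask to NIfTI
#'
#' @param x a [ct_volume] or [lesion_mask].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_nifti_volume <- function(x, path) {
  arr <- if (inherits(x, "ct_volume")) x$intensities else x$membership * 1
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- x$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}
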