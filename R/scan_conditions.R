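#' Specify a CT scanning condition
#'
#' A condition is a scanner plus a tube current and exposure time; their
#' product, the effective mAs, is proportional to x-ray output and is the
#' quantity that controls quantum noise in the image.
#'
#' @param scanner_id scanner label (e.g. `"scanner1"`).
#' @param tube_current tube current in mA (> 0).
#' @param exposure_time exposure time in s (> 0).
#' @param blur_mm extra in-plane Gaussian blur width (mm) modelling
#'   scanner-specific smoothing; default 0.
#' @return A `scan_condition` with derived field `effective_mas`.
#' @export
scan_condition <- function(scanner_id, tube_current, exposure_time,
                           blur_mm = 0) {
  stopifnot_scalar_number(tube_current, "tube_current", positive = TRUE)
  stopifnot_scalar_number(exposure_time, "exposure_time", positive = TRUE)
  stopifnot_scalar_number(blur_mm, "blur_mm")
  structure(list(scanner_id = as.character(scanner_id),
                 tube_current = tube_current,
                 exposure_time = exposure_time,
                 effective_mas = tube_current * exposure_time,
                 blur_mm = blur_mm,
                 condition_id = sprintf("%s_%gmA", scanner_id, tube_current)),
            class = "scan_condition")
}

#' Default two-scanner, four-current condition set
#'
#' Eight conditions: scanner 1 at 395/195/100/50 mA with 0.7 s exposure, and
#' scanner 2 at 480/260/130/65 mA with 0.5 s exposure. The currents are
#' paired so the two scanners reach roughly equivalent effective mAs levels;
#' scanner 2 carries a small extra blur standing in for its smoother
#' reconstruction behaviour.
#'
#' @return List of 8 [scan_condition] objects.
#' @export
default_scan_conditions <- function() {
  c(
    lapply(c(395, 195, 100, 50), function(mA)
      scan_condition("scanner1", mA, 0.7, blur_mm = 0)),
    lapply(c(480, 260, 130, 65), function(mA)
      scan_condition("scanner2", mA, 0.5, blur_mm = 0.4))
  )
}

#' Simulate acquisition noise for one scanning condition
#'
#' Adds zero-mean Gaussian noise whose standard deviation follows the
#' quantum-noise law `sigma = sigma_ref * sqrt(mas_ref / effective_mas)`,
#' then applies the condition's scanner-specific in-plane Gaussian blur.
#' Deterministic given `seed`.
#'
#' @param volume a [ct_volume].
#' @param condition a [scan_condition] with `effective_mas > 0`.
#' @param sigma_ref noise standard deviation (HU) at the reference mAs;
#'   default 20 HU.
#' @param mas_ref reference effective mAs; default 276.5 (the highest
#'   default scanner-1 level, 395 mA x 0.7 s).
#' @param seed integer RNG seed.
#' @return A new [ct_volume] with noise and blur applied.
#' @export
apply_scan_condition <- function(volume, condition, sigma_ref = 20,
                                 mas_ref = 276.5, seed = 1L) {
  if (!inherits(volume, "ct_volume")) stop("`volume` must be a ct_volume", call. = FALSE)
  if (!inherits(condition, "scan_condition")) {
    stop("`condition` must be a scan_condition", call. = FALSE)
  }
  if (!is.finite(condition$effective_mas) || condition$effective_mas <= 0) {
    stop("invalid condition: effective_mas must be > 0", call. = FALSE)
  }
  stopifnot_scalar_number(sigma_ref, "sigma_ref")
  if (sigma_ref < 0) stop("`sigma_ref` must be >= 0", call. = FALSE)
  sigma <- sigma_ref * sqrt(mas_ref / condition$effective_mas)
  arr <- volume$intensities
  if (sigma > 0) {
    noise <- with_seed(seed, array(stats::rnorm(length(arr), 0, sigma), dim = dim(arr)))
    arr <- arr + noise
  }
  if (condition$blur_mm > 0) {
    sig_vox <- c(condition$blur_mm / volume$spacing[1:2], 0)
    arr <- gauss_smooth3(arr, sig_vox)
  }
  ct_volume(arr, volume$spacing)
}

#' Image the phantom under one condition
#'
#' Applies [apply_scan_condition()] to every lesion volume of a phantom set,
#' deriving a per-lesion sub-seed from `(seed, lesion index)` so the whole
#' set is reproducible from a single seed.
#'
#' @param lesions output of [generate_phantom_lesions()].
#' @param condition a [scan_condition].
#' @param seed integer RNG seed.
#' @inheritParams apply_scan_condition
#' @return List parallel to `lesions` with noisy volumes and original masks.
#' @export
image_phantom <- function(lesions, condition, seed = 1L, sigma_ref = 20,
                          mas_ref = 276.5) {
  lapply(seq_along(lesions), function(i) {
    le <- lesions[[i]]
    list(spec = le$spec,
         volume = apply_scan_condition(le$volume, condition,
                                       sigma_ref = sigma_ref, mas_ref = mas_ref,
                                       seed = derive_seed(seed, i)),
         mask = le$mask,
         condition = condition)
  })
}
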