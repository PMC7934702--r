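#' Specify a synthetic phantom lesion
#'
#' Describes one lesion of the synthetic anthropomorphic-thorax phantom by
#' its volume-equivalent sphere diameter, shape family and CT density. The
#' default phantom emulates a 24-lesion insert: two effective diameters
#' (10 and 20 mm), four shapes (spherical, elliptical, lobular, spiculated)
#' and three densities (-630, -10, +100 HU).
#'
#' @param effective_diameter volume-equivalent sphere diameter in mm (> 0).
#' @param shape one of `"spherical"`, `"elliptical"`, `"lobular"`,
#'   `"spiculated"`.
#' @param density lesion CT number in HU, within `[-1000, 3000]`.
#' @return A `lesion_spec` object.
#' @export
lesion_spec <- function(effective_diameter, shape, density) {
  shape <- match.arg(shape, c("spherical", "elliptical", "lobular", "spiculated"))
  stopifnot_scalar_number(effective_diameter, "effective_diameter")
  if (effective_diameter <= 0) {
    stop("invalid lesion spec: effective_diameter must be > 0", call. = FALSE)
  }
  stopifnot_scalar_number(density, "density")
  if (density < -1000 || density > 3000) {
    stop("invalid lesion spec: density must lie in [-1000, 3000] HU", call. = FALSE)
  }
  structure(list(effective_diameter = effective_diameter, shape = shape,
                 density = density),
            class = "lesion_spec")
}

#' Default 24-lesion factorial
#'
#' @return List of 24 [lesion_spec] objects:
#'   {10, 20} mm x {4 shapes} x {-630, -10, +100} HU.
#' @export
default_lesion_specs <- function() {
  specs <- list()
  for (d in c(10, 20)) {
    for (sh in c("spherical", "elliptical", "lobular", "spiculated")) {
      for (hu in c(-630, -10, 100)) {
        specs[[length(specs) + 1L]] <- lesion_spec(d, sh, hu)
      }
    }
  }
  specs
}

# Directional radius functions r(theta, phi) for each shape family, before
# volume calibration. theta = polar angle from +z, phi = azimuth.
# All are smooth and deterministic so that masks are reproducible.
shape_radius <- function(shape, R, theta, phi) {
  switch(shape,
    spherical = rep(R, length(theta)),
    elliptical = {
      # axis ratios 1 : 0.7 : 0.5 rescaled so the ellipsoid keeps the
      # volume of the R-sphere: a*b*c = R^3
      s <- R / (0.7 * 0.5)^(1 / 3)
      a <- s; b <- 0.7 * s; c0 <- 0.5 * s
      sx <- sin(theta) * cos(phi); sy <- sin(theta) * sin(phi); sz <- cos(theta)
      1 / sqrt((sx / a)^2 + (sy / b)^2 + (sz / c0)^2)
    },
    lobular = {
      # 4 smooth radial bumps from low-order angular harmonics
      bump <- 0.18 * (sin(2 * theta) * cos(2 * phi)) +
        0.12 * cos(3 * phi) * sin(theta)^2 +
        0.08 * cos(2 * theta)
      R * (1 + bump)
    },
    spiculated = {
      # sphere plus 12 narrow radial spikes at fixed quasi-uniform directions
      dirs <- spike_directions(12L)
      ux <- sin(theta) * cos(phi); uy <- sin(theta) * sin(phi); uz <- cos(theta)
      boost <- 0
      for (i in seq_len(nrow(dirs))) {
        cosang <- pmin(1, pmax(-1, ux * dirs[i, 1] + uy * dirs[i, 2] + uz * dirs[i, 3]))
        ang <- acos(cosang)
        boost <- boost + exp(-(ang / 0.12)^2 / 2)
      }
      R * (1 + 0.9 * boost)
    },
    stop("unknown shape: ", shape, call. = FALSE)
  )
}

# Fibonacci-lattice directions on the sphere; deterministic spike layout.
spike_directions <- function(n) {
  i <- seq_len(n) - 0.5
  th <- acos(1 - 2 * i / n)
  ph <- pi * (1 + sqrt(5)) * i
  cbind(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
}

# Voxelize one lesion: star-shaped implicit test |x| <= r(direction), with
# the radius field rescaled iteratively so the voxelized volume matches the
# effective-diameter sphere volume.
voxelize_lesion <- function(spec, spacing, background_hu) {
  R <- spec$effective_diameter / 2
  target_vol <- 4 / 3 * pi * R^3
  # grid: generous margin around the largest extent (spiculated spikes reach
  # ~1.9 R before calibration shrinks them)
  half_extent <- 2.2 * R
  n <- pmax(3L, 2L * ceiling(half_extent / spacing) + 1L)
  centre <- (n - 1) / 2 * spacing
  xs <- ((seq_len(n[1]) - 1) * spacing[1]) - centre[1]
  ys <- ((seq_len(n[2]) - 1) * spacing[2]) - centre[2]
  zs <- ((seq_len(n[3]) - 1) * spacing[3]) - centre[3]
  gx <- array(rep(xs, times = n[2] * n[3]), dim = n)
  gy <- array(rep(rep(ys, each = n[1]), times = n[3]), dim = n)
  gz <- array(rep(zs, each = n[1] * n[2]), dim = n)
  rr <- sqrt(gx^2 + gy^2 + gz^2)
  theta <- acos(ifelse(rr > 0, gz / rr, 1))
  phi <- atan2(gy, gx)
  rad0 <- shape_radius(spec$shape, R, theta, phi)
  voxvol <- prod(spacing)
  scale <- 1
  mask <- rr <= rad0
  for (iter in 1:4) {
    mask <- rr <= scale * rad0
    vol <- sum(mask) * voxvol
    if (abs(vol - target_vol) / target_vol < 0.01) break
    scale <- scale * (target_vol / vol)^(1 / 3)
  }
  vol_arr <- array(background_hu, dim = n)
  vol_arr[mask] <- spec$density
  list(volume = ct_volume(vol_arr, spacing),
       mask = lesion_mask(mask, spacing))
}

#' Generate noise-free phantom lesion volumes and masks
#'
#' Builds one image/mask pair per lesion specification on a regular grid.
#' Lesion voxels are set to the spec density and everything else to a uniform
#' lung-parenchyma background; each lesion is placed in isolation at the
#' centre of its own grid. The voxelized mask volume is calibrated to the
#' volume of the effective-diameter sphere (within voxelization tolerance)
#' for every shape, so the size factorial is preserved across shapes.
#'
#' @param grid_spacing voxel spacing in mm per axis; default
#'   `c(0.7, 0.7, 1.25)` mirrors a thin-slice thoracic protocol.
#' @param specs list of [lesion_spec]; defaults to the 24-lesion factorial
#'   from [default_lesion_specs()].
#' @param background_hu background CT number; default -850 HU (aerated lung
#'   parenchyma), which contrasts with all three default lesion densities.
#' @return A list with one element per spec, each a list with components
#'   `spec`, `volume` ([ct_volume]) and `mask` ([lesion_mask]).
#' @examples
#' lesions <- generate_phantom_lesions(specs = list(
#'   lesion_spec(10, "spherical", -10)))
#' sum(lesions[[1]]$mask$membership) * prod(lesions[[1]]$mask$spacing)
#' @export
generate_phantom_lesions <- function(grid_spacing = c(0.7, 0.7, 1.25),
                                     specs = default_lesion_specs(),
                                     background_hu = -850) {
  grid_spacing <- rep(as.numeric(grid_spacing), length.out = 3L)
  if (any(!is.finite(grid_spacing)) || any(grid_spacing <= 0)) {
    stop("grid_spacing must be positive on all axes", call. = FALSE)
  }
  if (length(specs) == 0L) return(list())
  lapply(specs, function(sp) {
    if (!inherits(sp, "lesion_spec")) {
      stop("invalid lesion spec: use lesion_spec()", call. = FALSE)
    }
    vx <- voxelize_lesion(sp, grid_spacing, background_hu)
    list(spec = sp, volume = vx$volume, mask = vx$mask)
  })
}
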