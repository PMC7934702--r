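test_that("tumor mass integrates water-equivalent density", {
  mask <- make_ball_mask(R = 10, spacing = c(0.5, 0.5, 0.5))
  # HU = 0 (water): mass = volume in mg-equivalent; radius 10 mm sphere
  m0 <- compute_tumor_mass(const_volume(mask, 0), mask)
  expect_lt(abs(m0 - 4188.8) / 4188.8, 0.05)
  # HU = -1000 (air): zero mass
  expect_equal(compute_tumor_mass(const_volume(mask, -1000), mask), 0)
  # equal volumes, partial-solid vs solid density ordering
  expect_lt(compute_tumor_mass(const_volume(mask, -630), mask),
            compute_tumor_mass(const_volume(mask, 100), mask))
})

test_that("mass and volume are additive over disjoint components", {
  sp <- c(0.7, 0.7, 0.7)
  n <- c(41L, 41L, 41L)
  m1 <- array(FALSE, n); m1[5:10, 5:10, 5:10] <- TRUE
  m2 <- array(FALSE, n); m2[30:38, 30:38, 30:38] <- TRUE
  vol <- ct_volume(array(50, n), sp)
  mass_both <- compute_tumor_mass(vol, lesion_mask(m1 | m2, sp))
  mass_sep <- compute_tumor_mass(vol, lesion_mask(m1, sp)) +
    compute_tumor_mass(vol, lesion_mask(m2, sp))
  expect_equal(mass_both, mass_sep)
  v_both <- compute_size(vol, lesion_mask(m1 | m2, sp))$volume_mm3
  v_sep <- compute_size(vol, lesion_mask(m1, sp))$volume_mm3 +
    compute_size(vol, lesion_mask(m2, sp))$volume_mm3
  expect_equal(v_both, v_sep)
})

test_that("size features match analytic sphere values and the cube law", {
  sp <- c(0.5, 0.5, 0.5)
  m10 <- make_ball_mask(R = 5, spacing = sp)
  sz <- compute_size(const_volume(m10, 0), m10)
  expect_lt(abs(sz$volume_mm3 - 523.6) / 523.6, 0.05)
  expect_lt(abs(sz$largest_diameter_mm - 10), sp[1] + 1e-9)
  m20 <- make_ball_mask(R = 10, spacing = sp)
  sz20 <- compute_size(const_volume(m20, 0), m20)
  expect_lt(abs(sz20$volume_mm3 / sz$volume_mm3 - 8), 0.8)
  # single voxel: volume equals voxel volume
  one <- array(FALSE, c(9L, 9L, 9L)); one[5, 5, 5] <- TRUE
  mk <- lesion_mask(one, c(0.7, 0.7, 0.7))
  expect_equal(compute_size(const_volume(mk, 0), mk)$volume_mm3,
               0.7 * 0.7 * 0.7)
})

test_that("features are invariant to whole-voxel lesion translation", {
  sp <- c(0.7, 0.7, 0.7)
  n <- c(41L, 41L, 41L)
  set.seed(31)
  block <- array(rnorm(13^3, -100, 40), c(13L, 13L, 13L))
  embed_at <- function(origin) {
    arr <- array(-850, n)
    m <- array(FALSE, n)
    ix <- origin[1]:(origin[1] + 12L)
    iy <- origin[2]:(origin[2] + 12L)
    iz <- origin[3]:(origin[3] + 12L)
    arr[ix, iy, iz] <- block
    # ball mask centred on the block
    ctr <- origin + 6L
    for (i in ix) for (j in iy) for (k in iz) {
      m[i, j, k] <- sum(((c(i, j, k) - ctr) * sp)^2) <= 4^2
    }
    list(volume = ct_volume(arr, sp), mask = lesion_mask(m, sp))
  }
  a <- embed_at(c(5L, 5L, 5L))
  b <- embed_at(c(20L, 14L, 18L))
  expect_equal(compute_tumor_mass(a$volume, a$mask),
               compute_tumor_mass(b$volume, b$mask))
  expect_equal(compute_size(a$volume, a$mask)$volume_mm3,
               compute_size(b$volume, b$mask)$volume_mm3)
  expect_equal(compute_dwt_energy(a$volume, a$mask),
               compute_dwt_energy(b$volume, b$mask))
  expect_equal(compute_gabor_energy(a$volume, a$mask),
               compute_gabor_energy(b$volume, b$mask), tolerance = 1e-6)
})

test_that("empty masks are errors, never silent zeros", {
  sp <- c(0.7, 0.7, 0.7)
  empty <- lesion_mask(array(FALSE, c(8L, 8L, 8L)), sp)
  vol <- const_volume(empty, 0)
  expect_error(compute_tumor_mass(vol, empty), "empty")
  expect_error(compute_size(vol, empty), "empty")
  expect_error(compute_gabor_energy(vol, empty), "empty")
  expect_error(compute_dwt_energy(vol, empty), "empty")
  expect_error(compute_sigmoid_offset_mean(vol, empty), "empty")
})

test_that("delta features subtract baseline minus follow-up", {
  b <- c(tumor_mass = 5, dwt_energy = 1)
  f <- c(tumor_mass = 3, dwt_energy = 4)
  expect_equal(delta_features(b, f), c(tumor_mass = 2, dwt_energy = -3))
  expect_equal(unname(delta_features(b, b)), c(0, 0))
  # growth on follow-up yields a negative delta
  expect_equal(unname(delta_features(c(m = 1.0e6), c(m = 5.07e6))), -4.07e6)
  expect_error(delta_features(b, c(tumor_mass = 3, other = 1)), "schema")
})

test_that("extract_features bundles all six features finitely", {
  les <- make_sigmoid_sphere(R = 6)
  fv <- extract_features(les$volume, les$mask)
  expect_named(fv, c("tumor_mass", "sigmoid_offset_mean", "gabor_energy",
                     "dwt_energy", "volume_mm3", "largest_diameter_mm"))
  expect_true(all(is.finite(fv)))
  expect_gt(fv[["volume_mm3"]], 0)
})
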