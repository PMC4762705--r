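# Volume registration on the synthetic phantom: ground-truth recovery
# must stay within half a voxel (0.2 mm at 0.4 mm spacing) and 0.5 deg.

phantom40 <- generate_phantom(seed = 5, dim = c(40L, 40L, 40L))

rotation_angle_deg <- function(r1, r2) {
  dr <- r1 %*% t(r2)
  acos(max(-1, min(1, (sum(diag(dr)) - 1) / 2))) * 180 / pi
}

center_error_mm <- function(fit_tf, true_tf, center) {
  sqrt(sum((apply_transform(fit_tf, center) -
              apply_transform(true_tf, center))^2))
}

test_that("a volume registers to itself as the identity", {
  vol <- phantom40$volume
  fit <- register_volumes_rigid(vol, vol, mask = phantom40$cranial_mask)
  expect_lt(max(abs(fit$transform$translation)), 0.05 * vol$spacing[1])
  expect_lt(rotation_angle_deg(fit$transform$rotation, diag(3)), 0.1)
  expect_equal(det(fit$transform$rotation), 1, tolerance = 1e-9)
})

test_that("an integer-voxel shift is recovered within half a voxel", {
  vol <- phantom40$volume
  shift <- rigid_transform(diag(3), c(2, 1, -1) * vol$spacing)
  fixed <- gnathometry:::voxelize_density(phantom40$shape, dim(vol$data),
                                          vol$spacing, vol$origin,
                                          pose = shift)
  fit <- register_volumes_rigid(vol, fixed)
  expect_lt(max(abs(fit$transform$translation - shift$translation)), 0.2)
  expect_lt(rotation_angle_deg(fit$transform$rotation, diag(3)), 0.5)
})

test_that("rotation plus translation is recovered and is self-consistent", {
  vol <- phantom40$volume
  ctr <- vol$origin + (dim(vol$data) - 1) / 2 * vol$spacing
  r <- rotation_about_axis(c(0.2, -0.1, 1), 5)
  true_tf <- rigid_transform(r, c(1.2, -0.8, 1.5) + ctr -
                               as.numeric(r %*% ctr))
  fixed <- gnathometry:::voxelize_density(phantom40$shape, dim(vol$data),
                                          vol$spacing, vol$origin,
                                          pose = true_tf)
  fwd <- register_volumes_rigid(vol, fixed)
  expect_lt(center_error_mm(fwd$transform, true_tf, ctr), 0.2)
  expect_lt(rotation_angle_deg(fwd$transform$rotation, true_tf$rotation), 0.5)
  expect_equal(det(fwd$transform$rotation), 1, tolerance = 1e-9)

  # registering the other way gives (approximately) the inverse
  bwd <- register_volumes_rigid(fixed, vol)
  round_trip <- compose(fwd$transform, bwd$transform)
  expect_lt(max(abs(round_trip$translation)), 0.1)
  expect_lt(rotation_angle_deg(round_trip$rotation, diag(3)), 0.2)
})

test_that("crop_to_mask keeps exactly the masked region", {
  vol <- volume_image(array(seq_len(16^3) / 16^3, dim = c(16, 16, 16)),
                      spacing = 1)
  full <- region_mask(array(TRUE, dim = c(16, 16, 16)))
  expect_equal(crop_to_mask(vol, full)$data, vol$data)

  single <- array(FALSE, dim = c(16, 16, 16)); single[4, 7, 9] <- TRUE
  cs <- crop_to_mask(vol, region_mask(single))
  expect_equal(dim(cs$data), c(1L, 1L, 1L))
  expect_equal(cs$data[1, 1, 1], vol$data[4, 7, 9])
  expect_equal(cs$origin, c(3, 6, 8))

  half <- array(FALSE, dim = c(16, 16, 16)); half[1:8, , ] <- TRUE
  ch <- crop_to_mask(vol, region_mask(half))
  expect_equal(mean(ch$data, na.rm = TRUE), mean(vol$data[1:8, , ]))

  expect_error(region_mask(array(FALSE, dim = c(16, 16, 16))), "empty")
  small <- region_mask(array(TRUE, dim = c(8, 8, 8)))
  expect_error(crop_to_mask(vol, small), "shape")
})

test_that("masked registration requires usable voxels", {
  vol <- phantom40$volume
  thin <- array(FALSE, dim = dim(vol$data)); thin[1:2, 1:2, 1:2] <- TRUE
  expect_error(register_volumes_rigid(vol, vol, mask = region_mask(thin)),
               "too few usable voxels")
})
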