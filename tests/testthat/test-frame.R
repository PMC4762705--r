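test_that("canonical landmark configuration yields the world frame", {
  fr <- build_frame(oracle_canonical_landmarks())
  expect_equal(fr$axis_lr, c(1, 0, 0), tolerance = 1e-12)
  expect_equal(fr$axis_ap, c(0, 1, 0), tolerance = 1e-12)
  expect_equal(fr$axis_ud, c(0, 0, 1), tolerance = 1e-12)
  expect_equal(fr$origin, c(0, 10, 20))
})

test_that("frame axes rotate with the head and ignore translation", {
  lm <- oracle_canonical_landmarks()
  set.seed(11)
  for (i in 1:20) {
    r_star <- oracle_random_rotation()
    fr <- build_frame(rigidly_moved_landmarks(lm, r_star, runif(3, -30, 30)))
    expect_lt(max(abs(fr$axis_lr - r_star %*% c(1, 0, 0))), 1e-9)
    expect_lt(max(abs(fr$axis_ap - r_star %*% c(0, 1, 0))), 1e-9)
    expect_lt(max(abs(fr$axis_ud - r_star %*% c(0, 0, 1))), 1e-9)
  }
  fr <- build_frame(rigidly_moved_landmarks(lm, diag(3), c(10, 10, 10)))
  expect_equal(fr$axis_lr, c(1, 0, 0), tolerance = 1e-12)
  expect_equal(fr$origin, c(10, 20, 30))
})

test_that("frame axes are orthonormal and right-handed for valid inputs", {
  set.seed(12)
  lm <- oracle_canonical_landmarks()
  for (i in 1:50) {
    # jittered anatomy, arbitrary pose
    jl <- lapply(unclass(lm), function(p) p + rnorm(3, 0, 2))
    fr <- build_frame(rigidly_moved_landmarks(landmark_set(jl),
                                              oracle_random_rotation(),
                                              runif(3, -50, 50)))
    b <- fr$basis
    expect_lt(max(abs(crossprod(b) - diag(3))), 1e-9)
    cross_lr_ap <- c(b[2, 1] * b[3, 2] - b[3, 1] * b[2, 2],
                     b[3, 1] * b[1, 2] - b[1, 1] * b[3, 2],
                     b[1, 1] * b[2, 2] - b[2, 1] * b[1, 2])
    expect_lt(max(abs(cross_lr_ap - b[, 3])), 1e-9)
  }
})

test_that("missing or degenerate reference landmarks are reported", {
  lm <- unclass(oracle_canonical_landmarks())
  expect_error(build_frame(landmark_set(lm[names(lm) != "sella"])), "sella")
  expect_error(build_frame(landmark_set(
    lm[!names(lm) %in% c("orbitale_left", "orbitale_right")])), "orbitale")
  lm2 <- lm; lm2$porion_left <- lm2$porion_right
  expect_error(build_frame(landmark_set(lm2)), "porions")
})

test_that("decomposition reports the clinical components with their sign conventions", {
  fr <- build_frame(oracle_canonical_landmarks())

  z <- decompose_transform(rt_identity(), fr)
  expect_equal(max_component_error(z), 0)

  # +5 degree pitch about the LR axis through the origin point
  rp <- rigid_transform(oracle_axis_rotation(fr$axis_lr, 5))
  rp <- rigid_transform(rp$rotation,
                        fr$origin - as.numeric(rp$rotation %*% fr$origin))
  rep <- decompose_transform(rp, fr)
  expect_lt(max_component_error(rep, pitch = 5), 1e-9)

  # posterior displacement is negative AP
  tp <- decompose_transform(rigid_transform(diag(3), -2 * fr$axis_ap), fr)
  expect_lt(max_component_error(tp, d_ap = -2), 1e-12)
  # cranial displacement is positive UD, rightward positive LR
  expect_lt(max_component_error(
    decompose_transform(rigid_transform(diag(3), 1.5 * fr$axis_ud), fr),
    d_ud = 1.5), 1e-12)
  expect_lt(max_component_error(
    decompose_transform(rigid_transform(diag(3), 0.5 * fr$axis_lr), fr),
    d_lr = 0.5), 1e-12)
})

test_that("decompose/recompose round-trips 1000 random transforms to 1e-9", {
  set.seed(13)
  fr <- build_frame(rigidly_moved_landmarks(oracle_canonical_landmarks(),
                                            oracle_random_rotation(),
                                            c(5, -8, 12)))
  worst <- 0
  for (i in 1:1000) {
    rep <- movement_report(d_ap = runif(1, -5, 5), d_lr = runif(1, -5, 5),
                           d_ud = runif(1, -5, 5), pitch = runif(1, -45, 45),
                           roll = runif(1, -45, 45), yaw = runif(1, -45, 45))
    tf <- recompose_transform(rep, fr)
    back <- decompose_transform(tf, fr)
    worst <- max(worst, max_component_error(back, rep$d_ap, rep$d_lr,
                                            rep$d_ud, rep$pitch, rep$roll,
                                            rep$yaw))
  }
  expect_lt(worst, 1e-9)
})

test_that("translation components do not depend on the reference center", {
  fr <- build_frame(oracle_canonical_landmarks())
  tf <- rigid_transform(diag(3), c(1, -2, 3))
  a <- decompose_transform(tf, fr, center = c(0, 0, 0))
  b <- decompose_transform(tf, fr, center = c(40, -25, 60))
  expect_equal(c(a$d_ap, a$d_lr, a$d_ud), c(b$d_ap, b$d_lr, b$d_ud),
               tolerance = 1e-12)
})

test_that("gimbal lock raises an explicit error", {
  fr <- build_frame(oracle_canonical_landmarks())
  tf <- rigid_transform(oracle_axis_rotation(fr$axis_ap, 90))
  expect_error(decompose_transform(tf, fr), "gimbal")
})

test_that("Euler-order sensitivity stays second-order small at small angles", {
  # Cross-order discrepancy grows with the square of the angles: approx
  # 0.16 deg when each angle reaches 3 deg, under 0.02 deg at 1 deg.
  # Regression-tested at the measured bounds.
  fr <- build_frame(oracle_canonical_landmarks())
  # closed-form intrinsic x-y-z extraction (the reverse of the
  # implementation's z-y-x sequence, which maximizes the commutator
  # difference between orders)
  extract_xyz <- function(r) {
    c(x = atan2(-r[2, 3], r[3, 3]), y = asin(max(-1, min(1, r[1, 3]))),
      z = atan2(-r[1, 2], r[1, 1])) * 180 / pi
  }
  set.seed(14)
  for (amax in c(1, 3)) {
    worst <- 0
    for (i in 1:400) {
      ang <- runif(3, -amax, amax)
      rep <- movement_report(pitch = ang[1], roll = ang[2], yaw = ang[3])
      rf <- crossprod(fr$basis,
                      recompose_transform(rep, fr)$rotation %*% fr$basis)
      p <- extract_xyz(rf)
      worst <- max(worst, max(abs(p - ang)))
    }
    expect_lt(worst, if (amax == 1) 0.02 else 0.2)
  }
})

test_that("proximal measures pick out autorotation and flare", {
  fr <- build_frame(oracle_canonical_landmarks())
  expect_equal(unlist(proximal_measures(rt_identity(), fr, "left")
                      [c("autorotation", "flare")]),
               c(autorotation = 0, flare = 0))
  r3 <- rigid_transform(oracle_axis_rotation(fr$axis_lr, 3))
  p <- proximal_measures(r3, fr, "left", center = c(0, 0, 0))
  expect_equal(p$autorotation, 3, tolerance = 1e-9)
  expect_equal(p$flare, 0, tolerance = 1e-9)
  r2 <- rigid_transform(oracle_axis_rotation(fr$axis_ud, 2))
  p <- proximal_measures(r2, fr, "right", center = c(0, 0, 0))
  expect_equal(p$flare, 2, tolerance = 1e-9)
  expect_equal(p$autorotation, 0, tolerance = 1e-9)
})
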