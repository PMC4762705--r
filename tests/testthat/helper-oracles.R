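# Independent oracles used across tests. These deliberately avoid the
# package's SVD/Kabsch code path.

# Random rotation matrix from a uniform random unit quaternion.
oracle_random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  oracle_quat_to_matrix(q)
}

oracle_quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    3, 3, byrow = TRUE)
}

# Horn's closed-form absolute orientation: rotation as the eigenvector
# of the 4x4 quaternion matrix with the largest eigenvalue.
oracle_horn_rotation <- function(src, tgt) {
  s <- sweep(src, 2, colMeans(src))
  t <- sweep(tgt, 2, colMeans(tgt))
  m <- crossprod(s, t)
  sxx <- m[1, 1]; sxy <- m[1, 2]; sxz <- m[1, 3]
  syx <- m[2, 1]; syy <- m[2, 2]; syz <- m[2, 3]
  szx <- m[3, 1]; szy <- m[3, 2]; szz <- m[3, 3]
  n <- matrix(c(
    sxx + syy + szz, syz - szy,       szx - sxz,       sxy - syx,
    syz - szy,       sxx - syy - szz, sxy + syx,       szx + sxz,
    szx - sxz,       sxy + syx,       -sxx + syy - szz, syz + szy,
    sxy - syx,       szx + sxz,       syz + szy,       -sxx - syy + szz),
    4, 4, byrow = TRUE)
  ev <- eigen(n, symmetric = TRUE)
  oracle_quat_to_matrix(ev$vectors[, 1])
}

# Closed-form right-handed axis-angle rotation (Rodrigues), written
# independently of the package helper.
oracle_axis_rotation <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  c <- cos(th); s <- sin(th)
  outer(u, u) * (1 - c) + diag(3) * c +
    matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3) * s
}

# A well-conditioned maxillary test triangle (mm).
oracle_triangle <- function(state = "preop") {
  segment_triangle("maxilla",
                   rbind(c(25, 55, -33), c(0, 85, -35), c(-25, 55, -33)),
                   state)
}

# Canonical landmark configuration: porions span x, Frankfort plane =
# xy-plane, nasion anterior on +y, so the frame axes are the world axes.
oracle_canonical_landmarks <- function() {
  landmark_set(
    nasion = c(0, 80, 25), sella = c(0, 10, 20),
    porion_left = c(-58, 0, 0), porion_right = c(58, 0, 0),
    orbitale_left = c(-30, 65, 0), orbitale_right = c(30, 65, 0),
    upper_incisor = c(0, 85, -35),
    mesial_cusp_16 = c(25, 55, -33), mesial_cusp_26 = c(-25, 55, -33),
    lower_incisor = c(0, 83, -48),
    mesial_cusp_36 = c(-26, 53, -45), mesial_cusp_46 = c(26, 53, -45),
    condor_left = c(-55, -5, -5), condor_right = c(55, -5, -5),
    c_point_left = c(-52, 3, -20), c_point_right = c(52, 3, -20),
    gonion_left = c(-50, 0, -70), gonion_right = c(50, 0, -70))
}

rigidly_moved_landmarks <- function(lm, rotation, translation = c(0, 0, 0)) {
  tf <- rigid_transform(rotation, translation)
  out <- lapply(unclass(lm), function(p) apply_transform(tf, p))
  landmark_set(out)
}

max_component_error <- function(report, d_ap = 0, d_lr = 0, d_ud = 0,
                                pitch = 0, roll = 0, yaw = 0) {
  max(abs(c(report$d_ap - d_ap, report$d_lr - d_lr, report$d_ud - d_ud,
            report$pitch - pitch, report$roll - roll, report$yaw - yaw)))
}
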