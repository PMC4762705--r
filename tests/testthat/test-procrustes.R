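test_that("procrustes fit solves the trivial cases exactly", {
  a <- oracle_triangle()
  b <- oracle_triangle("planned")
  fit <- procrustes_rigid(a, b)
  expect_equal(fit$transform$rotation, diag(3), tolerance = 1e-12)
  expect_lt(max(abs(fit$transform$translation)), 1e-12)
  expect_lt(fit$rmsd, 1e-12)

  shifted <- segment_triangle("maxilla",
                              sweep(a$vertices, 2, c(1, 2, 3), "+"),
                              "planned")
  fit <- procrustes_rigid(a, shifted)
  expect_equal(fit$transform$rotation, diag(3), tolerance = 1e-12)
  expect_equal(fit$transform$translation, c(1, 2, 3), tolerance = 1e-12)
  expect_lt(fit$rmsd, 1e-12)
})

test_that("procrustes recovers 1000 random rigid transforms to 1e-9", {
  set.seed(101)
  src <- oracle_triangle()
  worst_r <- 0; worst_t <- 0; worst_rmsd <- 0
  for (i in 1:1000) {
    r_star <- oracle_random_rotation()
    t_star <- runif(3, -20, 20)
    tgt <- segment_triangle(
      "maxilla", sweep(src$vertices %*% t(r_star), 2, t_star, "+"),
      "postop")
    fit <- procrustes_rigid(src, tgt)
    worst_r <- max(worst_r, max(abs(fit$transform$rotation - r_star)))
    worst_t <- max(worst_t, max(abs(fit$transform$translation - t_star)))
    worst_rmsd <- max(worst_rmsd, fit$rmsd)
  }
  expect_lt(worst_r, 1e-9)
  expect_lt(worst_t, 1e-9)
  expect_lt(worst_rmsd, 1e-9)
})

test_that("procrustes rotation agrees with Horn's quaternion solution", {
  set.seed(102)
  src <- oracle_triangle()
  for (i in 1:25) {
    # noisy correspondence: the two solvers must still agree
    tgt_v <- sweep(src$vertices %*% t(oracle_random_rotation()), 2,
                   runif(3, -5, 5), "+") + matrix(rnorm(9, 0, 0.5), 3, 3)
    fit <- procrustes_rigid(src, segment_triangle("maxilla", tgt_v, "postop"))
    horn <- oracle_horn_rotation(src$vertices, tgt_v)
    expect_lt(max(abs(fit$transform$rotation - horn)), 1e-8)
  }
})

test_that("mirrored targets never yield a reflection", {
  # a triangle is planar, hence achiral: its mirror image is reached by
  # a proper 180-degree flip, so the fit must be proper AND exact
  src <- segment_triangle("maxilla",
                          rbind(c(30, 50, -30), c(-3, 88, -39),
                                c(-25, 55, -28)))
  mirrored <- src$vertices %*% diag(c(-1, 1, 1))
  fit <- procrustes_rigid(src, segment_triangle("maxilla", mirrored, "postop"))
  expect_equal(det(fit$transform$rotation), 1, tolerance = 1e-9)
  expect_lt(fit$rmsd, 1e-9)

  # a chiral (non-coplanar) point set cannot be mirrored by any proper
  # motion: determinant stays +1 and a residual remains
  tet <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 8, 0), c(0, 0, 6))
  fit4 <- gnathometry:::kabsch(tet, tet %*% diag(c(-1, 1, 1)))
  expect_equal(det(fit4$transform$rotation), 1, tolerance = 1e-9)
  expect_gt(fit4$rmsd, 1e-3)
})

test_that("degenerate and mismatched triangles are rejected", {
  expect_error(segment_triangle("maxilla",
                                rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))),
               "collinear")
  a <- oracle_triangle()
  b <- segment_triangle("mandible_distal",
                        rbind(c(26, 53, -45), c(0, 83, -48), c(-26, 53, -45)),
                        "postop")
  expect_error(procrustes_rigid(a, b), "segment_id")
})

test_that("transformed triangles keep their inter-vertex distances", {
  set.seed(103)
  src <- oracle_triangle()
  for (i in 1:50) {
    tf <- random_rigid(170, 50)
    moved <- apply_transform(tf, src$vertices)
    expect_equal(as.vector(dist(moved)), as.vector(dist(src$vertices)),
                 tolerance = 1e-9)
    expect_equal(triangle_area(moved), triangle_area(src), tolerance = 1e-9)
  }
})
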