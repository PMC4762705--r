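test_that("phantom generation is deterministic and well-conditioned", {
  a <- generate_phantom(seed = 7, dim = c(24L, 24L, 24L))
  b <- generate_phantom(seed = 7, dim = c(24L, 24L, 24L))
  expect_identical(a$landmarks, b$landmarks)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$meshes$maxilla$vertices, b$meshes$maxilla$vertices)
  c <- generate_phantom(seed = 8, dim = c(24L, 24L, 24L))
  expect_false(identical(a$landmarks, c$landmarks))

  fr <- build_frame(a$landmarks)
  expect_lt(max(abs(crossprod(fr$basis) - diag(3))), 1e-9)
  for (seg in c("maxilla", "mandible_distal", "proximal_left",
                "proximal_right")) {
    tri <- triangle_from_landmarks(a$landmarks, seg)
    expect_gt(triangle_area(tri), 10)
  }
  expect_true(any(a$cranial_mask$data))
  expect_identical(dim(a$cranial_mask$data), dim(a$volume$data))
})

test_that("simulated surgeries close over their ground-truth transforms", {
  phantom <- generate_phantom(seed = 4)
  plan <- list(maxilla = rigid_transform(rotation_about_axis(c(1, 0, 0), 2),
                                         c(0, 4, -1)))
  case <- simulate_surgery(phantom, plan, error_model(landmark_noise_sd = 0),
                           seed = 21)
  for (seg in names(case$ground_truth)) {
    gt <- case$ground_truth[[seg]]
    total <- compose(gt$error, gt$plan)
    moved <- apply_transform(total, gt$triangle_preop$vertices)
    expect_equal(moved, gt$triangle_postop$vertices, tolerance = 1e-9)
    expect_equal(det(gt$error$rotation), 1, tolerance = 1e-9)
  }
  # same seed regenerates bit-identically
  case2 <- simulate_surgery(phantom, plan, error_model(landmark_noise_sd = 0),
                            seed = 21)
  expect_identical(case$postop_triangles, case2$postop_triangles)
})

test_that("zero error model makes the postop state equal the plan", {
  phantom <- generate_phantom(seed = 4)
  fr <- build_frame(phantom$landmarks)
  zero <- error_model(translation_mean = c(0, 0, 0),
                      translation_sd = c(0, 0, 0),
                      rotation_mean = c(0, 0, 0), rotation_sd = c(0, 0, 0),
                      landmark_noise_sd = 0)
  plan <- list(maxilla = rigid_transform(diag(3), 4 * fr$axis_ap))
  case <- simulate_surgery(phantom, plan, zero, seed = 22,
                           segments = "maxilla")
  expect_equal(case$postop_triangles$maxilla$vertices,
               case$ground_truth$maxilla$triangle_planned$vertices,
               tolerance = 1e-12)
  res <- compute_case(case)
  expect_lt(max_component_error(res$accuracy$maxilla), 1e-9)
  expect_equal(res$displacement$maxilla$d_ap, 4, tolerance = 1e-9)
})

test_that("cohort error draws land near their model expectation", {
  # AP error ~ N(-0.5, 1.5^2): the absolute-mean of a folded normal is
  # sigma*sqrt(2/pi)*exp(-mu^2/(2 s^2)) + mu*(1-2*pnorm(-mu/s))
  phantom <- generate_phantom(seed = 4)
  em <- error_model(translation_mean = c(ap = -0.5, lr = 0, ud = 0),
                    translation_sd = c(ap = 1.5, lr = 0, ud = 0),
                    rotation_mean = c(0, 0, 0), rotation_sd = c(0, 0, 0),
                    landmark_noise_sd = 0)
  reports <- list()
  for (i in 1:10) {
    case <- simulate_surgery(phantom, list(), em, seed = 300 + i,
                             segments = "maxilla")
    reports[[i]] <- compute_case(case)$accuracy$maxilla
  }
  s <- summarize_cohort(reports)
  mu <- -0.5; sd <- 1.5
  expected_abs <- sd * sqrt(2 / pi) * exp(-mu^2 / (2 * sd^2)) +
    mu * (1 - 2 * pnorm(-mu / sd))
  se <- sd / sqrt(10)
  expect_lt(abs(s$abs_mean[s$component == "d_ap"] - expected_abs), 3 * se)
  expect_lt(abs(s$mean[s$component == "d_ap"] - mu), 3 * se)
})

test_that("noise-free observer sessions are identical across sessions", {
  phantom <- generate_phantom(seed = 4)
  cases <- lapply(1:3, function(i)
    simulate_surgery(phantom, list(), error_model(landmark_noise_sd = 0),
                     seed = 30 + i, segments = c("maxilla",
                                                 "mandible_distal")))
  grid <- simulate_observer_sessions(
    cases, landmark_noise_sd = 0,
    reg_noise = alignment_noise(c(0, 0, 0), c(0, 0, 0)),
    n_sessions = 3, seed = 40)
  v <- observer_variation(grid, "observer1_t1", "observer2", n_boot = 50)
  expect_true(all(v$value == 0))
})
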