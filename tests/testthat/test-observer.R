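make_grid <- function(values, sessions = c("observer1_t1", "observer1_t2")) {
  # values: patients x sessions matrix for a single component
  arr <- array(values, dim = c(nrow(values), length(sessions), 1),
               dimnames = list(patient = paste0("p", seq_len(nrow(values))),
                               session = sessions, component = "d_ap"))
  measurement_grid(arr)
}

test_that("observer variation is the mean absolute session difference", {
  set.seed(31)
  base <- rnorm(10, sd = 2)
  g <- make_grid(cbind(base, base))
  v <- observer_variation(g, "observer1_t1", "observer1_t2", n_boot = 100)
  expect_equal(v$value, 0)

  g <- make_grid(cbind(base, base + 0.1))
  v <- observer_variation(g, "observer1_t1", "observer1_t2", n_boot = 100)
  expect_equal(v$value, 0.1)

  # brute-force oracle on half-normal differences
  d <- abs(rnorm(10, 0, 0.1))
  g <- make_grid(cbind(base, base + d * sample(c(-1, 1), 10, TRUE)))
  v <- observer_variation(g, "observer1_t1", "observer1_t2", n_boot = 100)
  expect_equal(v$value, mean(d), tolerance = 1e-12)

  # symmetry in the two sessions, CI brackets the point estimate
  v2 <- observer_variation(g, "observer1_t2", "observer1_t1", n_boot = 2000,
                           seed = 4)
  expect_equal(v2$value, v$value)
  expect_lte(v2$ci_low, v2$value)
  expect_gte(v2$ci_high, v2$value)
})

test_that("grids refuse missing cells and undersized designs", {
  arr <- array(rnorm(8), dim = c(4, 2, 1),
               dimnames = list(paste0("p", 1:4), c("a", "b"), "d_ap"))
  arr[2, 1, 1] <- NA
  g <- measurement_grid(arr)
  expect_error(observer_variation(g, "a", "b"), "missing")
  expect_error(icc(g, c("a", "b")), "missing")
  expect_error(measurement_grid(array(1:4, dim = c(1, 2, 2))), "2 patients")
  expect_error(measurement_grid(array(1:4, dim = c(2, 1, 2))), "2 sessions")
})

test_that("ICC(2,1) matches an independent aov mean-squares oracle", {
  # small integer grid, 6 patients x 2 raters
  y <- rbind(c(9, 2), c(6, 1), c(8, 4), c(7, 1), c(10, 5), c(6, 2))
  g <- make_grid(y)
  got <- icc(g, c("observer1_t1", "observer1_t2"))$value

  long <- data.frame(v = as.vector(y),
                     patient = factor(rep(1:6, 2)),
                     rater = factor(rep(1:2, each = 6)))
  ms <- anova(aov(v ~ patient + rater, data = long))[["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  n <- 6; k <- 2
  want <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("ICC reaches 1 for identical sessions and falls with noise", {
  set.seed(32)
  base <- rnorm(10, sd = 2)
  expect_equal(icc(make_grid(cbind(base, base)))$value, 1)

  # SNR near zero: signal sd 0.01 against noise sd 2
  tiny <- rnorm(12, sd = 0.01)
  noisy <- cbind(tiny + rnorm(12, sd = 2), tiny + rnorm(12, sd = 2))
  expect_lt(icc(make_grid(noisy))$value, 0.2)

  # zero between-patient variance is an explicit error
  flat <- matrix(5, 6, 2)
  expect_error(icc(make_grid(flat)), "between-patient")
})

test_that("ICC is invariant to shifts and positive scalings", {
  set.seed(33)
  y <- cbind(rnorm(8, sd = 2), rnorm(8, sd = 2) + 0.3)
  v0 <- icc(make_grid(y))$value
  expect_equal(icc(make_grid(y + 7))$value, v0, tolerance = 1e-12)
  expect_equal(icc(make_grid(y * 3.5))$value, v0, tolerance = 1e-12)
})

test_that("ICC confidence intervals bracket the estimate", {
  set.seed(34)
  sig <- rnorm(10, sd = 2)
  y <- cbind(sig + rnorm(10, sd = 0.3), sig + rnorm(10, sd = 0.3),
             sig + rnorm(10, sd = 0.3))
  g <- measurement_grid(array(y, dim = c(10, 3, 1),
                              dimnames = list(paste0("p", 1:10),
                                              c("s1", "s2", "s3"), "d_ap")))
  r <- icc(g)
  expect_lte(r$ci_low, r$value)
  expect_gte(r$ci_high, r$value)
  expect_lte(r$value, 1)
})
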