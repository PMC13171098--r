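# Lateral deviation, exponential fits, savings classification, statistics.

test_that("lateral deviation recovers planted arc offsets with sign", {
  start <- c(0.1, 0.2); target <- c(0.25, 0.35)
  expect_equal(lateral_deviation(synth_trajectory(start, target, 0),
                                 start, target), 0, tolerance = 1e-12)
  expect_equal(lateral_deviation(synth_trajectory(start, target, 0.02),
                                 start, target), 0.02, tolerance = 1e-9)
  expect_equal(lateral_deviation(synth_trajectory(start, target, -0.02),
                                 start, target), -0.02, tolerance = 1e-9)
  expect_error(lateral_deviation(synth_trajectory(start, start, 0.01),
                                 start, start), "coincide")
})

test_that("lateral deviation is invariant under rigid rotation of the scene", {
  set.seed(4)
  for (i in 1:20) {
    start <- rnorm(2); target <- start + rnorm(2)
    off <- rnorm(1, sd = 0.03)
    path <- synth_trajectory(start, target, off)
    d0 <- lateral_deviation(path, start, target)
    th <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    expect_equal(lateral_deviation(path %*% t(R), drop(R %*% start),
                                   drop(R %*% target)), d0,
                 tolerance = 1e-10)
  }
})

test_that("exponential fit recovers noiseless parameters and scales correctly", {
  cv <- synth_learning_curve(0.02, 2, sigma = 0, n_batches = 200)
  # without smoothing the recovery is exact
  f1 <- fit_learning_curve(cv, kernel = 1L)
  expect_equal(f1$alpha, 0.02, tolerance = 1e-6)
  expect_equal(f1$r, 2, tolerance = 1e-6)
  # the default 5-batch smoothing perturbs the optimum only marginally
  f <- fit_learning_curve(cv)
  expect_true(f$converged)
  expect_equal(f$alpha, 0.02, tolerance = 1e-3)
  expect_equal(f$r, 2, tolerance = 1e-3)
  # constant curve: r ~ 0
  f0 <- fit_learning_curve(synth_learning_curve(0.05, 0, n_batches = 50))
  expect_equal(f0$r, 0, tolerance = 1e-6)
  # doubling y doubles alpha, leaves r unchanged
  cv2 <- learning_curve(2 * cv$deviation, batch = cv$batch)
  f2 <- fit_learning_curve(cv2)
  expect_equal(f2$alpha, 2 * f$alpha, tolerance = 1e-6)
  expect_equal(f2$r, f$r, tolerance = 1e-5)
})

test_that("savings classification uses strict inequalities and is antisymmetric", {
  fit <- function(r) structure(list(r = r), class = "exp_fit")
  s <- classify_savings(fit(1.8), fit(2.5), 0.03, 0.02)
  expect_true(s$rate_savings); expect_true(s$deviation_savings)
  # ties are not savings
  expect_false(classify_savings(fit(2), fit(2), 0.03, 0.03)$rate_savings)
  expect_false(classify_savings(fit(2), fit(2), 0.03, 0.03)$deviation_savings)
  # the opposite-field expectation: both false
  s2 <- classify_savings(fit(2.5), fit(1.8), 0.02, 0.03)
  expect_false(s2$rate_savings); expect_false(s2$deviation_savings)
  # swapping inputs negates both flags (ties aside)
  expect_equal(classify_savings(fit(2.5), fit(1.8), 0.02, 0.03),
               lapply(classify_savings(fit(1.8), fit(2.5), 0.03, 0.02),
                      isFALSE))
})

test_that("Wilson interval matches a brute-force score-test inversion", {
  wilson_brute <- function(k, n, conf = 0.95) {
    z <- qnorm(1 - (1 - conf) / 2)
    ph <- k / n
    grid <- seq(0, 1, by = 1e-6)
    ok <- abs(ph - grid) <= z * sqrt(grid * (1 - grid) / n)
    100 * range(grid[ok])
  }
  sr <- savings_rate(c(rep(TRUE, 32), rep(FALSE, 8)))
  expect_equal(sr$percentage, 80)
  bf <- wilson_brute(32, 40)
  expect_equal(unname(sr$ci), bf, tolerance = 1e-4)
  sr0 <- savings_rate(rep(FALSE, 40))
  expect_equal(sr0$percentage, 0)
  expect_equal(unname(sr0$ci[1]), 0)
  expect_error(savings_rate(logical(0)), "empty")
})

test_that("paired t statistic matches a hand computation", {
  a <- c(2.1, 3.4, 1.9, 4.2, 2.8)
  b <- c(1.8, 3.1, 2.0, 3.6, 2.5)
  res <- paired_t(a, b)
  d <- a - b
  t_hand <- mean(d) / (sd(d) / sqrt(5))
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$df, 4)
  expect_equal(res$p, 2 * stats::pt(-abs(t_hand), 4), tolerance = 1e-12)
  # identical samples -> t = 0; df is n - 1
  expect_equal(paired_t(a, a)$t, 0)
  expect_equal(paired_t(rnorm(40), rnorm(40))$df, 39)
  expect_error(paired_t(a, a + 1), "zero variance")
})

test_that("field-aligned deviation is positive in the field's push direction", {
  # b > 0 rotates velocity counter-clockwise, so a CCW (negative) raw
  # deviation is aligned-positive
  expect_equal(field_aligned_deviation(-0.03, 8), 0.03)
  expect_equal(field_aligned_deviation(0.03, -8), 0.03)
  expect_equal(field_aligned_deviation(0.03, 0), 0.03)
})
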