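# Planar arm, muscles, and the curl field.

test_that("curl force follows the rotation matrix and stays orthogonal", {
  expect_equal(curl_force(c(0, 0), 8), c(0, 0))
  expect_equal(curl_force(c(0.1, 0), 8), c(0, 0.8))
  expect_equal(curl_force(c(0.3, -0.2), 0), c(0, 0))
  set.seed(1)
  for (i in 1:1000) {
    v <- rnorm(2); b <- rnorm(1, sd = 5)
    F <- curl_force(v, b)
    expect_lt(abs(sum(F * v)), 1e-12 * max(1, sqrt(sum(F^2)) * sqrt(sum(v^2))))
    expect_equal(sqrt(sum(F^2)), abs(b) * sqrt(sum(v^2)), tolerance = 1e-12)
  }
  expect_error(curl_force(c(NA, 0), 8), "finite")
})

test_that("forward kinematics matches the planar two-link mapping", {
  cfg <- tiny_arm()
  expect_equal(forward_kinematics(c(0, 0), cfg), c(0.63, 0))
  expect_equal(forward_kinematics(c(pi / 2, 0), cfg), c(0, 0.63),
               tolerance = 1e-12)
  # matrix input
  Q <- rbind(c(0, 0), c(pi / 2, 0))
  expect_equal(forward_kinematics(Q, cfg),
               rbind(c(0.63, 0), c(0, 0.63)), tolerance = 1e-12)
})

test_that("analytic Jacobian matches finite differences of the kinematics", {
  cfg <- tiny_arm()
  set.seed(2)
  for (i in 1:20) {
    q <- runif(2, c(0.1, 0.3), c(2, 2.4))
    J <- arm_jacobian(q, cfg)
    h <- 1e-7
    for (j in 1:2) {
      dq <- c(0, 0); dq[j] <- h
      fd <- (forward_kinematics(q + dq, cfg) -
               forward_kinematics(q - dq, cfg)) / (2 * h)
      expect_equal(unname(J[, j]), fd, tolerance = 1e-6)
    }
  }
})

test_that("arm at rest with zero stimulation stays at rest", {
  cfg <- tiny_arm()
  s <- arm_state(cfg$qref, config = cfg)
  s2 <- arm_step(s, rep(0, 6), curl_field(0), cfg)
  expect_equal(s2$qd, c(0, 0))
  expect_equal(s2$q, s$q)
})

test_that("arm step is pure and rejects out-of-range stimulation", {
  cfg <- tiny_arm()
  s <- arm_state(c(1, 1.3), qd = c(0.2, -0.1), act = rep(0.1, 6),
                 config = cfg)
  u <- seq(0.1, 0.6, length.out = 6)
  a <- arm_step(s, u, curl_field(8), cfg)
  b <- arm_step(s, u, curl_field(8), cfg)
  expect_identical(a, b)
  expect_error(arm_step(s, rep(1.2, 6), curl_field(0), cfg), "API error")
  expect_error(arm_step(s, rep(-0.1, 6), curl_field(0), cfg), "API error")
})

test_that("stimulating the shoulder flexor flexes the shoulder", {
  cfg <- tiny_arm()
  s <- arm_state(cfg$qref, config = cfg)
  stim <- c(1, 0, 0, 0, 0, 0)  # SF only
  for (i in 1:10) s <- arm_step(s, stim, curl_field(0), cfg)
  expect_gt(s$q[1], cfg$qref[1])
})

test_that("endpoint force is the Jacobian-transpose-inverse of muscle torques", {
  cfg <- tiny_arm()
  s <- arm_state(c(1, 1.4), act = rep(0, 6), config = cfg)
  expect_equal(endpoint_force(s, cfg), c(0, 0))
  set.seed(3)
  for (i in 1:20) {
    st <- arm_state(runif(2, c(0.3, 0.4), c(1.8, 2.2)),
                    qd = rnorm(2, sd = 0.5),
                    act = runif(6), config = cfg)
    Fe <- endpoint_force(st, cfg)
    # independent composition: tau = R'f, F solves J'F = tau
    tau <- drop(t(cfg$moment) %*% st$f)
    Fref <- drop(solve(t(arm_jacobian(st$q, cfg))) %*% tau)
    expect_equal(Fe, Fref, tolerance = 1e-10)
    # doubling forces doubles the endpoint force
    st2 <- st; st2$f <- 2 * st$f
    expect_equal(endpoint_force(st2, cfg), 2 * Fe, tolerance = 1e-10)
  }
  s_ext <- arm_state(c(1, 0), config = cfg)
  s_ext$q <- c(1, 0)
  expect_error(endpoint_force(s_ext, cfg), "singular")
})

test_that("passive arm does not gain energy over 100 steps", {
  cfg <- tiny_arm()
  s <- arm_state(c(1.1, 1.2), qd = c(0.3, -0.4), config = cfg)
  speed0 <- sqrt(sum(s$qd^2))
  speeds <- numeric(100)
  for (i in 1:100) {
    s <- arm_step(s, rep(0, 6), curl_field(0), cfg)
    speeds[i] <- sqrt(sum(s$qd^2))
  }
  expect_lt(max(speeds), speed0 * 1.05)
  expect_lt(speeds[100], speed0)
})

test_that("moment-arm pattern realises the six named muscles", {
  cfg <- tiny_arm()
  expect_error(arm_config(moment = matrix(0.02, 6, 2)), "mono-articular")
  nz <- rowSums(cfg$moment != 0)
  expect_equal(unname(nz), c(1, 1, 1, 1, 2, 2))
})
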