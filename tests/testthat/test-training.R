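# Composite loss, its gradients, and the two optimisation regimes.

test_that("desired position switches at the true go step", {
  cfg <- tiny_arm()
  ep <- centre_episode(go = 20L, config = cfg)
  start_x <- forward_kinematics(ep$start_q, cfg)
  expect_equal(desired_position(ep, 19, config = cfg), start_x)
  expect_equal(desired_position(ep, 20, config = cfg), ep$target)
  # catch trial: the goal never moves
  epc <- episode_spec(ep$start_q, ep$target, 0L, T = 100L)
  xs <- desired_position(epc, 1:100, config = cfg)
  expect_equal(xs, matrix(rep(start_x, 100), ncol = 2, byrow = TRUE))
  # start = target: constant goal regardless of go
  eps <- episode_spec(ep$start_q, start_x, 20L)
  expect_equal(desired_position(eps, 5, config = cfg),
               desired_position(eps, 50, config = cfg))
})

test_that("loss vanishes on a perfect trajectory and isolates single terms", {
  cfg <- tiny_arm()
  n <- 4; T <- 50
  tgt <- c(0.1, 0.4)
  xs <- matrix(rep(tgt, T + 1), ncol = 2, byrow = TRUE)
  z6 <- matrix(0, T, 6); zh <- matrix(0, T + 1, n)
  tr0 <- fake_trajectory(xs, zh, z6, go_step = 1L, target = tgt)
  expect_equal(compute_loss(tr0, config = cfg)$total, 0)
  # constant 1 cm offset in x: L = 1e3 * 0.01 = 10
  tr1 <- fake_trajectory(sweep(xs, 2, c(0.01, 0)), zh, z6, 1L, tgt)
  expect_equal(compute_loss(tr1, config = cfg)$total, 10)
  # constant hidden activity with h'h = 1.28: L = 1.28e-5
  h <- matrix(sqrt(1.28 / n), T + 1, n)
  tr2 <- fake_trajectory(xs, h, z6, 1L, tgt)
  expect_equal(compute_loss(tr2, config = cfg)$total, 1.28e-5,
               tolerance = 1e-12)
})

test_that("loss terms are non-negative and sum to the total", {
  cfg <- tiny_arm()
  p <- wiggly_params()
  tr <- rollout(p, centre_episode(go = 15L, T = 60L, config = cfg), cfg,
                curl_field(8))
  cl <- compute_loss(tr, config = cfg)
  expect_true(all(cl$breakdown >= 0))
  expect_equal(sum(cl$breakdown), cl$total)
})

test_that("compiled loss agrees with the reference implementation", {
  cfg <- tiny_arm()
  p <- wiggly_params()
  eps <- list(centre_episode(go = 12L, T = 40L, config = cfg),
              centre_episode(go = 0L, T = 40L, target_idx = 3L, config = cfg))
  res <- motorsavings:::batch_loss_grad(p, eps, cfg, 8, loss_weights(),
                                        want_grad = FALSE)
  trs <- motorsavings:::rollout_batch(p, eps, cfg, curl_field(8))
  ref <- mean(vapply(trs, function(tr) compute_loss(tr, config = cfg)$total,
                     numeric(1)))
  expect_equal(res$loss, ref, tolerance = 1e-12)
  expect_equal(sum(res$terms), res$loss, tolerance = 1e-12)
})

test_that("backpropagated gradients match central finite differences", {
  cfg <- tiny_arm()
  p <- init_params(4, seed = 7)
  eps <- list(episode_spec(c(pi / 3, pi / 2), c(0.05, 0.45), 4L, T = 12L),
              episode_spec(c(1.2, 1.4), c(-0.05, 0.5), 0L, T = 12L))
  arr <- motorsavings:::episode_batch_arrays(eps)
  # smooth terms (position's L1 kink excluded): tight agreement
  w <- loss_weights(position = 0)
  lg <- function(pp, wg) motorsavings:::cpp_loss_grad(
    unclass(pp), unclass(cfg), arr$q0, arr$target, arr$go, arr$T, 8,
    unclass(w), wg)
  res <- lg(p, TRUE)
  set.seed(1)
  h <- 1e-5
  for (nm in names(res$grads)) {
    g <- res$grads[[nm]]
    for (i in sample(length(g), min(4, length(g)))) {
      pp <- p; pp[[nm]][i] <- pp[[nm]][i] + h
      lp <- lg(pp, FALSE)$loss
      pp <- p; pp[[nm]][i] <- pp[[nm]][i] - h
      lm <- lg(pp, FALSE)$loss
      fd <- (lp - lm) / (2 * h)
      expect_equal(g[i], fd, tolerance = 5e-3,
                   info = sprintf("%s[%d]", nm, i))
    }
  }
})

test_that("growing up is deterministic, balanced, and reduces the loss", {
  cfg <- tiny_arm()
  p <- init_params(12, seed = 3)
  a <- growing_up(p, cfg, seed = 4, batches = 60L, batch_size = 16L, T = 50L)
  b <- growing_up(p, cfg, seed = 4, batches = 60L, batch_size = 16L, T = 50L)
  expect_identical(a$log, b$log)
  # about half the episodes are catch trials
  frac <- sum(a$log$catch) / (60 * 16)
  expect_gt(frac, 0.4); expect_lt(frac, 0.6)
  # the loss comes down even at this toy scale
  expect_lt(mean(tail(a$log$total, 10)), mean(head(a$log$total, 10)))
})

test_that("phase training freezes the input/output maps and logs a metric", {
  cfg <- tiny_arm()
  p <- init_params(8, seed = 2)
  task <- centre_out_task(config = cfg)
  ph <- phase_spec("FF1", 8, 3L)
  res <- train_phase(p, ph, task, cfg, seed = 1, lr = 1e-4)
  for (nm in frozen_mask())
    expect_identical(res$params[[nm]], p[[nm]], info = nm)
  expect_false(identical(res$params$Uz, p$Uz))
  expect_length(res$curve$deviation, 3)
  # zero learning rate: parameters unchanged, metric still produced
  res0 <- train_phase(p, ph, task, cfg, seed = 1, lr = 0)
  expect_identical(unclass(res0$params), unclass(p))
  expect_length(res0$curve$deviation, 3)
})

test_that("loss is invariant to episode order within a batch", {
  cfg <- tiny_arm()
  p <- wiggly_params()
  eps <- lapply(c(1L, 3L, 5L, 7L), function(i)
    centre_episode(go = 10L + i, T = 40L, target_idx = i, config = cfg))
  l1 <- motorsavings:::batch_loss_grad(p, eps, cfg, 8, loss_weights(),
                                       FALSE)$loss
  l2 <- motorsavings:::batch_loss_grad(p, rev(eps), cfg, 8, loss_weights(),
                                       FALSE)$loss
  expect_equal(l1, l2, tolerance = 1e-12)
})
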