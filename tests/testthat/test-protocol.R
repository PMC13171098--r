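# Centre-out batches, phase plan, evaluation rollouts, experiment record.

test_that("centre-out batches repeat each target four times", {
  cfg <- tiny_arm()
  task <- centre_out_task(config = cfg)
  expect_equal(nrow(task$targets), 8)
  r <- sqrt(rowSums(sweep(task$targets, 2, task$start_x)^2))
  expect_equal(r, rep(0.1, 8), tolerance = 1e-12)
  eps <- centre_out_batch(task, 32L, 0.5, seed = 3)
  tgt <- t(vapply(eps, `[[`, numeric(2), "target"))
  counts <- table(apply(tgt, 1, paste, collapse = ","))
  expect_true(all(counts == 4))
  expect_error(centre_out_batch(task, 30L), "divisible")
  expect_identical(centre_out_batch(task, 32L, 0.5, seed = 3), eps)
  # catch fraction over many batches stays near one half
  set.seed(10)
  n_catch <- sum(vapply(centre_out_batch(task, 32L, 0.5), `[[`, logical(1),
                        "catch"))
  for (i in 1:19)
    n_catch <- n_catch + sum(vapply(centre_out_batch(task, 32L, 0.5),
                                    `[[`, logical(1), "catch"))
  expect_gt(n_catch / 640, 0.42); expect_lt(n_catch / 640, 0.58)
  # go times of non-catch episodes span 100-300 ms
  gos <- vapply(eps, `[[`, integer(1), "go_step")
  expect_true(all(gos[gos > 0] >= 10 & gos[gos > 0] <= 30))
})

test_that("phase plan realises the main and opposite-field protocols", {
  plan <- motorsavings:::phase_plan(micro_config())
  expect_equal(vapply(plan, `[[`, character(1), "name"),
               c("NF1", "FF1", "NF2", "FF2"))
  expect_equal(vapply(plan, `[[`, numeric(1), "b"), c(0, 8, 0, 8))
  cfg_ctrl <- micro_config(); cfg_ctrl$control <- TRUE
  plan_c <- motorsavings:::phase_plan(cfg_ctrl)
  expect_equal(vapply(plan_c, `[[`, numeric(1), "b"), c(0, -8, 0, 8))
  expect_equal(plan_c[[2]]$b, -plan_c[[4]]$b)
  expect_error(phase_spec("NF1", 8, 10), "b = 0")
})

test_that("evaluation rollouts give one settled trajectory per target", {
  cfg <- tiny_arm()
  p <- wiggly_params(n = 8L)
  task <- centre_out_task(config = cfg)
  ev <- evaluation_rollouts(p, task, curl_field(0),
                            list(T = 150L, go_step = 50L), cfg)
  expect_length(ev, 8)
  ev2 <- evaluation_rollouts(p, task, curl_field(0),
                             list(T = 150L, go_step = 50L), cfg)
  expect_identical(ev, ev2)
  H <- prep_activity(ev)
  expect_equal(dim(H), c(8, 8))
  expect_equal(attr(H, "state_index"), 16L)
  # preparatory states differ across targets
  expect_gt(min(dist(H)), 0)
  expect_error(evaluation_rollouts(p, task, curl_field(0),
                                   list(T = 60L, go_step = 20L), cfg),
               "340 ms")
})

test_that("a miniature experiment record is structured and reproducible", {
  cfg <- experiment_config(n_units = 6L, seeds = 1L, grow_batches = 2L,
                           grow_batch_size = 8L,
                           phase_batches = c(NF1 = 2L, FF1 = 2L, NF2 = 2L,
                                             FF2 = 2L),
                           phase_lr = 1e-5, T_train = 30L)
  rec <- run_experiment(cfg)
  net <- rec$networks[["1"]]
  expect_equal(names(net$checkpoints), c("grow", "NF1", "FF1", "NF2", "FF2"))
  expect_equal(names(net$curves), c("NF1", "FF1", "NF2", "FF2"))
  expect_length(net$evals$FF2, 8)
  # frozen groups carry identical values across every phase boundary
  for (nm in frozen_mask())
    for (ph in c("NF1", "FF1", "NF2", "FF2"))
      expect_identical(net$checkpoints[[ph]][[nm]],
                       net$checkpoints$grow[[nm]], info = paste(nm, ph))
  # reruns reproduce every logged number exactly
  rec2 <- run_experiment(cfg)
  expect_identical(rec2$networks[["1"]]$curves, net$curves)
  expect_identical(rec2$networks[["1"]]$checkpoints$FF2$Uz,
                   net$checkpoints$FF2$Uz)
})

test_that("observations never encode the field gain", {
  cfg <- tiny_arm()
  p <- wiggly_params(n = 8L)
  ep <- centre_episode(go = 30L, T = 60L, config = cfg)
  # the field can influence observations only through the delayed plant
  # state (the joint state first differs at state 2, seen at step 4); no
  # input channel carries the gain itself
  tr0 <- rollout(p, ep, cfg, curl_field(0))
  tr8 <- rollout(p, ep, cfg, curl_field(8))
  expect_identical(tr0$obs[1:3, ], tr8$obs[1:3, ])
  expect_equal(ncol(tr0$obs), 17)
})
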