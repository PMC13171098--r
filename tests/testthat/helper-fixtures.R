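# Shared helpers: small deterministic objects used across test files.

tiny_arm <- function() arm_config()

# A controller whose output layer is active enough to move the arm without
# any training (used for delay/rollout plumbing tests).
wiggly_params <- function(n = 6L, seed = 11L) {
  p <- init_params(n, seed = seed)
  set.seed(seed + 1L)
  p$Wout <- matrix(rnorm(6 * n, sd = 0.8), 6, n)
  p$bout <- rep(0, 6)
  p
}

centre_episode <- function(go = 20L, T = 100L, target_idx = 1L,
                           config = arm_config()) {
  task <- centre_out_task(config = config)
  episode_spec(task$start_q, task$targets[target_idx, ], go, T = T)
}

# Build a trajectory-like object from raw arrays, for loss unit tests.
fake_trajectory <- function(x, h, f, go_step, target, T = nrow(f),
                            dt = 0.01) {
  structure(list(x = x, h = h, f = f, go_step = go_step, catch = go_step == 0,
                 start = x[1, ], target = target, T = T, dt = dt),
            class = "trajectory")
}
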