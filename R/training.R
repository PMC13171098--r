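# Training: composite rollout loss, Adam growing-up on random reaches, and
# batch-local gradient descent during the experimental phases.

#' Loss weights for the composite rollout loss
#'
#' Defaults are the coefficients of the training objective: per time step,
#' `1e3 |x* - x|_1 + 1e5 j'j + 1e-1 (f'f + 3e-3 fd'fd) + 1e-5 (h'h + 1e2
#' hd'hd)`, averaged over steps, where `j` is the per-step third difference
#' (jerk) of endpoint position, `f` the normalised muscle forces, and `fd`,
#' `hd` per-step first differences.
#'
#' @param position,jerk,muscle,hidden outer term weights.
#' @param muscle_deriv,hidden_deriv inner derivative weights.
#' @return An object of class `loss_weights`.
#' @export
loss_weights <- function(position = 1e3, jerk = 1e5,
                         muscle = 1e-1, muscle_deriv = 3e-3,
                         hidden = 1e-5, hidden_deriv = 1e2) {
  structure(list(position = position, jerk = jerk, muscle = muscle,
                 muscle_deriv = muscle_deriv, hidden = hidden,
                 hidden_deriv = hidden_deriv), class = "loss_weights")
}

#' Desired endpoint position over an episode
#'
#' The goal is the start position before the go cue (and for the whole
#' episode on catch trials) and the target position from the go step onward.
#'
#' @param episode an [episode_spec()].
#' @param t step index (1-based), possibly a vector.
#' @param start_x endpoint position of the start posture; computed from the
#'   episode's start posture if omitted.
#' @param config an [arm_config()] used for that computation.
#' @return 2-column matrix (or 2-vector for scalar `t`) of goal positions.
#' @export
desired_position <- function(episode, t, start_x = NULL,
                             config = arm_config()) {
  if (is.null(start_x)) start_x <- forward_kinematics(episode$start_q, config)
  after <- !episode$catch & t >= episode$go_step
  out <- matrix(rep(start_x, length(t)), ncol = 2, byrow = TRUE)
  out[after, ] <- matrix(rep(episode$target, sum(after)), ncol = 2,
                         byrow = TRUE)
  if (length(t) == 1) drop(out) else out
}

pad1 <- function(i) pmax(i, 1L)

#' Composite loss of a trajectory
#'
#' Reference implementation operating on a recorded trajectory; the training
#' path computes the same quantity (and its gradient) in compiled code.
#' Time derivatives are per-step forward differences with edge replication
#' (jerk is the third difference of endpoint position), and muscle forces
#' enter normalised by their maximum isometric force; with these conventions
#' the four coefficient magnitudes are balanced against each other.
#'
#' @param traj a `trajectory` from [rollout()].
#' @param weights a [loss_weights()].
#' @param config the [arm_config()] used for the rollout (for the maximum
#'   isometric forces).
#' @return List with `total` and a named per-term `breakdown` (already
#'   weighted, summing to the total).
#' @export
compute_loss <- function(traj, weights = loss_weights(),
                         config = arm_config()) {
  T <- traj$T
  x <- traj$x[-1, , drop = FALSE]           # states 1..T
  h <- traj$h[-1, , drop = FALSE]
  f <- sweep(traj$f, 2, config$fmax, "/")
  goal <- desired_position(
    structure(list(start_q = NULL, target = traj$target,
                   go_step = traj$go_step, catch = traj$catch), class = "episode_spec"),
    seq_len(T), start_x = traj$start)
  if (!all(is.finite(x))) stop("non-finite endpoint positions in loss")
  Lp <- sum(abs(goal - x)) / T
  t3 <- seq_len(T)
  jerk <- x[t3, ] - 3 * x[pad1(t3 - 1), ] + 3 * x[pad1(t3 - 2), ] -
    x[pad1(t3 - 3), ]
  Lj <- sum(jerk^2) / T
  fd <- rbind(rep(0, 6), diff(f))
  Lm <- (sum(f^2) + weights$muscle_deriv * sum(fd^2)) / T
  hd <- rbind(rep(0, ncol(h)), diff(h))
  Lh <- (sum(h^2) + weights$hidden_deriv * sum(hd^2)) / T
  breakdown <- c(position = weights$position * Lp,
                 jerk = weights$jerk * Lj,
                 muscle = weights$muscle * Lm,
                 hidden = weights$hidden * Lh)
  list(total = sum(breakdown), breakdown = breakdown)
}

# Batched loss + gradient through the compiled engine.
batch_loss_grad <- function(params, episodes, config, b, weights,
                            want_grad = TRUE) {
  arr <- episode_batch_arrays(episodes)
  cpp_loss_grad(unclass(params), unclass(config), arr$q0, arr$target,
                arr$go, arr$T, b, unclass(weights), want_grad)
}

# ---- episode sampling -------------------------------------------------------

sample_go_step <- function(n) sample(10:30, n, replace = TRUE)

#' Sample a growing-up batch of random reaches
#'
#' Start and target postures are drawn uniformly from the joint box; half the
#' episodes are catch trials; go times are uniform on 100-300 ms.
#'
#' @param batch_size number of episodes.
#' @param config an [arm_config()].
#' @param T episode length in steps.
#' @return List of [episode_spec()].
#' @export
random_reach_batch <- function(batch_size, config = arm_config(), T = 100L) {
  lapply(seq_len(batch_size), function(i) {
    q0 <- runif(2, config$qmin, config$qmax)
    qt <- runif(2, config$qmin, config$qmax)
    catch <- runif(1) < 0.5
    episode_spec(q0, forward_kinematics(qt, config),
                 go_step = if (catch) 0L else sample_go_step(1), T = T)
  })
}

# ---- optimisers -------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_update <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Growing-up training on random reaches
#'
#' Adam optimisation of all controller parameters on batches of random
#' point-to-point reaches in a null field (50% catch trials, go cue uniform
#' on 100-300 ms).
#'
#' @param params freshly initialised [init_params()].
#' @param config an [arm_config()].
#' @param seed integer seed controlling episode sampling.
#' @param batches,batch_size,lr optimisation hyper-parameters (defaults:
#'   20000 batches of 32 at learning rate 0.003).
#' @param T episode length in steps.
#' @param weights a [loss_weights()].
#' @param verbose print progress every 200 batches.
#' @return List with trained `params` and a per-batch `log` data frame
#'   (batch, total and per-term losses, catch count).
#' @export
growing_up <- function(params, config = arm_config(), seed = 1L,
                       batches = 20000L, batch_size = 32L, lr = 0.003,
                       T = 100L, weights = loss_weights(), verbose = FALSE) {
  set.seed(seed)
  opt <- adam_init(params)
  log <- matrix(NA_real_, batches, 6,
                dimnames = list(NULL, c("batch", "total", "position", "jerk",
                                        "muscle", "hidden")))
  n_catch <- integer(batches)
  for (i in seq_len(batches)) {
    eps <- random_reach_batch(batch_size, config, T)
    res <- batch_loss_grad(params, eps, config, 0, weights)
    if (!is.finite(res$loss)) stop("growing-up loss diverged at batch ", i)
    upd <- adam_update(unclass(params), res$grads, opt, lr)
    params[] <- upd$params
    opt <- upd$state
    log[i, ] <- c(i - 1, res$loss, res$terms)
    n_catch[i] <- sum(vapply(eps, `[[`, logical(1), "catch"))
    if (verbose && i %% 200 == 0)
      message(sprintf("grow batch %d loss %.3f", i, res$loss))
  }
  list(params = params,
       log = cbind(as.data.frame(log), catch = n_catch))
}

#' Batch-local gradient descent during an experimental phase
#'
#' Plain (momentum-free) stochastic gradient descent on centre-out batches;
#' only the recurrent cell (recurrent maps and gate biases) is updated, and
#' the frozen parameter groups are verified unchanged at the end of the
#' phase.  The per-batch metric is the mean signed lateral deviation over the
#' non-catch reaches of each batch, measured before that batch's update, so
#' the first entry is the phase's batch-0 behaviour.
#'
#' @param params trained [init_params()] (post growing-up).
#' @param phase a [phase_spec()] (name, field gain, batch count).
#' @param task a [centre_out_task()].
#' @param config an [arm_config()].
#' @param seed integer seed for episode sampling.
#' @param lr learning rate (default 0.005).
#' @param weights a [loss_weights()].
#' @param frozen names of frozen parameter groups.
#' @return List with updated `params` and `curve`, a [learning_curve()] of
#'   per-batch mean signed lateral deviation (m, positive = clockwise).
#' @export
train_phase <- function(params, phase, task = centre_out_task(),
                        config = arm_config(), seed = 1L, lr = 0.005,
                        weights = loss_weights(), frozen = frozen_mask()) {
  set.seed(seed)
  before <- unclass(params)[frozen]
  plastic <- setdiff(names(params), frozen)
  dev <- numeric(phase$batches)
  for (i in seq_len(phase$batches)) {
    eps <- centre_out_batch(task, 32L, 0.5)
    res <- batch_loss_grad(params, eps, config, phase$b, weights,
                           want_grad = lr != 0)
    if (!is.finite(res$loss))
      stop("phase ", phase$name, " loss diverged at batch ", i)
    dev[i] <- batch_mean_deviation(res$X, eps)
    if (lr != 0)
      for (nm in plastic) params[[nm]] <- params[[nm]] - lr * res$grads[[nm]]
  }
  if (!identical(unclass(params)[frozen], before))
    stop("freeze violation: a masked parameter changed during phase ",
         phase$name)
  list(params = params,
       curve = learning_curve(dev, phase$name))
}

# Mean signed lateral deviation over the non-catch episodes of a batch,
# computed from the endpoint-position cube of the forward pass.
batch_mean_deviation <- function(X, episodes) {
  devs <- vapply(seq_along(episodes), function(b) {
    ep <- episodes[[b]]
    if (ep$catch) return(NA_real_)
    path <- t(X[, b, (ep$go_step + 1):(ep$T + 1)])
    lateral_deviation(path, drop(X[, b, 1]), ep$target)
  }, numeric(1))
  mean(devs, na.rm = TRUE)
}
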