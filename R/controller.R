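# Controller: GRU policy mapping the 17-dimensional observation (task inputs
# plus delayed visual and proprioceptive feedback) to six muscle stimulation
# commands in (0, 1).

OBS_DIM <- 17L
VIS_DELAY_STEPS <- 7L   # 70 ms at dt = 10 ms
PROP_DELAY_STEPS <- 2L  # 20 ms

#' Initialise controller parameters
#'
#' Input maps are Glorot-initialised, recurrent maps orthogonally initialised,
#' gate biases zero, the output bias -5 (so stimulation starts near zero), and
#' the learnable initial hidden state zero.
#'
#' @param n_units number of GRU units (>= 2).
#' @param seed integer seed; the draw is deterministic given the seed.
#' @return An object of class `ctrl_params`: matrices `Wz, Wr, Wn` (input
#'   maps, units x 17), `Uz, Ur, Un` (recurrent maps), gate biases
#'   `bz, br, bn`, output map `Wout` (6 x units) with bias `bout`, and the
#'   initial hidden state `h0`.
#' @export
init_params <- function(n_units, seed = 1L) {
  stopifnot(n_units >= 2)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  glorot <- function(nr, nc) {
    lim <- sqrt(6 / (nr + nc))
    matrix(runif(nr * nc, -lim, lim), nr, nc)
  }
  ortho <- function(n) {
    qrd <- qr(matrix(rnorm(n * n), n, n))
    q <- qr.Q(qrd)
    q * rep(sign(diag(qr.R(qrd))), each = n)
  }
  p <- list(Wz = glorot(n_units, OBS_DIM), Wr = glorot(n_units, OBS_DIM),
            Wn = glorot(n_units, OBS_DIM),
            Uz = ortho(n_units), Ur = ortho(n_units), Un = ortho(n_units),
            bz = numeric(n_units), br = numeric(n_units),
            bn = numeric(n_units),
            Wout = glorot(6, n_units), bout = rep(-5, 6),
            h0 = numeric(n_units))
  structure(p, class = "ctrl_params", n_units = as.integer(n_units))
}

#' Parameter groups frozen after the growing-up phase
#'
#' Only the recurrent cell (recurrent maps and gate biases) stays plastic
#' during the experimental phases; input and output maps, the output bias and
#' the initial hidden state are frozen.
#'
#' @return Character vector of frozen parameter names.
#' @export
frozen_mask <- function() c("Wz", "Wr", "Wn", "Wout", "bout", "h0")

plastic_mask <- function() c("Uz", "Ur", "Un", "bz", "br", "bn")

#' One GRU controller step
#'
#' Standard gated-recurrent-unit update in the convention where the reset
#' gate multiplies the hidden state before the candidate's recurrent product,
#' followed by a sigmoid output layer, so stimulation is strictly in (0, 1).
#'
#' @param params a [init_params()] object.
#' @param h hidden state (units).
#' @param obs observation vector (17).
#' @return List with the new hidden state `h` and `stimulation` (6).
#' @export
forward_step <- function(params, h, obs) {
  stopifnot(length(obs) == OBS_DIM, all(is.finite(h)), all(is.finite(obs)))
  sig <- function(x) 1 / (1 + exp(-x))
  z <- sig(drop(params$Wz %*% obs + params$Uz %*% h) + params$bz)
  r <- sig(drop(params$Wr %*% obs + params$Ur %*% h) + params$br)
  nc <- tanh(drop(params$Wn %*% obs + params$Un %*% (r * h)) + params$bn)
  hn <- z * h + (1 - z) * nc
  if (!all(is.finite(hn))) stop("non-finite hidden state in forward_step")
  list(h = hn, stimulation = sig(drop(params$Wout %*% hn) + params$bout))
}

#' Delay buffers for visual and proprioceptive feedback
#'
#' Fixed-depth queues (7 steps visual, 2 steps proprioceptive); before a
#' queue fills it yields the pre-trial value it was initialised with.
#'
#' @param init_visual initial visual entry (endpoint x, y and go cue).
#' @param init_prop initial proprioceptive entry (6 lengths, 6 velocities).
#' @return An object of class `delay_buffer` with `push()` and peek fields.
#' @export
delay_buffer <- function(init_visual, init_prop) {
  vq <- rep(list(init_visual), VIS_DELAY_STEPS)
  pq <- rep(list(init_prop), PROP_DELAY_STEPS)
  env <- new.env(parent = emptyenv())
  env$vq <- vq; env$pq <- pq
  structure(env, class = "delay_buffer")
}

#' Advance delay buffers by one step
#'
#' @param buf a [delay_buffer()].
#' @param visual current visual entry (endpoint x, y, go).
#' @param prop current proprioceptive entry (lengths, velocities).
#' @export
push_buffer <- function(buf, visual, prop) {
  buf$vq <- c(buf$vq[-1], list(visual))
  buf$pq <- c(buf$pq[-1], list(prop))
  invisible(buf)
}

#' Assemble the 17-dimensional observation
#'
#' The target is an undelayed task input; the go cue and endpoint position
#' are read from the 7-step visual queue and the muscle lengths/velocities
#' from the 2-step proprioceptive queue.  Ordering: target x, target y, go,
#' endpoint x, endpoint y, lengths 1-6, velocities 1-6.
#'
#' @param target target position (m, 2).
#' @param buffers a [delay_buffer()]; the oldest entries are read.
#' @return Observation vector of length 17.
#' @export
assemble_input <- function(target, buffers) {
  vis <- buffers$vq[[1]]   # (x, y, go) as seen VIS_DELAY steps ago
  prop <- buffers$pq[[1]]  # (lengths, velocities)
  c(target, vis[3], vis[1:2], prop)
}

#' Episode specification
#'
#' @param start_q start posture (joint angles, rad).
#' @param target target endpoint position (m, 2).
#' @param go_step 1-based step at which the go cue switches to 1, or 0 for a
#'   catch episode in which the cue never arrives.
#' @param T episode length in steps (default 100 steps = 1 s).
#' @return An object of class `episode_spec`.
#' @export
episode_spec <- function(start_q, target, go_step, T = 100L) {
  stopifnot(length(start_q) == 2, length(target) == 2,
            go_step >= 0, T >= 1, go_step <= T)
  structure(list(start_q = start_q, target = target,
                 go_step = as.integer(go_step), T = as.integer(T),
                 catch = go_step == 0L),
            class = "episode_spec")
}

episode_batch_arrays <- function(episodes) {
  T <- unique(vapply(episodes, `[[`, integer(1), "T"))
  stopifnot(length(T) == 1)
  list(q0 = vapply(episodes, `[[`, numeric(2), "start_q"),
       target = vapply(episodes, `[[`, numeric(2), "target"),
       go = vapply(episodes, `[[`, integer(1), "go_step"),
       T = T)
}

#' Closed-loop rollout of controller and arm
#'
#' Simulates a full episode: at each step the observation is assembled from
#' the delayed state history, the GRU updates, the sigmoid output stimulates
#' the muscles, and the arm advances one step (optionally inside a curl
#' field).  An optional hook may add a vector to the stored hidden state at
#' exactly one declared state index, before the output layer and the next
#' recurrent step read it.
#'
#' @param params a [init_params()] object.
#' @param episode an [episode_spec()].
#' @param config an [arm_config()].
#' @param field a [curl_field()].
#' @param hook optional `list(step =, delta =)`: at state index `step`
#'   (0-based; 0 edits the initial hidden state) `delta` is added to the
#'   hidden state.
#' @return A `trajectory` object: matrices over time of arm state, hidden
#'   activity `h` ((T+1) x units), stimulation `u`, muscle forces `f`,
#'   endpoint positions `x`, observations `obs`, and episode metadata.
#' @export
rollout <- function(params, episode, config = arm_config(),
                    field = curl_field(0), hook = NULL) {
  rollout_batch(params, list(episode), config, field, hook)[[1]]
}

rollout_batch <- function(params, episodes, config = arm_config(),
                          field = curl_field(0), hook = NULL) {
  arr <- episode_batch_arrays(episodes)
  n <- attr(params, "n_units")
  pert_state <- -1L
  delta <- numeric(n)
  if (!is.null(hook)) {
    stopifnot(hook$step >= 0, hook$step <= arr$T, length(hook$delta) == n)
    pert_state <- as.integer(hook$step)
    delta <- as.numeric(hook$delta)
  }
  W <- cpp_rollout(unclass(params), unclass(config), arr$q0, arr$target,
                   arr$go, arr$T, field$b, pert_state, delta)
  lapply(seq_along(episodes), function(b) {
    tr <- list(q = t(W$Q[, b, ]), qd = t(W$QD[, b, ]), act = t(W$ACT[, b, ]),
               x = t(W$X[, b, ]), h = t(W$H[, b, ]), u = t(W$U[, b, ]),
               f = t(W$F[, b, ]), ln = t(W$LN[, b, ]), vn = t(W$VN[, b, ]),
               obs = t(W$OBS[, b, ]),
               go_step = episodes[[b]]$go_step, catch = episodes[[b]]$catch,
               start = drop(W$X[, b, 1]), target = episodes[[b]]$target,
               T = arr$T, dt = config$dt)
    class(tr) <- "trajectory"
    tr
  })
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory: %d steps, %d hidden units, go at step %s>\n",
              x$T, ncol(x$h),
              if (x$catch) "never (catch)" else x$go_step))
  invisible(x)
}
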