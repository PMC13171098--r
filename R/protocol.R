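# Protocol: the centre-out task, the NF1 -> FF1 -> NF2 -> FF2 schedule, the
# opposite-field control, seed management, and evaluation rollouts.

#' Phase specification
#'
#' @param name one of `"NF1", "FF1", "NF2", "FF2"`.
#' @param b curl-field gain of the phase (0 for null-field phases).
#' @param batches number of training batches (paper defaults: 10000 for NF,
#'   3200 for FF phases).
#' @return An object of class `phase_spec`.
#' @export
phase_spec <- function(name, b, batches) {
  stopifnot(name %in% c("NF1", "FF1", "NF2", "FF2"))
  if (grepl("^NF", name) && b != 0) stop("null-field phases must have b = 0")
  structure(list(name = name, b = b, batches = as.integer(batches)),
            class = "phase_spec")
}

#' Centre-out reaching task
#'
#' Eight equidistant targets on a circle around the endpoint of the start
#' posture (shoulder 60 deg, elbow 90 deg).  Target 1 lies along +x of the
#' workspace frame; targets are numbered counter-clockwise.
#'
#' @param start_q start posture (rad).
#' @param radius target distance (m).
#' @param n_targets number of targets.
#' @param config an [arm_config()].
#' @return An object of class `centre_out_task` with the start posture, the
#'   start endpoint and the `n_targets x 2` target matrix.
#' @export
centre_out_task <- function(start_q = c(pi / 3, pi / 2), radius = 0.1,
                            n_targets = 8L, config = arm_config()) {
  start_x <- forward_kinematics(start_q, config)
  ang <- 2 * pi * (seq_len(n_targets) - 1) / n_targets
  targets <- cbind(start_x[1] + radius * cos(ang),
                   start_x[2] + radius * sin(ang))
  structure(list(start_q = start_q, start_x = start_x, radius = radius,
                 targets = targets), class = "centre_out_task")
}

#' Sample one centre-out training batch
#'
#' `size / 8` repetitions of each of the eight targets; each episode is a
#' catch trial with probability `catch_fraction`, otherwise the go cue is
#' uniform on 100-300 ms.
#'
#' @param task a [centre_out_task()].
#' @param size batch size (must be divisible by the number of targets).
#' @param catch_fraction probability an episode is a catch trial.
#' @param seed optional seed; by default the current RNG stream is used.
#' @param T episode length in steps.
#' @return List of [episode_spec()].
#' @export
centre_out_batch <- function(task, size = 32L, catch_fraction = 0.5,
                             seed = NULL, T = 100L) {
  k <- nrow(task$targets)
  if (size %% k != 0) stop("batch size must be divisible by ", k)
  if (!is.null(seed)) set.seed(seed)
  idx <- rep(seq_len(k), size / k)
  catch <- runif(size) < catch_fraction
  go <- ifelse(catch, 0L, sample_go_step(size))
  lapply(seq_len(size), function(i) {
    episode_spec(task$start_q, task$targets[idx[i], ], go[i], T = T)
  })
}

#' Evaluation rollouts for analysis
#'
#' One noise-free, non-catch rollout per target with a long episode and a
#' late, fixed go cue so that the preparatory sample 340 ms before the go cue
#' exists and the hidden state has settled.
#'
#' @param params trained controller parameters.
#' @param task a [centre_out_task()].
#' @param field the [curl_field()] the phase was trained in.
#' @param eval_spec list with episode length `T` and `go_step` (defaults
#'   150 steps, go at step 50 = 0.5 s).
#' @param config an [arm_config()].
#' @param hook optional hidden-state edit passed to [rollout()].
#' @return List of 8 `trajectory` objects, one per target.
#' @export
evaluation_rollouts <- function(params, task = centre_out_task(),
                                field = curl_field(0),
                                eval_spec = list(T = 150L, go_step = 50L),
                                config = arm_config(), hook = NULL) {
  if (eval_spec$go_step - 34L < 0)
    stop("go cue must be at least 340 ms after episode start")
  eps <- lapply(seq_len(nrow(task$targets)), function(i) {
    episode_spec(task$start_q, task$targets[i, ], eval_spec$go_step,
                 T = eval_spec$T)
  })
  rollout_batch(params, eps, config, field, hook)
}

#' Experiment configuration
#'
#' Bundles everything one run needs: unit count, seeds, growing-up and phase
#' hyper-parameters, the task, the evaluation episode, the plant and the
#' loss.  Defaults are the full-scale study conditions; see [tiny_config()]
#' and [micro_config()] for documented reduced presets.
#'
#' @param n_units hidden units per network.
#' @param seeds integer vector, one network per seed.
#' @param grow_batches,grow_batch_size,grow_lr growing-up schedule.
#' @param phase_batches named vector of batch counts for NF1, FF1, NF2, FF2.
#' @param phase_lr gradient-descent learning rate during phases.
#' @param ff_gain curl-field gain of the trained field (N s / m).
#' @param control if `TRUE`, the first adaptation phase uses the
#'   opposite-sign field (`-ff_gain`) and FF2 the trained field, the
#'   interference control condition.
#' @param T_train training episode length (steps).
#' @param eval_spec evaluation episode (length and go step).
#' @param plant an [arm_config()].
#' @param weights a [loss_weights()].
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(n_units = 128L, seeds = 1:40,
                              grow_batches = 20000L, grow_batch_size = 32L,
                              grow_lr = 0.003,
                              phase_batches = c(NF1 = 10000L, FF1 = 3200L,
                                                NF2 = 10000L, FF2 = 3200L),
                              phase_lr = 0.005, ff_gain = 8,
                              control = FALSE, T_train = 100L,
                              eval_spec = list(T = 150L, go_step = 50L),
                              plant = arm_config(),
                              weights = loss_weights()) {
  stopifnot(all(c("NF1", "FF1", "NF2", "FF2") %in% names(phase_batches)))
  structure(list(n_units = as.integer(n_units), seeds = as.integer(seeds),
                 grow_batches = as.integer(grow_batches),
                 grow_batch_size = as.integer(grow_batch_size),
                 grow_lr = grow_lr, phase_batches = phase_batches,
                 phase_lr = phase_lr, ff_gain = ff_gain, control = control,
                 T_train = as.integer(T_train), eval_spec = eval_spec,
                 plant = plant, weights = weights),
            class = "experiment_config")
}

phase_plan <- function(config) {
  g <- config$ff_gain
  g1 <- if (config$control) -g else g
  list(phase_spec("NF1", 0, config$phase_batches[["NF1"]]),
       phase_spec("FF1", g1, config$phase_batches[["FF1"]]),
       phase_spec("NF2", 0, config$phase_batches[["NF2"]]),
       phase_spec("FF2", g, config$phase_batches[["FF2"]]))
}

#' Grow one network
#'
#' Initialises a controller from the seed and runs the growing-up phase.
#'
#' @param config an [experiment_config()].
#' @param seed the network's seed.
#' @return List with `params` and the growing-up `log`.
#' @export
grow_network <- function(config, seed) {
  params <- init_params(config$n_units, seed = seed)
  growing_up(params, config$plant, seed = seed + 1000L,
             batches = config$grow_batches,
             batch_size = config$grow_batch_size,
             lr = config$grow_lr, T = config$T_train,
             weights = config$weights)
}

#' Run the four experimental phases for one network
#'
#' Applies the post-growing-up freeze and trains NF1, FF1, NF2, FF2 in
#' order (FF1 carries the opposite-sign field when `config$control` is
#' set).  Evaluation rollouts (in the phase's own field) are collected at
#' every phase end.
#'
#' @param params post-growing-up parameters.
#' @param config an [experiment_config()].
#' @param seed the network's seed.
#' @return List with per-phase `checkpoints`, `curves`, `evals`, and the
#'   final `params`.
#' @export
run_phases <- function(params, config, seed) {
  task <- centre_out_task(config = config$plant)
  checkpoints <- list(); curves <- list(); evals <- list()
  for (ph in phase_plan(config)) {
    res <- train_phase(params, ph, task, config$plant,
                       seed = seed + 2000L + match(ph$name,
                                                   c("NF1", "FF1",
                                                     "NF2", "FF2")),
                       lr = config$phase_lr, weights = config$weights)
    params <- res$params
    checkpoints[[ph$name]] <- params
    curves[[ph$name]] <- res$curve
    evals[[ph$name]] <- evaluation_rollouts(params, task, curl_field(ph$b),
                                            config$eval_spec, config$plant)
  }
  list(checkpoints = checkpoints, curves = curves, evals = evals,
       params = params)
}

#' Run the full experiment across seeds
#'
#' For each seed: growing up, then the four phases with the frozen mask
#' applied.  No observation ever encodes the field gain; the field acts only
#' through the plant dynamics.
#'
#' @param config an [experiment_config()].
#' @param grown optional named list of pre-grown networks (as returned by
#'   [grow_network()]), keyed by seed, to share growing-up across the main
#'   and control conditions.
#' @param verbose print progress.
#' @return An object of class `experiment_record`: per seed, the growing-up
#'   checkpoint, phase checkpoints, learning curves and evaluation rollouts,
#'   with the configuration embedded.
#' @export
run_experiment <- function(config, grown = NULL, verbose = FALSE) {
  networks <- lapply(config$seeds, function(seed) {
    if (verbose) message("seed ", seed, ": growing up")
    gw <- if (!is.null(grown) && !is.null(grown[[as.character(seed)]]))
      grown[[as.character(seed)]] else grow_network(config, seed)
    if (verbose) message("seed ", seed, ": phases")
    ph <- run_phases(gw$params, config, seed)
    list(seed = seed, n_units = config$n_units,
         checkpoints = c(list(grow = gw$params), ph$checkpoints),
         grow_log = gw$log, curves = ph$curves, evals = ph$evals)
  })
  names(networks) <- as.character(config$seeds)
  structure(list(networks = networks, config = config),
            class = "experiment_record")
}

#' Behavioural savings summary of one network
#'
#' Aligns the FF-phase learning curves with the field's push direction, fits
#' the exponential learning-rate model to each, and classifies rate and
#' deviation savings.
#'
#' @param network one element of an `experiment_record`'s `networks`.
#' @param config the record's `experiment_config`.
#' @return List with per-phase fits, field-aligned batch-0 deviations and
#'   the [classify_savings()] flags.
#' @export
analyze_savings <- function(network, config) {
  plan <- phase_plan(config)
  names(plan) <- vapply(plan, `[[`, character(1), "name")
  aligned <- function(phase) {
    b <- plan[[phase]]$b
    cv <- network$curves[[phase]]
    learning_curve(field_aligned_deviation(cv$deviation, b), phase)
  }
  ff1 <- aligned("FF1"); ff2 <- aligned("FF2")
  fit1 <- fit_learning_curve(ff1); fit2 <- fit_learning_curve(ff2)
  dev1 <- ff1$deviation[1]; dev2 <- ff2$deviation[1]
  c(list(fit_ff1 = fit1, fit_ff2 = fit2,
         dev_ff1_b0 = dev1, dev_ff2_b0 = dev2),
    classify_savings(fit1, fit2, dev1, dev2))
}

#' @export
print.experiment_record <- function(x, ...) {
  cat(sprintf("<experiment_record: %d network(s), %d units, %s>\n",
              length(x$networks), x$config$n_units,
              if (x$config$control) "control (opposite-field)" else "main"))
  invisible(x)
}
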