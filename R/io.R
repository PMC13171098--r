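# Structured-config and artifact I/O: YAML experiment configs, delimited-text
# logs, and parameter checkpoints with a shape manifest.

#' Write an experiment configuration to a YAML file
#'
#' @param config an [experiment_config()].
#' @param path output file.
#' @export
write_experiment_config <- function(config, path) {
  x <- unclass(config)
  x$plant <- unclass(x$plant)
  x$plant$moment <- apply(x$plant$moment, 1, as.list, simplify = FALSE)
  x$weights <- unclass(x$weights)
  x$phase_batches <- as.list(x$phase_batches)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read an experiment configuration from a YAML file
#'
#' @param path YAML file written by [write_experiment_config()] (or edited
#'   by hand with the same sections).
#' @return An [experiment_config()].
#' @export
read_experiment_config <- function(path) {
  x <- yaml::read_yaml(path)
  moment <- do.call(rbind, lapply(x$plant$moment, unlist))
  plant_args <- x$plant
  plant_args$moment <- moment
  plant <- do.call(arm_config, plant_args)
  experiment_config(n_units = x$n_units, seeds = unlist(x$seeds),
                    grow_batches = x$grow_batches,
                    grow_batch_size = x$grow_batch_size,
                    grow_lr = x$grow_lr,
                    phase_batches = unlist(x$phase_batches),
                    phase_lr = x$phase_lr, ff_gain = x$ff_gain,
                    control = isTRUE(x$control), T_train = x$T_train,
                    eval_spec = lapply(x$eval_spec, as.integer),
                    plant = plant,
                    weights = do.call(loss_weights, x$weights))
}

#' Save a parameter checkpoint
#'
#' Stores the parameter arrays together with a manifest of shapes and the
#' frozen mask, so checkpoints are self-describing.
#'
#' @param params a [init_params()] object.
#' @param path output file (`.rds`).
#' @export
save_checkpoint <- function(params, path) {
  manifest <- lapply(unclass(params), function(p)
    if (is.matrix(p)) dim(p) else length(p))
  saveRDS(list(params = unclass(params), n_units = attr(params, "n_units"),
               manifest = manifest, frozen = frozen_mask()), path)
  invisible(path)
}

#' Load a parameter checkpoint
#'
#' @param path file written by [save_checkpoint()].
#' @return A `ctrl_params` object; shapes are checked against the manifest.
#' @export
load_checkpoint <- function(path) {
  x <- readRDS(path)
  for (nm in names(x$manifest)) {
    got <- if (is.matrix(x$params[[nm]])) dim(x$params[[nm]])
           else length(x$params[[nm]])
    if (!identical(got, x$manifest[[nm]]))
      stop("checkpoint shape mismatch for ", nm)
  }
  structure(x$params, class = "ctrl_params", n_units = x$n_units)
}

#' Write a learning curve as a delimited-text table
#'
#' @param curve a [learning_curve()].
#' @param path output CSV.
#' @export
write_learning_curve <- function(curve, path) {
  write.csv(data.frame(batch = curve$batch, phase = curve$phase,
                       deviation = curve$deviation),
            path, row.names = FALSE)
  invisible(path)
}
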