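# Causal test: inject scaled uniform-shift vectors into the hidden state
# during preparation and measure the effect on re-exposure behaviour.

#' Perturbation specification
#'
#' A hidden-state perturbation of magnitude `m` along a direction vector,
#' applied at exactly one state index (340 ms before the go cue by default)
#' for one simulation step.
#'
#' @param direction unit-space direction (typically the uniform shift).
#' @param magnitude scalar multiplier (the study used -2, -1, 0, 1, 2).
#' @param step state index at which the perturbation is applied (0-based).
#' @return An object of class `perturbation_spec`.
#' @export
perturbation_spec <- function(direction, magnitude, step) {
  if (inherits(direction, "uniform_shift")) direction <- direction$us
  stopifnot(is.numeric(direction), length(magnitude) == 1, step >= 0)
  structure(list(direction = direction, magnitude = magnitude,
                 step = as.integer(step)), class = "perturbation_spec")
}

#' Rollout with a hidden-state perturbation
#'
#' Identical to [rollout()] except that `magnitude * direction` is added to
#' the stored hidden state at the application step, before the output layer
#' and the next recurrent step read it; no other step is modified.
#'
#' @param params controller parameters.
#' @param episode an [episode_spec()]; its go cue must be at least 340 ms
#'   after episode start when the default timing is used.
#' @param field a [curl_field()].
#' @param spec a [perturbation_spec()].
#' @param config an [arm_config()].
#' @return A `trajectory`.
#' @export
perturbed_rollout <- function(params, episode, field, spec,
                              config = arm_config()) {
  if (spec$step > episode$T) stop("perturbation step out of range")
  rollout(params, episode, config, field,
          hook = list(step = spec$step,
                      delta = spec$magnitude * spec$direction))
}

#' Dose-response perturbation experiment
#'
#' Runs perturbed evaluation rollouts at the start of re-exposure (the
#' washed-out checkpoint, before any FF2 training), separately for each
#' movement direction and each magnitude, in the trained field.  Deviations
#' are reported field-aligned (positive = in the field's push direction), so
#' negative magnitudes are expected to increase deviation (erasing the
#' memory trace) and positive magnitudes to decrease it.
#'
#' @param params the checkpoint at FF2 batch 0 (end of washout).
#' @param us the network's [compute_uniform_shift()] (from its NF1/FF1).
#' @param magnitudes perturbation magnitudes.
#' @param field_b gain of the trained field.
#' @param task a [centre_out_task()].
#' @param eval_spec evaluation episode (length and go step).
#' @param config an [arm_config()].
#' @return List with `table` (magnitude x target deviations, field-aligned)
#'   and `mean_by_magnitude`.
#' @export
perturbation_experiment <- function(params, us,
                                    magnitudes = c(-2, -1, 0, 1, 2),
                                    field_b = 8,
                                    task = centre_out_task(),
                                    eval_spec = list(T = 150L, go_step = 50L),
                                    config = arm_config()) {
  if (inherits(us, "uniform_shift")) us <- us$us
  if (is.null(us) || is.null(params)) stop("missing checkpoint or shift")
  p_step <- eval_spec$go_step - PREP_OFFSET_STEPS
  if (p_step < 0) stop("go cue too early for the perturbation step")
  rows <- list()
  for (m in magnitudes) {
    evals <- evaluation_rollouts(params, task, curl_field(field_b), eval_spec,
                                 config,
                                 hook = list(step = p_step, delta = m * us))
    dev <- vapply(evals, lateral_deviation, numeric(1))
    rows[[length(rows) + 1L]] <-
      data.frame(magnitude = m, target = seq_along(evals),
                 deviation = field_aligned_deviation(dev, field_b))
  }
  tab <- do.call(rbind, rows)
  means <- tapply(tab$deviation, tab$magnitude, mean)
  list(table = tab,
       mean_by_magnitude = data.frame(magnitude = as.numeric(names(means)),
                                      deviation = as.numeric(means)))
}
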