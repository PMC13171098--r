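# Neural-geometry analyses of preparatory activity: the force-predictive
# subspace from targeted dimensionality reduction, the uniform shift, their
# normalised projections, and a PCA projection utility.

PREP_OFFSET_STEPS <- 34L   # 340 ms before the go cue
FORCE_OFFSET_STEPS <- 9L   # 90 ms after the go cue (peak acceleration)

#' Preparatory-activity matrix from evaluation rollouts
#'
#' Hidden-unit activity sampled exactly 340 ms before the go cue, one row per
#' target.
#'
#' @param evals list of evaluation `trajectory` objects (one per target).
#' @return `targets x units` matrix with the phase sample time as attribute.
#' @export
prep_activity <- function(evals) {
  g <- evals[[1]]$go_step
  s <- g - PREP_OFFSET_STEPS
  if (s < 0) stop("episode too short for the preparatory sample")
  H <- t(vapply(evals, function(tr) tr$h[s + 1L, ], numeric(ncol(evals[[1]]$h))))
  attr(H, "state_index") <- s
  H
}

#' Endpoint-force matrix from evaluation rollouts
#'
#' Muscle-generated endpoint force sampled 90 ms after the go cue (the early
#' acceleration phase), one row per target; the external field is excluded.
#'
#' @param evals list of evaluation `trajectory` objects.
#' @param config an [arm_config()].
#' @return `targets x 2` force matrix (N).
#' @export
force_matrix <- function(evals, config = arm_config()) {
  g <- evals[[1]]$go_step
  s <- g + FORCE_OFFSET_STEPS
  t(vapply(evals, function(tr) {
    endpoint_force(list(q = tr$q[s + 1L, ], f = tr$f[s, ]), config)
  }, numeric(2)))
}

# Moore-Penrose pseudo-inverse via SVD with a relative cutoff.
pinv <- function(A, rcond = 1e-12) {
  s <- svd(A)
  keep <- s$d > rcond * s$d[1]
  s$v[, keep, drop = FALSE] %*%
    ((1 / s$d[keep]) * t(s$u[, keep, drop = FALSE]))
}

#' Fit the force-predictive preparatory subspace (TDR)
#'
#' Solves `H = [F 1] W` by least squares (`W` is 3 x units), takes the first
#' two columns of the pseudo-inverse `W+` (ignoring the intercept column) and
#' orthonormalises them by Gram-Schmidt in column order.
#'
#' @param H `targets x units` preparatory-activity matrix (baseline phase).
#' @param F `targets x 2` endpoint-force matrix.
#' @return An object of class `tdr_subspace` with the orthonormal basis
#'   `What` (units x 2) and the raw `W`, `Wplus`.
#' @export
fit_tdr <- function(H, F) {
  stopifnot(nrow(H) == nrow(F), ncol(F) == 2, ncol(H) >= 3)
  A <- cbind(F, 1)
  if (qr(A)$rank < 3) stop("rank-deficient regressor matrix [F 1]")
  W <- qr.solve(A, H)                   # 3 x units
  Wplus <- pinv(W)                      # units x 3
  v1 <- Wplus[, 1]
  v1 <- v1 / sqrt(sum(v1^2))
  v2 <- Wplus[, 2] - sum(v1 * Wplus[, 2]) * v1
  v2 <- v2 / sqrt(sum(v2^2))
  structure(list(What = cbind(v1, v2, deparse.level = 0), W = W,
                 Wplus = Wplus), class = "tdr_subspace")
}

#' Project preparatory activity onto the TDR plane
#'
#' @param H `targets x units` preparatory-activity matrix.
#' @param tdr a [fit_tdr()] result.
#' @param global_mean unit-space mean over all phases and targets entering
#'   the comparison.
#' @return `targets x 2` coordinates in the force-predictive plane.
#' @export
project_onto_tdr <- function(H, tdr, global_mean = colMeans(H)) {
  sweep(H, 2, global_mean) %*% tdr$What
}

#' Uniform shift of preparatory activity
#'
#' Target-averaged displacement of preparatory activity from the baseline to
#' the adapted phase, orthogonalised against the TDR plane; its residual
#' after washout is the candidate memory trace.
#'
#' @param H_ff1,H_nf1 `targets x units` preparatory matrices.
#' @param tdr a [fit_tdr()] result.
#' @return An object of class `uniform_shift` with the orthogonalised vector
#'   `us` and the raw difference `us_raw`.
#' @export
compute_uniform_shift <- function(H_ff1, H_nf1, tdr) {
  stopifnot(ncol(H_ff1) == ncol(H_nf1))
  us_raw <- colMeans(H_ff1) - colMeans(H_nf1)
  us <- us_raw - drop(tdr$What %*% (t(tdr$What) %*% us_raw))
  structure(list(us = us, us_raw = us_raw), class = "uniform_shift")
}

#' Normalised uniform-shift projections of all phases
#'
#' Projects each phase's target-mean preparatory activity (global mean
#' removed) onto the uniform shift, then rescales so the baseline phase maps
#' to 0 and the first adaptation phase to 1; washout and re-exposure land on
#' that scale.
#'
#' @param H_by_phase named list of 4 preparatory matrices
#'   (`NF1, FF1, NF2, FF2`).
#' @param us a [compute_uniform_shift()] result.
#' @param global_mean grand mean over all phases x targets; computed from
#'   `H_by_phase` if omitted.
#' @return Named numeric vector of normalised projections.
#' @export
project_and_normalize <- function(H_by_phase, us, global_mean = NULL) {
  stopifnot(length(H_by_phase) == 4)
  if (sqrt(sum(us$us^2)) < 1e-10)
    stop("uniform shift is numerically zero; normalisation undefined")
  if (is.null(global_mean))
    global_mean <- colMeans(do.call(rbind, H_by_phase))
  p <- vapply(H_by_phase, function(H) {
    sum((colMeans(H) - global_mean) * us$us)
  }, numeric(1))
  denom <- p[["FF1"]] - p[["NF1"]]
  if (abs(denom) < 1e-12)
    stop("degenerate normalisation: FF1 and NF1 project identically")
  (p - p[["NF1"]]) / denom
}

#' Uniform-shift analysis of one trained network
#'
#' Convenience wrapper running the full preparatory-geometry pipeline on an
#' experiment record entry: TDR fitted on the baseline phase, uniform shift
#' from baseline vs adaptation, normalised projections of all four phases.
#'
#' @param network one element of an `experiment_record`'s `networks`.
#' @param config the record's `experiment_config`.
#' @return List with `tdr`, `us`, the preparatory matrices `H`, the force
#'   matrix `F`, and the normalised `projections`.
#' @export
analyze_uniform_shift <- function(network, config) {
  H <- lapply(network$evals, prep_activity)
  F <- force_matrix(network$evals$NF1, config$plant)
  tdr <- fit_tdr(H$NF1, F)
  us <- compute_uniform_shift(H$FF1, H$NF1, tdr)
  proj <- project_and_normalize(H[c("NF1", "FF1", "NF2", "FF2")], us)
  list(tdr = tdr, us = us, H = H, F = F, projections = proj)
}

#' PCA projection of pooled hidden activity
#'
#' Mean-centred principal components of condition x time hidden activity,
#' for qualitative visualisation of preparatory and movement trajectories.
#'
#' @param hidden matrix of pooled activity (samples x units).
#' @param k number of components to return.
#' @return List with `scores` (samples x k), component standard deviations
#'   `sdev`, the `rotation`, and the grand `center`.
#' @export
pca_project <- function(hidden, k = 3L) {
  stopifnot(ncol(hidden) >= k)
  pc <- prcomp(hidden, center = TRUE, scale. = FALSE)
  list(scores = pc$x[, seq_len(k), drop = FALSE], sdev = pc$sdev,
       rotation = pc$rotation, center = pc$center)
}
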