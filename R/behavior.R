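# Behavioural metrics: signed maximum lateral deviation, exponential
# learning-rate fits, savings classification, and cross-network statistics.

#' Signed maximum lateral deviation
#'
#' Maximum absolute perpendicular distance of the path from the straight
#' start-to-target segment, signed positive when the deviating point lies
#' clockwise of the segment (negative z-component of
#' `cross(target - start, point - start)` in the y-up workspace frame).
#' For a `trajectory`, only movement samples (states from the go step
#' onward) are used.
#'
#' @param traj a `trajectory` from [rollout()], or a 2-column matrix of path
#'   points (all rows used).
#' @param start,target segment endpoints (m, 2); taken from the trajectory
#'   if omitted.
#' @return Signed deviation in metres (positive = clockwise).
#' @export
lateral_deviation <- function(traj, start = NULL, target = NULL) {
  if (inherits(traj, "trajectory")) {
    if (traj$catch) stop("lateral deviation is undefined for catch episodes")
    if (is.null(start)) start <- traj$start
    if (is.null(target)) target <- traj$target
    pts <- traj$x[(traj$go_step + 1):(traj$T + 1), , drop = FALSE]
  } else {
    pts <- as.matrix(traj)
    stopifnot(!is.null(start), !is.null(target))
  }
  u <- target - start
  len <- sqrt(sum(u^2))
  if (len < 1e-12) stop("start and target coincide")
  w1 <- pts[, 1] - start[1]; w2 <- pts[, 2] - start[2]
  d_cw <- -(u[1] * w2 - u[2] * w1) / len   # positive = clockwise
  d_cw[which.max(abs(d_cw))]
}

#' Deviation expressed in the force field's push direction
#'
#' The curl matrix rotates velocity by +90 degrees in the y-up frame, so a
#' positive gain deflects reaches counter-clockwise.  Learning curves and
#' savings comparisons are made on `-sign(b) * deviation`, which is positive
#' when the hand deviates in the direction the field pushes, independent of
#' the field's sign.
#'
#' @param dev signed lateral deviation(s), clockwise-positive.
#' @param b field gain of the phase being aligned to.
#' @return Field-aligned deviation(s); unchanged for `b = 0`.
#' @export
field_aligned_deviation <- function(dev, b) {
  if (b == 0) dev else -sign(b) * dev
}

#' Learning curve container
#'
#' @param deviation per-batch mean signed lateral deviation (m).
#' @param phase phase name.
#' @param batch 0-based batch indices.
#' @return An object of class `learning_curve`.
#' @export
learning_curve <- function(deviation, phase = "",
                           batch = seq_along(deviation) - 1L) {
  stopifnot(length(deviation) == length(batch))
  structure(list(deviation = as.numeric(deviation), batch = as.integer(batch),
                 phase = phase), class = "learning_curve")
}

# centred moving average with shrinking windows at the edges
smooth_ma <- function(y, k = 5L) {
  half <- k %/% 2L
  n <- length(y)
  vapply(seq_len(n), function(i) {
    mean(y[max(1, i - half):min(n, i + half)])
  }, numeric(1))
}

#' Fit an exponential learning curve
#'
#' Smooths the deviation series with a 5-batch moving average, then fits
#' `y = alpha * exp(-r * x / 1000)` by nonlinear least squares, where `x` is
#' the batch number.  `r` is the decay rate per 1000 batches (the learning
#' rate); negative `r` encodes worsening performance and is permitted.
#'
#' @param curve a [learning_curve()] (at least 10 batches).
#' @param kernel moving-average window (batches).
#' @return An object of class `exp_fit` with `alpha`, `r`, `resid_norm` and
#'   a `converged` flag (a failed fit is returned flagged, with the error
#'   message in `diagnostic`).
#' @export
fit_learning_curve <- function(curve, kernel = 5L) {
  stopifnot(inherits(curve, "learning_curve"), length(curve$deviation) >= 10)
  y <- smooth_ma(curve$deviation, kernel)
  x <- as.numeric(curve$batch)
  a0 <- y[1]
  if (abs(a0) < 1e-12) a0 <- mean(y) + 1e-9
  r0 <- 1
  if (a0 > 0 && all(y > 0)) {
    lf <- stats::lm(log(y) ~ x)
    r0 <- -coef(lf)[[2]] * 1000
    a0 <- exp(coef(lf)[[1]])
  }
  try_fit <- function(a, r) tryCatch(
    minpack.lm::nlsLM(y ~ alpha * exp(-r * x / 1000),
                      start = list(alpha = a, r = r),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  fit <- try_fit(a0, r0)
  # a start that already fits perfectly can abort the optimiser; nudge it
  if (inherits(fit, "error")) fit <- try_fit(a0 * 1.01 + 1e-9, r0 + 0.5)
  if (inherits(fit, "error")) {
    return(structure(list(alpha = NA_real_, r = NA_real_,
                          resid_norm = NA_real_, converged = FALSE,
                          diagnostic = conditionMessage(fit)),
                     class = "exp_fit"))
  }
  cf <- coef(fit)
  structure(list(alpha = cf[["alpha"]], r = cf[["r"]],
                 resid_norm = sqrt(sum(stats::resid(fit)^2)),
                 converged = TRUE, diagnostic = NULL),
            class = "exp_fit")
}

#' Classify savings from paired adaptation phases
#'
#' Rate savings: the re-exposure learning rate exceeds the first-exposure
#' rate.  Deviation savings: the initial (batch-0) deviation on re-exposure
#' is smaller than on first exposure.  Both use strict inequalities (ties
#' are not savings), and both expect field-aligned deviations so "smaller"
#' means less deflection in the field's direction.
#'
#' @param fit1,fit2 [fit_learning_curve()] results for FF1 and FF2.
#' @param dev1_b0,dev2_b0 field-aligned batch-0 deviations (m).
#' @return List with logical `rate_savings` and `deviation_savings`.
#' @export
classify_savings <- function(fit1, fit2, dev1_b0, dev2_b0) {
  list(rate_savings = isTRUE(fit2$r > fit1$r),
       deviation_savings = isTRUE(dev2_b0 < dev1_b0))
}

#' Proportion of networks showing savings, with Wilson interval
#'
#' @param flags logical vector, one entry per network.
#' @param conf confidence level.
#' @return List with `percentage` and the Wilson score `ci` (percent).
#' @export
savings_rate <- function(flags, conf = 0.95) {
  if (length(flags) < 1) stop("empty flag list")
  n <- length(flags)
  p <- mean(flags)
  z <- qnorm(1 - (1 - conf) / 2)
  centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  list(percentage = 100 * p,
       ci = 100 * c(lower = max(0, centre - half),
                    upper = min(1, centre + half)))
}

#' Paired t test
#'
#' @param sample_a,sample_b equal-length numeric vectors (paired by network).
#' @return List with `t`, `df` and the two-tailed `p`.
#' @export
paired_t <- function(sample_a, sample_b) {
  stopifnot(length(sample_a) == length(sample_b), length(sample_a) >= 2)
  d <- sample_a - sample_b
  if (sd(d) <= 1e-12 * max(abs(d), 1)) {
    if (all(abs(d) <= 1e-12)) return(list(t = 0, df = length(d) - 1L, p = 1))
    stop("zero variance of paired differences")
  }
  tt <- t.test(sample_a, sample_b, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}
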