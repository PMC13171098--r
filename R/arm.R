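# Effector: planar two-joint arm with six muscle-like actuators and an
# optional velocity-dependent curl force field at the endpoint.

MUSCLE_NAMES <- c("SF", "SE", "EF", "EE", "BF", "BE")

#' Arm model configuration
#'
#' Parameters of the simplified rigid-tendon Hill-type arm: a planar two-link
#' rigid body driven by six muscles (shoulder flexor/extensor, elbow
#' flexor/extensor, bi-articular flexor/extensor) with constant signed moment
#' arms, a first-order activation filter, Gaussian force-length and sigmoidal
#' force-velocity scaling, smooth soft joint limits, and light viscous joint
#' damping.  Muscle lengths are affine in the joint angles and are at optimal
#' length at the reference posture `qref`.
#'
#' @param L1,L2 upper-arm and forearm lengths (m).
#' @param m1,m2 link masses (kg).
#' @param lc1,lc2 link centre-of-mass distances from the proximal joint (m).
#' @param I1,I2 link moments of inertia about the centre of mass (kg m^2).
#' @param moment 6 x 2 matrix of signed muscle moment arms (m); rows are the
#'   muscles `SF, SE, EF, EE, BF, BE`, columns shoulder and elbow.  Flexors
#'   have positive entries (they increase the joint angle).
#' @param fmax per-muscle maximum isometric force (N).
#' @param lopt per-muscle optimal length (m); lengths are normalised by it.
#' @param tau_act activation time constant (s).
#' @param dt integration time step (s).
#' @param vmax maximum normalised shortening velocity (optimal lengths / s).
#' @param fl_width width of the Gaussian force-length curve (normalised).
#' @param fv_slope slope parameter of the sigmoidal force-velocity curve.
#' @param joint_damping viscous joint damping (N m s / rad).
#' @param qref reference posture (rad) at which all muscles sit at optimal
#'   length; defaults to the centre-out start (shoulder 60 deg, elbow 90 deg).
#' @param qmin,qmax soft joint-angle limits (rad).
#' @param klim,slim stiffness (N m / rad) and smoothing width (rad) of the
#'   soft-limit torque.
#' @return An object of class `arm_config`.
#' @export
arm_config <- function(L1 = 0.30, L2 = 0.33,
                       m1 = 1.8, m2 = 1.2,
                       lc1 = 0.15, lc2 = 0.165,
                       I1 = m1 * L1^2 / 12, I2 = m2 * L2^2 / 12,
                       moment = default_moment_arms(),
                       fmax = c(40, 40, 30, 30, 35, 35),
                       lopt = rep(0.1, 6),
                       tau_act = 0.05,
                       dt = 0.01,
                       vmax = 10,
                       fl_width = 0.45,
                       fv_slope = 4,
                       joint_damping = 0.05,
                       qref = c(pi / 3, pi / 2),
                       qmin = c(0, 5 * pi / 180),
                       qmax = c(135 * pi / 180, 155 * pi / 180),
                       klim = 20, slim = 0.05) {
  moment <- as.matrix(moment)
  dimnames(moment) <- list(MUSCLE_NAMES, c("shoulder", "elbow"))
  cfg <- list(L1 = L1, L2 = L2, m1 = m1, m2 = m2, lc1 = lc1, lc2 = lc2,
              I1 = I1, I2 = I2, moment = moment, fmax = fmax, lopt = lopt,
              tau_act = tau_act, dt = dt, vmax = vmax, fl_width = fl_width,
              fv_slope = fv_slope, joint_damping = joint_damping,
              qref = qref, qmin = qmin, qmax = qmax, klim = klim, slim = slim)
  class(cfg) <- "arm_config"
  validate_arm_config(cfg)
  cfg
}

default_moment_arms <- function() {
  rbind(SF = c( 0.040, 0.000),
        SE = c(-0.040, 0.000),
        EF = c( 0.000, 0.025),
        EE = c( 0.000, -0.025),
        BF = c( 0.028, 0.028),
        BE = c(-0.028, -0.028))
}

validate_arm_config <- function(cfg) {
  stopifnot(cfg$dt > 0, cfg$L1 > 0, cfg$L2 > 0, cfg$m1 > 0, cfg$m2 > 0,
            all(cfg$fmax > 0), all(cfg$lopt > 0), cfg$tau_act > 0)
  nz <- rowSums(cfg$moment != 0)
  if (!all(nz[1:4] == 1L) || !all(nz[5:6] == 2L))
    stop("moment-arm sign pattern must give mono-articular muscles one ",
         "nonzero column and bi-articular muscles two")
  # flexors pull the joint positive, extensors negative
  signs <- sign(cfg$moment)
  ok <- signs["SF", 1] > 0 && signs["SE", 1] < 0 &&
    signs["EF", 2] > 0 && signs["EE", 2] < 0 &&
    all(signs["BF", ] > 0) && all(signs["BE", ] < 0)
  if (!ok) stop("moment-arm signs do not realise the named muscles")
  invisible(cfg)
}

#' Curl force field
#'
#' @param b field gain (N s / m); 0 gives a null field, +8 the trained field,
#'   -8 the opposite-sign control field.
#' @return An object of class `curl_field`.
#' @export
curl_field <- function(b = 0) {
  if (!is.finite(b)) stop("curl-field gain must be finite")
  structure(list(b = b), class = "curl_field")
}

#' Velocity-dependent curl force
#'
#' Returns the endpoint force `(Fx, Fy) = b [[0, -1], [1, 0]] (vx, vy)`, a
#' force of magnitude `|b| |v|` always orthogonal to the endpoint velocity.
#'
#' @param v endpoint velocity, length-2 (m/s).
#' @param b field gain (N s / m), or a [curl_field()].
#' @return Length-2 force vector (N).
#' @export
curl_force <- function(v, b) {
  if (inherits(b, "curl_field")) b <- b$b
  if (length(v) != 2 || !all(is.finite(v)) || !is.finite(b))
    stop("curl_force needs a finite 2-vector velocity and finite gain")
  b * c(-v[2], v[1])
}

#' Forward kinematics of the two-link arm
#'
#' @param q joint angles (rad): a length-2 vector or a 2-column matrix.
#' @param config an [arm_config()].
#' @return Endpoint position(s) (m), same shape convention as `q`.
#' @export
forward_kinematics <- function(q, config = arm_config()) {
  if (is.matrix(q)) {
    t(cpp_forward_kinematics(unclass(config), t(q)))
  } else {
    drop(cpp_forward_kinematics(unclass(config), matrix(q, 2, 1)))
  }
}

#' Endpoint Jacobian of the two-link arm
#'
#' @inheritParams forward_kinematics
#' @return 2 x 2 Jacobian of endpoint position with respect to joint angles.
#' @export
arm_jacobian <- function(q, config = arm_config()) {
  cpp_jacobian(unclass(config), q[1], q[2])
}

muscle_geometry <- function(q, qd, config) {
  ln <- 1 - drop(config$moment %*% (q - config$qref)) / config$lopt
  vn <- -drop(config$moment %*% qd) / (config$lopt * config$vmax)
  list(ln = ln, vn = vn)
}

#' Construct an arm state
#'
#' @param q joint angles (rad, 2).
#' @param qd joint velocities (rad/s, 2).
#' @param act muscle activations in `[0, 1]` (6).
#' @param config an [arm_config()].
#' @return An object of class `arm_state` with derived endpoint position,
#'   endpoint velocity, normalised muscle lengths/velocities and muscle
#'   forces.
#' @export
arm_state <- function(q, qd = c(0, 0), act = rep(0, 6),
                      config = arm_config()) {
  stopifnot(length(q) == 2, length(qd) == 2, length(act) == 6,
            all(is.finite(c(q, qd, act))), all(act >= 0), all(act <= 1))
  g <- muscle_geometry(q, qd, config)
  fl <- exp(-((g$ln - 1) / config$fl_width)^2)
  fv <- 2 / (1 + exp(-config$fv_slope * g$vn))
  f <- config$fmax * act * fl * fv
  J <- arm_jacobian(q, config)
  structure(list(q = q, qd = qd, act = act,
                 ln = g$ln, vn = g$vn, f = f,
                 x = drop(forward_kinematics(q, config)),
                 v = drop(J %*% qd)),
            class = "arm_state")
}

#' Advance the arm one time step
#'
#' Semi-implicit Euler step of the muscle-driven two-link dynamics:
#' first-order activation dynamics, Hill-type force scaling, joint torques
#' through the constant moment arms, rigid-body dynamics, and the curl-field
#' force mapped through the endpoint Jacobian transpose.  The update is a
#' smooth function of state and stimulation, so gradients can propagate
#' through rollouts.
#'
#' @param state an [arm_state()].
#' @param stimulation muscle stimulation commands in `[0, 1]` (6).
#' @param field a [curl_field()].
#' @param config an [arm_config()].
#' @return The advanced `arm_state`.
#' @export
arm_step <- function(state, stimulation, field = curl_field(0),
                     config = arm_config()) {
  stopifnot(inherits(state, "arm_state"))
  if (length(stimulation) != 6 || !all(is.finite(stimulation)))
    stop("stimulation must be a finite 6-vector")
  if (any(stimulation < 0) || any(stimulation > 1))
    stop("stimulation outside [0, 1] is an API error (the controller's ",
         "sigmoid guarantees range)")
  out <- cpp_plant_step(unclass(config),
                        matrix(state$q, 2, 1), matrix(state$qd, 2, 1),
                        matrix(state$act, 6, 1), matrix(stimulation, 6, 1),
                        field$b)
  ns <- arm_state(drop(out$q), drop(out$qd), pmin(pmax(drop(out$act), 0), 1),
                  config)
  ns$f <- drop(out$f)  # force produced during the transition
  ns
}

#' Muscle-generated force at the endpoint
#'
#' Expresses the muscle joint torques as an equivalent endpoint force through
#' the inverse-transpose Jacobian, excluding any external field contribution.
#' Used as the force covariate (sampled 90 ms after the go cue) when fitting
#' the force-predictive preparatory subspace.
#'
#' @param state an [arm_state()] (or any list with `q` and `f`).
#' @param config an [arm_config()].
#' @return Length-2 endpoint force (N).
#' @export
endpoint_force <- function(state, config = arm_config()) {
  J <- arm_jacobian(state$q, config)
  if (abs(det(J)) < 1e-8)
    stop("endpoint Jacobian is singular (arm fully extended); ",
         "endpoint force is undefined at this posture")
  tau <- drop(t(config$moment) %*% state$f)
  drop(solve(t(J), tau))
}
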