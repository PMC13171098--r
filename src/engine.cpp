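// Differentiable closed-loop simulation engine: a GRU policy with delayed
// visual/proprioceptive feedback drives a planar two-joint arm actuated by six
// Hill-type muscles, optionally inside a velocity-dependent curl force field.
// Forward rollouts and full reverse-mode backpropagation through time are
// implemented here; everything above this level (optimisers, protocol,
// analyses) lives in R.
//
// Conventions used throughout:
//   * batch episodes are matrix columns (dim x B);
//   * "state index" s = 0..T indexes arm/hidden states (s = 0 is the initial
//     state), "step" t = 1..T indexes transitions; step t maps state t-1 to
//     state t and produces stimulation/force arrays stored at slice t-1;
//   * the visual queue is 7 steps deep (70 ms), the proprioceptive queue 2
//     steps (20 ms); before a queue fills it yields the initial state.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;
using Rcpp::List;
using Rcpp::Named;
using Rcpp::stop;

static const int VIS_DELAY = 7;   // steps
static const int PROP_DELAY = 2;  // steps

struct Plant {
  double L1, L2, m1, m2, lc1, lc2, I1, I2;
  double dt, tau_act, vmax, fl_width, fv_slope, joint_damping;
  double klim, slim;
  mat moment;           // 6 x 2 signed moment arms (m)
  vec fmax, lopt;       // 6
  vec qref, qmin, qmax; // 2
};

static Plant plant_from_list(const List& cfg) {
  Plant p;
  p.L1 = cfg["L1"]; p.L2 = cfg["L2"];
  p.m1 = cfg["m1"]; p.m2 = cfg["m2"];
  p.lc1 = cfg["lc1"]; p.lc2 = cfg["lc2"];
  p.I1 = cfg["I1"]; p.I2 = cfg["I2"];
  p.dt = cfg["dt"]; p.tau_act = cfg["tau_act"];
  p.vmax = cfg["vmax"]; p.fl_width = cfg["fl_width"];
  p.fv_slope = cfg["fv_slope"]; p.joint_damping = cfg["joint_damping"];
  p.klim = cfg["klim"]; p.slim = cfg["slim"];
  p.moment = Rcpp::as<mat>(cfg["moment"]);
  p.fmax = Rcpp::as<vec>(cfg["fmax"]);
  p.lopt = Rcpp::as<vec>(cfg["lopt"]);
  p.qref = Rcpp::as<vec>(cfg["qref"]);
  p.qmin = Rcpp::as<vec>(cfg["qmin"]);
  p.qmax = Rcpp::as<vec>(cfg["qmax"]);
  return p;
}

struct Params {
  mat Wz, Wr, Wn;    // n x 17
  mat Uz, Ur, Un;    // n x n
  vec bz, br, bn;    // n
  mat Wout;          // 6 x n
  vec bout;          // 6
  vec h0;            // n
  int n;
};

static Params params_from_list(const List& pl) {
  Params p;
  p.Wz = Rcpp::as<mat>(pl["Wz"]); p.Wr = Rcpp::as<mat>(pl["Wr"]);
  p.Wn = Rcpp::as<mat>(pl["Wn"]);
  p.Uz = Rcpp::as<mat>(pl["Uz"]); p.Ur = Rcpp::as<mat>(pl["Ur"]);
  p.Un = Rcpp::as<mat>(pl["Un"]);
  p.bz = Rcpp::as<vec>(pl["bz"]); p.br = Rcpp::as<vec>(pl["br"]);
  p.bn = Rcpp::as<vec>(pl["bn"]);
  p.Wout = Rcpp::as<mat>(pl["Wout"]); p.bout = Rcpp::as<vec>(pl["bout"]);
  p.h0 = Rcpp::as<vec>(pl["h0"]);
  p.n = p.Uz.n_rows;
  return p;
}

static inline mat sigmoid_mat(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

static inline void fk_point(const Plant& P, double q1, double q2,
                            double& x, double& y) {
  x = P.L1 * std::cos(q1) + P.L2 * std::cos(q1 + q2);
  y = P.L1 * std::sin(q1) + P.L2 * std::sin(q1 + q2);
}

static inline void jacobian(const Plant& P, double q1, double q2, mat22& J) {
  double s1 = std::sin(q1), c1 = std::cos(q1);
  double s12 = std::sin(q1 + q2), c12 = std::cos(q1 + q2);
  J(0, 0) = -P.L1 * s1 - P.L2 * s12; J(0, 1) = -P.L2 * s12;
  J(1, 0) =  P.L1 * c1 + P.L2 * c12; J(1, 1) =  P.L2 * c12;
}

static inline double softplus(double x) {
  return x > 30.0 ? x : std::log1p(std::exp(x));
}
static inline double sigmoid1(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// Soft joint-limit torque: smooth restoring torque growing past qmin/qmax.
static inline double limit_torque(const Plant& P, int j, double q) {
  return P.klim * P.slim * softplus((P.qmin(j) - q) / P.slim)
       - P.klim * P.slim * softplus((q - P.qmax(j)) / P.slim);
}
static inline double limit_torque_dq(const Plant& P, int j, double q) {
  return -P.klim * (sigmoid1((P.qmin(j) - q) / P.slim)
                  + sigmoid1((q - P.qmax(j)) / P.slim));
}

// Everything recorded during a forward pass, sized for reverse-mode reuse.
struct Rollout {
  int T, B, n;
  cube Q, QD, ACT, LN, VN, X;     // states: dim x B x (T+1)
  cube H;                         // n x B x (T+1)
  cube Z, Rg, Nc;                 // n x B x T (GRU gate records)
  cube U, F, FL, FV;              // 6 x B x T
  cube OBS;                       // 17 x B x T
};

static void state_geometry(const Plant& P, const mat& q, const mat& qd,
                           mat& ln, mat& vn, mat& x) {
  // ln = 1 - moment (q - qref) / lopt ; vn = -moment qd / (lopt vmax)
  const int B = q.n_cols;
  mat dq = q; dq.each_col() -= P.qref;
  mat mlen = P.moment * dq;           // 6 x B (muscle shortening, m)
  mat mvel = P.moment * qd;           // 6 x B
  ln = -mlen; ln.each_col() /= P.lopt; ln += 1.0;
  vn = -mvel; vn.each_col() /= (P.lopt * P.vmax);
  x.set_size(2, B);
  for (int b = 0; b < B; ++b)
    fk_point(P, q(0, b), q(1, b), x(0, b), x(1, b));
}

// One plant transition for all columns. act_prev/u are 6 x B; writes the
// next-state columns and the step records (f, fl, fv).
static void plant_step_cols(const Plant& P, double bgain,
                            const mat& q, const mat& qd, const mat& act_prev,
                            const mat& ln, const mat& vn, const mat& u,
                            mat& q_next, mat& qd_next, mat& act_next,
                            mat& f, mat& fl, mat& fv, int step_for_error) {
  const int B = q.n_cols;
  const double k = P.dt / P.tau_act;
  act_next = (1.0 - k) * act_prev + k * u;
  fl = exp(-square((ln - 1.0) / P.fl_width));
  fv = 2.0 / (1.0 + exp(-P.fv_slope * vn));
  f = act_next % fl % fv;
  f.each_col() %= P.fmax;
  mat tau_m = P.moment.t() * f;  // 2 x B
  q_next.set_size(2, B); qd_next.set_size(2, B);
  for (int b = 0; b < B; ++b) {
    double q1 = q(0, b), q2 = q(1, b), qd1 = qd(0, b), qd2 = qd(1, b);
    double c2 = std::cos(q2), s2 = std::sin(q2);
    double M11 = P.I1 + P.I2 + P.m1 * P.lc1 * P.lc1
               + P.m2 * (P.L1 * P.L1 + P.lc2 * P.lc2 + 2.0 * P.L1 * P.lc2 * c2);
    double M12 = P.I2 + P.m2 * (P.lc2 * P.lc2 + P.L1 * P.lc2 * c2);
    double M22 = P.I2 + P.m2 * P.lc2 * P.lc2;
    double hco = P.m2 * P.L1 * P.lc2 * s2;
    double C1 = -hco * qd2 * (2.0 * qd1 + qd2);
    double C2 = hco * qd1 * qd1;
    // Curl field mapped to joint torques: J^T R90 J = det(J) R90 with
    // det(J) = L1 L2 sin(q2), so tau_ext = b L1 L2 s2 (-qd2, qd1).
    double dj = bgain * P.L1 * P.L2 * s2;
    double te1 = -dj * qd2, te2 = dj * qd1;
    double r1 = tau_m(0, b) + te1 + limit_torque(P, 0, q1)
              - C1 - P.joint_damping * qd1;
    double r2 = tau_m(1, b) + te2 + limit_torque(P, 1, q2)
              - C2 - P.joint_damping * qd2;
    double det = M11 * M22 - M12 * M12;
    double qdd1 = ( M22 * r1 - M12 * r2) / det;
    double qdd2 = (-M12 * r1 + M11 * r2) / det;
    double nqd1 = qd1 + P.dt * qdd1, nqd2 = qd2 + P.dt * qdd2;
    qd_next(0, b) = nqd1; qd_next(1, b) = nqd2;
    q_next(0, b) = q1 + P.dt * nqd1; q_next(1, b) = q2 + P.dt * nqd2;
    if (!std::isfinite(q_next(0, b)) || !std::isfinite(q_next(1, b)) ||
        !std::isfinite(nqd1) || !std::isfinite(nqd2))
      stop("non-finite joint state at simulation step %d", step_for_error);
  }
}

// Full closed-loop forward pass.  go: B-vector of 1-based go steps (0 = catch,
// i.e. the cue never arrives).  pert_state >= 0 adds pert_delta to the stored
// hidden state at that state index, before the output layer and the next GRU
// step read it.
static void forward_pass(const Params& par, const Plant& P,
                         const mat& q0, const mat& target,
                         const ivec& go, int T, double bgain,
                         int pert_state, const vec& pert_delta,
                         Rollout& W) {
  const int B = q0.n_cols, n = par.n;
  W.T = T; W.B = B; W.n = n;
  W.Q.zeros(2, B, T + 1); W.QD.zeros(2, B, T + 1);
  W.ACT.zeros(6, B, T + 1);
  W.LN.zeros(6, B, T + 1); W.VN.zeros(6, B, T + 1);
  W.X.zeros(2, B, T + 1);
  W.H.zeros(n, B, T + 1);
  W.Z.zeros(n, B, T); W.Rg.zeros(n, B, T); W.Nc.zeros(n, B, T);
  W.U.zeros(6, B, T); W.F.zeros(6, B, T);
  W.FL.zeros(6, B, T); W.FV.zeros(6, B, T);
  W.OBS.zeros(17, B, T);

  W.Q.slice(0) = q0;
  {
    mat ln, vn, x;
    state_geometry(P, W.Q.slice(0), W.QD.slice(0), ln, vn, x);
    W.LN.slice(0) = ln; W.VN.slice(0) = vn; W.X.slice(0) = x;
  }
  W.H.slice(0) = repmat(par.h0, 1, B);
  if (pert_state == 0) W.H.slice(0).each_col() += pert_delta;

  for (int t = 1; t <= T; ++t) {
    // observation (17 x B): target, delayed go + endpoint, delayed muscles
    int iv = std::max(t - VIS_DELAY, 0);
    int ip = std::max(t - PROP_DELAY, 0);
    mat obs(17, B);
    obs.rows(0, 1) = target;
    for (int b = 0; b < B; ++b)
      obs(2, b) = (go(b) > 0 && (t - VIS_DELAY) >= go(b)) ? 1.0 : 0.0;
    obs.rows(3, 4) = W.X.slice(iv);
    obs.rows(5, 10) = W.LN.slice(ip);
    obs.rows(11, 16) = W.VN.slice(ip);
    W.OBS.slice(t - 1) = obs;

    const mat& hprev = W.H.slice(t - 1);
    mat az = par.Wz * obs + par.Uz * hprev; az.each_col() += par.bz;
    mat ar = par.Wr * obs + par.Ur * hprev; ar.each_col() += par.br;
    mat z = sigmoid_mat(az), r = sigmoid_mat(ar);
    mat an = par.Wn * obs + par.Un * (r % hprev); an.each_col() += par.bn;
    mat nc = tanh(an);
    mat h = z % hprev + (1.0 - z) % nc;
    if (!h.is_finite()) stop("non-finite hidden state at step %d", t);
    if (pert_state == t) h.each_col() += pert_delta;
    W.Z.slice(t - 1) = z; W.Rg.slice(t - 1) = r; W.Nc.slice(t - 1) = nc;
    W.H.slice(t) = h;

    mat upre = par.Wout * h; upre.each_col() += par.bout;
    mat u = sigmoid_mat(upre);
    W.U.slice(t - 1) = u;

    mat qn, qdn, an2, f, fl, fv;
    plant_step_cols(P, bgain, W.Q.slice(t - 1), W.QD.slice(t - 1),
                    W.ACT.slice(t - 1), W.LN.slice(t - 1), W.VN.slice(t - 1),
                    u, qn, qdn, an2, f, fl, fv, t);
    W.Q.slice(t) = qn; W.QD.slice(t) = qdn; W.ACT.slice(t) = an2;
    W.F.slice(t - 1) = f; W.FL.slice(t - 1) = fl; W.FV.slice(t - 1) = fv;
    mat ln, vn, x;
    state_geometry(P, qn, qdn, ln, vn, x);
    W.LN.slice(t) = ln; W.VN.slice(t) = vn; W.X.slice(t) = x;
  }
}

// [[Rcpp::export]]
List cpp_rollout(List params, List plant, arma::mat q0, arma::mat target,
                 arma::ivec go, int T, double bgain,
                 int pert_state, arma::vec pert_delta) {
  Params par = params_from_list(params);
  Plant P = plant_from_list(plant);
  Rollout W;
  forward_pass(par, P, q0, target, go, T, bgain, pert_state, pert_delta, W);
  return List::create(
    Named("Q") = W.Q, Named("QD") = W.QD, Named("ACT") = W.ACT,
    Named("LN") = W.LN, Named("VN") = W.VN, Named("X") = W.X,
    Named("H") = W.H, Named("U") = W.U, Named("F") = W.F,
    Named("OBS") = W.OBS);
}

// [[Rcpp::export]]
List cpp_plant_step(List plant, arma::mat q, arma::mat qd, arma::mat act,
                    arma::mat u, double bgain) {
  Plant P = plant_from_list(plant);
  mat ln, vn, x;
  state_geometry(P, q, qd, ln, vn, x);
  mat qn, qdn, an, f, fl, fv;
  plant_step_cols(P, bgain, q, qd, act, ln, vn, u, qn, qdn, an, f, fl, fv, 1);
  mat ln2, vn2, x2;
  state_geometry(P, qn, qdn, ln2, vn2, x2);
  return List::create(Named("q") = qn, Named("qd") = qdn, Named("act") = an,
                      Named("f") = f, Named("ln") = ln2, Named("vn") = vn2,
                      Named("x") = x2);
}

// [[Rcpp::export]]
arma::mat cpp_forward_kinematics(List plant, arma::mat q) {
  Plant P = plant_from_list(plant);
  mat x(2, q.n_cols);
  for (uword b = 0; b < q.n_cols; ++b)
    fk_point(P, q(0, b), q(1, b), x(0, b), x(1, b));
  return x;
}

// [[Rcpp::export]]
arma::mat cpp_jacobian(List plant, double q1, double q2) {
  Plant P = plant_from_list(plant);
  mat22 J; jacobian(P, q1, q2, J);
  return mat(J);
}

// ---------------------------------------------------------------------------
// Composite rollout loss and reverse-mode BPTT.
//
// L = (1/(T B)) sum_{b,t} [ wp |x*-x|_1 + wj j'j + wm (f'f + wmd fd'fd)
//                           + wh (h'h + whd hd'hd) ]
// with j the third forward difference of endpoint position (edge-replicated)
// and fd/hd first forward differences (zero at t = 1).  Differences are per
// simulation step (not divided by dt) and muscle forces enter normalised by
// their maximum isometric force; with those conventions the four printed
// coefficients are balanced (in SI units the jerk term would exceed the
// position term by ~6 orders of magnitude and the optimum would be to stay
// still).

struct LossWeights { double wp, wj, wm, wmd, wh, whd; };

static LossWeights weights_from_list(const List& wl) {
  LossWeights w;
  w.wp = wl["position"]; w.wj = wl["jerk"];
  w.wm = wl["muscle"]; w.wmd = wl["muscle_deriv"];
  w.wh = wl["hidden"]; w.whd = wl["hidden_deriv"];
  return w;
}

// [[Rcpp::export]]
List cpp_loss_grad(List params, List plant, arma::mat q0, arma::mat target,
                   arma::ivec go, int T, double bgain, List weights,
                   bool want_grad) {
  Params par = params_from_list(params);
  Plant P = plant_from_list(plant);
  LossWeights w = weights_from_list(weights);
  Rollout W;
  vec nopert(par.n, fill::zeros);
  forward_pass(par, P, q0, target, go, T, bgain, -1, nopert, W);

  const int B = W.B, n = W.n;
  const double dt = P.dt;
  const double scale = 1.0 / (double(T) * double(B));

  // adjoint accumulators on recorded quantities
  cube GX(2, B, T + 1, fill::zeros);   // endpoint positions (states)
  cube GF(6, B, T, fill::zeros);       // muscle forces (steps)
  cube GH(n, B, T + 1, fill::zeros);   // hidden states
  double Lp = 0, Lj = 0, Lm = 0, Lh = 0;

  // desired positions: start before go (always, on catch), target after
  mat startx = W.X.slice(0);
  for (int t = 1; t <= T; ++t) {
    const mat& x = W.X.slice(t);
    for (int b = 0; b < B; ++b) {
      bool after = (go(b) > 0 && t >= go(b));
      double sx = after ? target(0, b) : startx(0, b);
      double sy = after ? target(1, b) : startx(1, b);
      double e0 = sx - x(0, b), e1 = sy - x(1, b);
      Lp += w.wp * (std::fabs(e0) + std::fabs(e1));
      GX(0, b, t) += -w.wp * ((e0 > 0) - (e0 < 0)) * scale;
      GX(1, b, t) += -w.wp * ((e1 > 0) - (e1 < 0)) * scale;
    }
  }
  // jerk: third difference over states 1..T with edge replication below 1
  const double cst[4] = {1.0, -3.0, 3.0, -1.0};
  for (int t = 1; t <= T; ++t) {
    int i0 = t, i1 = std::max(t - 1, 1), i2 = std::max(t - 2, 1),
        i3 = std::max(t - 3, 1);
    for (int b = 0; b < B; ++b) {
      for (int d = 0; d < 2; ++d) {
        double j = W.X(d, b, i0) - 3.0 * W.X(d, b, i1)
                   + 3.0 * W.X(d, b, i2) - W.X(d, b, i3);
        Lj += w.wj * j * j;
        double g = 2.0 * w.wj * j * scale;
        int idx[4] = {i0, i1, i2, i3};
        for (int k = 0; k < 4; ++k) GX(d, b, idx[k]) += g * cst[k];
      }
    }
  }
  // muscle term (forces normalised by fmax)
  for (int t = 1; t <= T; ++t) {
    mat fn = W.F.slice(t - 1); fn.each_col() /= P.fmax;
    Lm += w.wm * accu(fn % fn);
    mat g0 = 2.0 * w.wm * fn * scale; g0.each_col() /= P.fmax;
    GF.slice(t - 1) += g0;
    if (t >= 2) {
      mat fp = W.F.slice(t - 2); fp.each_col() /= P.fmax;
      mat fd = fn - fp;
      Lm += w.wm * w.wmd * accu(fd % fd);
      mat g = 2.0 * w.wm * w.wmd * fd * scale; g.each_col() /= P.fmax;
      GF.slice(t - 1) += g; GF.slice(t - 2) -= g;
    }
  }
  // hidden term
  for (int t = 1; t <= T; ++t) {
    const mat& h = W.H.slice(t);
    Lh += w.wh * accu(h % h);
    GH.slice(t) += 2.0 * w.wh * h * scale;
    if (t >= 2) {
      mat hd = h - W.H.slice(t - 1);
      Lh += w.wh * w.whd * accu(hd % hd);
      mat g = 2.0 * w.wh * w.whd * hd * scale;
      GH.slice(t) += g; GH.slice(t - 1) -= g;
    }
  }
  double total = (Lp + Lj + Lm + Lh) * scale;

  List out = List::create(
    Named("loss") = total,
    Named("terms") = Rcpp::NumericVector::create(
      Named("position") = Lp * scale, Named("jerk") = Lj * scale,
      Named("muscle") = Lm * scale, Named("hidden") = Lh * scale),
    Named("X") = W.X, Named("go") = go);
  if (!want_grad) return out;

  // ---- reverse pass ----
  cube AQ(2, B, T + 1, fill::zeros), AQD(2, B, T + 1, fill::zeros),
       AACT(6, B, T + 1, fill::zeros);
  mat gWz(size(par.Wz), fill::zeros), gWr(size(par.Wr), fill::zeros),
      gWn(size(par.Wn), fill::zeros);
  mat gUz(size(par.Uz), fill::zeros), gUr(size(par.Ur), fill::zeros),
      gUn(size(par.Un), fill::zeros);
  vec gbz(n, fill::zeros), gbr(n, fill::zeros), gbn(n, fill::zeros);
  mat gWout(size(par.Wout), fill::zeros);
  vec gbout(6, fill::zeros);

  const double k = dt / P.tau_act;
  for (int t = T; t >= 1; --t) {
    // endpoint-position adjoints at state t -> joint angles via J^T
    {
      const mat& gx = GX.slice(t);
      for (int b = 0; b < B; ++b) {
        mat22 J; jacobian(P, W.Q(0, b, t), W.Q(1, b, t), J);
        AQ(0, b, t) += J(0, 0) * gx(0, b) + J(1, 0) * gx(1, b);
        AQ(1, b, t) += J(0, 1) * gx(0, b) + J(1, 1) * gx(1, b);
      }
    }
    // ---- plant backward for step t ----
    mat gu(6, B, fill::zeros);
    {
      const mat& q = W.Q.slice(t - 1);   const mat& qd = W.QD.slice(t - 1);
      const mat& ln = W.LN.slice(t - 1); const mat& vn = W.VN.slice(t - 1);
      const mat& acn = W.ACT.slice(t);
      const mat& f = W.F.slice(t - 1);
      const mat& fl = W.FL.slice(t - 1); const mat& fv = W.FV.slice(t - 1);
      mat gf = GF.slice(t - 1);          // accumulates tau_m path below
      mat ga_next = AACT.slice(t);
      for (int b = 0; b < B; ++b) {
        double q1 = q(0, b), q2 = q(1, b), qd1 = qd(0, b), qd2 = qd(1, b);
        double c2 = std::cos(q2), s2 = std::sin(q2);
        double M11 = P.I1 + P.I2 + P.m1 * P.lc1 * P.lc1
                   + P.m2 * (P.L1 * P.L1 + P.lc2 * P.lc2
                             + 2.0 * P.L1 * P.lc2 * c2);
        double M12 = P.I2 + P.m2 * (P.lc2 * P.lc2 + P.L1 * P.lc2 * c2);
        double M22 = P.I2 + P.m2 * P.lc2 * P.lc2;
        double det = M11 * M22 - M12 * M12;
        double hco = P.m2 * P.L1 * P.lc2 * s2;
        double dhco = P.m2 * P.L1 * P.lc2 * c2;
        double dj = bgain * P.L1 * P.L2 * s2;
        // recompute rhs/qdd (cheap, avoids storing them)
        double C1 = -hco * qd2 * (2.0 * qd1 + qd2);
        double C2 = hco * qd1 * qd1;
        double r1 = 0, r2 = 0;
        {
          double tm1 = 0, tm2 = 0;
          for (int m = 0; m < 6; ++m) {
            tm1 += P.moment(m, 0) * f(m, b);
            tm2 += P.moment(m, 1) * f(m, b);
          }
          r1 = tm1 - dj * qd2 + limit_torque(P, 0, q1)
             - C1 - P.joint_damping * qd1;
          r2 = tm2 + dj * qd1 + limit_torque(P, 1, q2)
             - C2 - P.joint_damping * qd2;
        }
        double qdd1 = ( M22 * r1 - M12 * r2) / det;
        double qdd2 = (-M12 * r1 + M11 * r2) / det;

        // q' = q + dt qd'; qd' = qd + dt qdd
        double gq1 = AQ(0, b, t), gq2v = AQ(1, b, t);
        double gqd1 = AQD(0, b, t) + dt * gq1;
        double gqd2 = AQD(1, b, t) + dt * gq2v;
        double gqdd1 = dt * gqd1, gqdd2 = dt * gqd2;
        // grhs = M^-1 gqdd (M symmetric)
        double gr1 = ( M22 * gqdd1 - M12 * gqdd2) / det;
        double gr2 = (-M12 * gqdd1 + M11 * gqdd2) / det;
        // accumulate into previous-state adjoints
        double pgq1 = gq1, pgq2 = gq2v, pgqd1 = gqd1, pgqd2 = gqd2;
        // mass-matrix dependence on q2 (gM = -grhs qdd^T)
        double dM11 = -2.0 * P.m2 * P.L1 * P.lc2 * s2;
        double dM12 = -P.m2 * P.L1 * P.lc2 * s2;
        pgq2 += -(gr1 * qdd1 * dM11 + (gr1 * qdd2 + gr2 * qdd1) * dM12);
        // curl-field torque tau_ext = (-dj qd2, dj qd1), dj = b L1 L2 s2
        double ddj = bgain * P.L1 * P.L2 * c2;
        pgq2 += ddj * (-qd2 * gr1 + qd1 * gr2);
        pgqd2 += -dj * gr1; pgqd1 += dj * gr2;
        // soft joint limits
        pgq1 += gr1 * limit_torque_dq(P, 0, q1);
        pgq2 += gr2 * limit_torque_dq(P, 1, q2);
        // Coriolis/centripetal (rhs has -C)
        double dC1dq2 = -dhco * qd2 * (2.0 * qd1 + qd2);
        double dC2dq2 = dhco * qd1 * qd1;
        pgq2 += -(gr1 * dC1dq2 + gr2 * dC2dq2);
        pgqd1 += -(gr1 * (-2.0 * hco * qd2) + gr2 * (2.0 * hco * qd1));
        pgqd2 += -(gr1 * (-hco * (2.0 * qd1 + 2.0 * qd2)));
        // viscous joint damping
        pgqd1 += -P.joint_damping * gr1;
        pgqd2 += -P.joint_damping * gr2;
        // muscle torques: gf += moment * grhs
        for (int m = 0; m < 6; ++m)
          gf(m, b) += P.moment(m, 0) * gr1 + P.moment(m, 1) * gr2;
        // force model f = fmax act' fl fv
        for (int m = 0; m < 6; ++m) {
          double ga = ga_next(m, b) + gf(m, b) * P.fmax(m) * fl(m, b) * fv(m, b);
          double gfl = gf(m, b) * P.fmax(m) * acn(m, b) * fv(m, b);
          double gfv = gf(m, b) * P.fmax(m) * acn(m, b) * fl(m, b);
          double glnm = gfl * fl(m, b)
                        * (-2.0 * (ln(m, b) - 1.0) / (P.fl_width * P.fl_width));
          double gvnm = gfv * P.fv_slope * fv(m, b) * (1.0 - fv(m, b) / 2.0);
          // ln = 1 - moment (q - qref)/lopt ; vn = -moment qd/(lopt vmax)
          pgq1 += -P.moment(m, 0) * glnm / P.lopt(m);
          pgq2 += -P.moment(m, 1) * glnm / P.lopt(m);
          pgqd1 += -P.moment(m, 0) * gvnm / (P.lopt(m) * P.vmax);
          pgqd2 += -P.moment(m, 1) * gvnm / (P.lopt(m) * P.vmax);
          // act' = (1-k) act + k u
          AACT(m, b, t - 1) += (1.0 - k) * ga;
          gu(m, b) += k * ga;
        }
        AQ(0, b, t - 1) += pgq1; AQ(1, b, t - 1) += pgq2;
        AQD(0, b, t - 1) += pgqd1; AQD(1, b, t - 1) += pgqd2;
      }
    }
    // ---- output layer backward ----
    const mat& u = W.U.slice(t - 1);
    const mat& h = W.H.slice(t);
    mat gupre = gu % u % (1.0 - u);
    gWout += gupre * h.t();
    gbout += sum(gupre, 1);
    mat gh = GH.slice(t) + par.Wout.t() * gupre;
    // ---- GRU backward ----
    const mat& hprev = W.H.slice(t - 1);
    const mat& z = W.Z.slice(t - 1);
    const mat& r = W.Rg.slice(t - 1);
    const mat& nc = W.Nc.slice(t - 1);
    const mat& obs = W.OBS.slice(t - 1);
    mat gz = gh % (hprev - nc);
    mat gnc = gh % (1.0 - z);
    mat ghp = gh % z;
    mat gan = gnc % (1.0 - nc % nc);
    mat grh = par.Un.t() * gan;
    mat gr = grh % hprev;
    ghp += grh % r;
    mat gaz = gz % z % (1.0 - z);
    mat gar = gr % r % (1.0 - r);
    ghp += par.Uz.t() * gaz + par.Ur.t() * gar;
    mat gobs = par.Wz.t() * gaz + par.Wr.t() * gar + par.Wn.t() * gan;
    gWz += gaz * obs.t(); gWr += gar * obs.t(); gWn += gan * obs.t();
    gUz += gaz * hprev.t(); gUr += gar * hprev.t();
    gUn += gan * (r % hprev).t();
    gbz += sum(gaz, 1); gbr += sum(gar, 1); gbn += sum(gan, 1);
    GH.slice(t - 1) += ghp;
    // ---- scatter observation adjoints to delayed states ----
    int iv = std::max(t - VIS_DELAY, 0);
    int ip = std::max(t - PROP_DELAY, 0);
    if (iv >= 1) GX.slice(iv) += gobs.rows(3, 4);
    if (ip >= 1) {
      // ln rows 5..10, vn rows 11..16 of the observation
      for (int b = 0; b < B; ++b) {
        for (int m = 0; m < 6; ++m) {
          double gl = gobs(5 + m, b), gv = gobs(11 + m, b);
          AQ(0, b, ip) += -P.moment(m, 0) * gl / P.lopt(m);
          AQ(1, b, ip) += -P.moment(m, 1) * gl / P.lopt(m);
          AQD(0, b, ip) += -P.moment(m, 0) * gv / (P.lopt(m) * P.vmax);
          AQD(1, b, ip) += -P.moment(m, 1) * gv / (P.lopt(m) * P.vmax);
        }
      }
    }
  }
  vec gh0 = sum(GH.slice(0), 1);

  out["grads"] = List::create(
    Named("Wz") = gWz, Named("Wr") = gWr, Named("Wn") = gWn,
    Named("Uz") = gUz, Named("Ur") = gUr, Named("Un") = gUn,
    Named("bz") = gbz, Named("br") = gbr, Named("bn") = gbn,
    Named("Wout") = gWout, Named("bout") = gbout, Named("h0") = gh0);
  return out;
}
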