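// Fixed-step RK4 integrator for the two-link six-muscle arm coupled to an
// admittance-rendered manipulandum. The delayed proportional-derivative
// feedback is realized as a ring buffer over the muscle tracking errors
// recorded at step starts (zero-order hold within a step).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

struct SimPars {
  mat Jm;          // 6 x 2 moment arms
  vec K0, K1;      // 6 intrinsic stiffness parameters
  double dm_ratio; // muscle damping / stiffness (1/12)
  double gp, gd;   // reflex PD gains
  int nd;          // feedback delay [steps]
  vec pb;          // 3 base inertial parameters
  vec madm, dadm;  // admittance inertia / damping diagonals (incl. handle in madm)
  bool reflex_on;
};

static inline void arm_matrices(const vec &q, const vec &qd, const SimPars &P,
                                mat &Mq, mat &C) {
  double c2 = std::cos(q(1)), s2 = std::sin(q(1));
  Mq = {{P.pb(0) + P.pb(1) + 2 * P.pb(2) * c2, P.pb(1) + P.pb(2) * c2},
        {P.pb(1) + P.pb(2) * c2, P.pb(1)}};
  C = {{-P.pb(2) * s2 * qd(1), -P.pb(2) * s2 * (qd(0) + qd(1))},
       {P.pb(2) * s2 * qd(0), 0.0}};
}

// qdd of the coupled system for given state, inputs, and held feedback term
static inline vec coupled_qdd(const vec &q, const vec &qd,
                              const vec &qref, const vec &qdref,
                              const vec &aff, const vec &an, const vec &afb,
                              const vec &upert, const SimPars &P,
                              double l1, double l2, int *n_clamped) {
  vec e = P.Jm * (qref - q);
  vec ed = P.Jm * (qdref - qd);
  vec a = aff + afb + an;
  for (int i = 0; i < 6; ++i)
    if (a(i) < 0) { a(i) = 0; ++*n_clamped; }
  vec Km = P.K0 + P.K1 % a;
  vec m = a + (P.dm_ratio * Km) % ed + Km % e;
  for (int i = 0; i < 6; ++i)
    if (m(i) < 0) { m(i) = 0; ++*n_clamped; }
  vec tau_int = P.Jm.t() * m;

  double s1 = std::sin(q(0)), c1 = std::cos(q(0));
  double s12 = std::sin(q(0) + q(1)), c12 = std::cos(q(0) + q(1));
  mat J = {{-l1 * s1 - l2 * s12, -l2 * s12},
           {l1 * c1 + l2 * c12, l2 * c12}};
  double w1 = qd(0), w12 = qd(0) + qd(1);
  mat Jd = {{-l1 * c1 * w1 - l2 * c12 * w12, -l2 * c12 * w12},
            {-l1 * s1 * w1 - l2 * s12 * w12, -l2 * s12 * w12}};
  mat Mq, C;
  arm_matrices(q, qd, P, Mq, C);
  vec xd = J * qd;
  mat A = Mq + J.t() * (J.each_col() % P.madm);
  vec rhs = tau_int - C * qd +
    J.t() * (upert - P.dadm % xd - P.madm % (Jd * qd));
  return solve(A, rhs, solve_opts::fast);
}

// [[Rcpp::export]]
Rcpp::List sim_core_cpp(const arma::mat &q_ref, const arma::mat &qd_ref,
                        const arma::mat &aFF, const arma::mat &aN,
                        const arma::mat &upert,
                        const arma::mat &Jm, const arma::vec &K0,
                        const arma::vec &K1, double dm_ratio,
                        double gp, double gd, int nd, bool reflex_on,
                        const arma::vec &pb, const arma::vec &madm,
                        const arma::vec &dadm,
                        double l1, double l2, double dt,
                        const arma::vec &q0, const arma::vec &qd0) {
  int n = q_ref.n_rows;
  SimPars P{Jm, K0, K1, dm_ratio, gp, gd, nd, pb, madm, dadm, reflex_on};
  mat q(n, 2), qd(n, 2), qdd(n, 2), a_out(n, 6);
  mat e_hist(n, 6, fill::zeros), ed_hist(n, 6, fill::zeros);
  int n_clamped = 0;

  vec qc = q0, qdc = qd0;
  for (int i = 0; i < n; ++i) {
    q.row(i) = qc.t();
    qd.row(i) = qdc.t();
    vec e_now = Jm * (q_ref.row(i).t() - qc);
    vec ed_now = Jm * (qd_ref.row(i).t() - qdc);
    e_hist.row(i) = e_now.t();
    ed_hist.row(i) = ed_now.t();
    int idel = i - nd; if (idel < 0) idel = 0;
    vec afb(6, fill::zeros);
    if (reflex_on) {
      afb = gp * e_hist.row(idel).t() + gd * ed_hist.row(idel).t();
      for (int k = 0; k < 6; ++k) if (afb(k) < 0) afb(k) = 0;
    }
    {
      vec a = aFF.row(i).t() + afb + aN.row(i).t();
      for (int k = 0; k < 6; ++k) if (a(k) < 0) a(k) = 0;
      a_out.row(i) = a.t();
    }
    vec k1v = coupled_qdd(qc, qdc, q_ref.row(i).t(), qd_ref.row(i).t(),
                          aFF.row(i).t(), aN.row(i).t(), afb,
                          upert.row(i).t(), P, l1, l2, &n_clamped);
    qdd.row(i) = k1v.t();
    if (i == n - 1) break;

    int j = i + 1;
    vec qref_h = 0.5 * (q_ref.row(i) + q_ref.row(j)).t();
    vec qdref_h = 0.5 * (qd_ref.row(i) + qd_ref.row(j)).t();
    vec aff_h = 0.5 * (aFF.row(i) + aFF.row(j)).t();
    vec an_h = 0.5 * (aN.row(i) + aN.row(j)).t();
    vec up_h = 0.5 * (upert.row(i) + upert.row(j)).t();

    // RK4 on y = (q, qd)
    vec q1 = qc, qd1 = qdc, acc1 = k1v;
    vec q2 = qc + 0.5 * dt * qd1, qd2 = qdc + 0.5 * dt * acc1;
    vec acc2 = coupled_qdd(q2, qd2, qref_h, qdref_h, aff_h, an_h, afb, up_h,
                           P, l1, l2, &n_clamped);
    vec q3 = qc + 0.5 * dt * qd2, qd3 = qdc + 0.5 * dt * acc2;
    vec acc3 = coupled_qdd(q3, qd3, qref_h, qdref_h, aff_h, an_h, afb, up_h,
                           P, l1, l2, &n_clamped);
    vec q4 = qc + dt * qd3, qd4 = qdc + dt * acc3;
    vec acc4 = coupled_qdd(q4, qd4, q_ref.row(j).t(), qd_ref.row(j).t(),
                           aFF.row(j).t(), aN.row(j).t(), afb,
                           upert.row(j).t(), P, l1, l2, &n_clamped);
    qc = qc + dt / 6.0 * (qd1 + 2 * qd2 + 2 * qd3 + qd4);
    qdc = qdc + dt / 6.0 * (acc1 + 2 * acc2 + 2 * acc3 + acc4);
    if (!qc.is_finite() || !qdc.is_finite() || norm(qdc) > 1e3) {
      Rcpp::stop("sim_core: numerical instability at step %d (t = %.4f s)",
                 i + 1, (i + 1) * dt);
    }
  }
  return Rcpp::List::create(Rcpp::Named("q") = q,
                            Rcpp::Named("qd") = qd,
                            Rcpp::Named("qdd") = qdd,
                            Rcpp::Named("a") = a_out,
                            Rcpp::Named("n_clamped") = n_clamped);
}
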