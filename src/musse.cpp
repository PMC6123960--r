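// State-dependent diversification (MuSSE) likelihood core.
//
// Along every branch, from the tip end towards the root, we integrate the
// coupled extinction/data ODEs
//   dE_i/dt = mu_i - (lam_i + mu_i + sum_{j!=i} q_ij) E_i
//             + lam_i E_i^2 + sum_{j!=i} q_ij E_j
//   dD_i/dt = -(lam_i + mu_i + sum_{j!=i} q_ij) D_i
//             + sum_{j!=i} q_ij D_j + 2 lam_i E_i D_i
// with tip conditions D_i(0) = f * 1[i in observed set], E_i(0) = 1 - f.
// Internal nodes multiply the two daughter D vectors and one speciation
// rate.  The integrator is an adaptive Cash-Karp Runge-Kutta (4th/5th
// order) with per-component absolute/relative error control.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Musse {
  int k;
  std::vector<double> lam, mu, qrow;
  std::vector<double> Q;  // row-major k x k

  void deriv(const std::vector<double>& y, std::vector<double>& dy) const {
    for (int i = 0; i < k; ++i) {
      double qE = 0.0, qD = 0.0;
      for (int j = 0; j < k; ++j) {
        if (j == i) continue;
        qE += Q[i * k + j] * y[j];
        qD += Q[i * k + j] * y[k + j];
      }
      const double tot = lam[i] + mu[i] + qrow[i];
      dy[i] = mu[i] - tot * y[i] + lam[i] * y[i] * y[i] + qE;
      dy[k + i] = -tot * y[k + i] + qD + 2.0 * lam[i] * y[i] * y[k + i];
    }
  }
};

// scratch space reused across steps to avoid per-step allocation
struct Scratch {
  std::vector<double> ak2, ak3, ak4, ak5, ak6, ytmp, dydt, yout;
  explicit Scratch(int n)
      : ak2(n), ak3(n), ak4(n), ak5(n), ak6(n), ytmp(n), dydt(n), yout(n) {}
};

// one Cash-Karp step; returns max scaled error
double ck_step(const Musse& M, const std::vector<double>& y, double h,
               Scratch& w, double atol, double rtol) {
  static const double b21 = 1.0 / 5.0;
  static const double b31 = 3.0 / 40.0, b32 = 9.0 / 40.0;
  static const double b41 = 3.0 / 10.0, b42 = -9.0 / 10.0, b43 = 6.0 / 5.0;
  static const double b51 = -11.0 / 54.0, b52 = 5.0 / 2.0,
                      b53 = -70.0 / 27.0, b54 = 35.0 / 27.0;
  static const double b61 = 1631.0 / 55296.0, b62 = 175.0 / 512.0,
                      b63 = 575.0 / 13824.0, b64 = 44275.0 / 110592.0,
                      b65 = 253.0 / 4096.0;
  static const double c1 = 37.0 / 378.0, c3 = 250.0 / 621.0,
                      c4 = 125.0 / 594.0, c6 = 512.0 / 1771.0;
  static const double dc1 = c1 - 2825.0 / 27648.0,
                      dc3 = c3 - 18575.0 / 48384.0,
                      dc4 = c4 - 13525.0 / 55296.0,
                      dc5 = -277.0 / 14336.0, dc6 = c6 - 0.25;
  const int n = (int)y.size();
  std::vector<double>& ak2 = w.ak2;
  std::vector<double>& ak3 = w.ak3;
  std::vector<double>& ak4 = w.ak4;
  std::vector<double>& ak5 = w.ak5;
  std::vector<double>& ak6 = w.ak6;
  std::vector<double>& ytmp = w.ytmp;
  const std::vector<double>& dydt = w.dydt;

  for (int i = 0; i < n; ++i) ytmp[i] = y[i] + h * b21 * dydt[i];
  M.deriv(ytmp, ak2);
  for (int i = 0; i < n; ++i)
    ytmp[i] = y[i] + h * (b31 * dydt[i] + b32 * ak2[i]);
  M.deriv(ytmp, ak3);
  for (int i = 0; i < n; ++i)
    ytmp[i] = y[i] + h * (b41 * dydt[i] + b42 * ak2[i] + b43 * ak3[i]);
  M.deriv(ytmp, ak4);
  for (int i = 0; i < n; ++i)
    ytmp[i] = y[i] + h * (b51 * dydt[i] + b52 * ak2[i] + b53 * ak3[i] +
                          b54 * ak4[i]);
  M.deriv(ytmp, ak5);
  for (int i = 0; i < n; ++i)
    ytmp[i] = y[i] + h * (b61 * dydt[i] + b62 * ak2[i] + b63 * ak3[i] +
                          b64 * ak4[i] + b65 * ak5[i]);
  M.deriv(ytmp, ak6);

  double errmax = 0.0;
  for (int i = 0; i < n; ++i) {
    w.yout[i] = y[i] + h * (c1 * dydt[i] + c3 * ak3[i] + c4 * ak4[i] +
                            c6 * ak6[i]);
    const double yerr = h * (dc1 * dydt[i] + dc3 * ak3[i] + dc4 * ak4[i] +
                             dc5 * ak5[i] + dc6 * ak6[i]);
    const double sc = atol + rtol * std::max(std::fabs(y[i]),
                                             std::fabs(w.yout[i]));
    errmax = std::max(errmax, std::fabs(yerr) / sc);
  }
  return errmax;
}

void integrate_branch(const Musse& M, std::vector<double>& y, double t_len,
                      double atol, double rtol, int edge_id, Scratch& w) {
  if (t_len <= 0.0) return;
  double t = 0.0;
  double h = t_len;
  const double hmin = t_len * 1e-12;
  int steps = 0;
  while (t < t_len) {
    if (++steps > 1000000)
      stop("ODE integration failure on edge %d: step budget exhausted",
           edge_id);
    if (t + h > t_len) h = t_len - t;
    M.deriv(y, w.dydt);
    double err = ck_step(M, y, h, w, atol, rtol);
    if (err <= 1.0) {
      t += h;
      y = w.yout;
      // sanity and gentle clipping of roundoff-level violations
      for (int i = 0; i < M.k; ++i) {
        if (y[i] < -1e-6 || y[i] > 1.0 + 1e-6)
          stop("ODE integration failure on edge %d: E out of [0,1]",
               edge_id);
        if (y[i] < 0.0) y[i] = 0.0;
        if (y[i] > 1.0) y[i] = 1.0;
        if (y[M.k + i] < 0.0) {
          if (y[M.k + i] < -1e-8)
            stop("ODE integration failure on edge %d: negative D", edge_id);
          y[M.k + i] = 0.0;
        }
      }
      double grow = 0.9 * std::pow(std::max(err, 1e-10), -0.2);
      h *= std::min(grow, 5.0);
    } else {
      h *= std::max(0.9 * std::pow(err, -0.25), 0.1);
      if (h < hmin)
        stop("ODE integration failure on edge %d: step size underflow",
             edge_id);
    }
  }
}

}  // namespace

// [[Rcpp::export]]
List musse_loglik_cpp(IntegerMatrix edge, NumericVector edge_length,
                      int ntip, int nnode, NumericMatrix tipD, double E0,
                      NumericVector lam, NumericVector mu, NumericMatrix Q,
                      int root_mode, NumericVector root_p, bool cond_surv,
                      double atol, double rtol) {
  const int k = tipD.nrow();
  const int ntot = ntip + nnode;
  Musse M;
  M.k = k;
  M.lam.assign(lam.begin(), lam.end());
  M.mu.assign(mu.begin(), mu.end());
  M.Q.resize(k * k);
  M.qrow.assign(k, 0.0);
  for (int i = 0; i < k; ++i)
    for (int j = 0; j < k; ++j) {
      M.Q[i * k + j] = Q(i, j);
      if (j != i) M.qrow[i] += Q(i, j);
    }

  // per-node accumulated D products, E storage and child counts
  std::vector<std::vector<double> > accD(ntot, std::vector<double>(k, 1.0));
  std::vector<std::vector<double> > nodeE(ntot, std::vector<double>(k, 0.0));
  std::vector<int> nkids(ntot, 0);
  double logcomp = 0.0;

  std::vector<double> y(2 * k);
  Scratch w(2 * k);
  const int ne = edge.nrow();
  for (int e = 0; e < ne; ++e) {
    const int ch = edge(e, 1) - 1;  // 0-based
    const int pa = edge(e, 0) - 1;
    // initial conditions at the child end
    if (ch < ntip) {
      for (int i = 0; i < k; ++i) {
        y[i] = E0;
        y[k + i] = tipD(i, ch);
      }
    } else {
      if (nkids[ch] != 2)
        stop("internal node %d is not binary", ch + 1);
      double s = 0.0;
      for (int i = 0; i < k; ++i) {
        double d = accD[ch][i] * M.lam[i];
        y[k + i] = d;
        s += d;
        y[i] = nodeE[ch][i];
      }
      if (!(s > 0.0) || !R_finite(s))
        return List::create(Named("loglik") = R_NegInf);
      for (int i = 0; i < k; ++i) y[k + i] /= s;
      logcomp += std::log(s);
    }
    integrate_branch(M, y, edge_length[e], atol, rtol, e + 1, w);
    for (int i = 0; i < k; ++i) {
      accD[pa][i] *= y[k + i];
      if (nkids[pa] == 0) nodeE[pa][i] = y[i];
    }
    nkids[pa] += 1;
  }

  // root node (ape convention: ntip + 1, i.e. index ntip)
  const int root = ntip;
  if (nkids[root] != 2) stop("root is not binary");
  std::vector<double> D(k), E(k);
  double s = 0.0;
  for (int i = 0; i < k; ++i) {
    D[i] = accD[root][i] * M.lam[i];
    E[i] = nodeE[root][i];
    s += D[i];
  }
  if (!(s > 0.0) || !R_finite(s))
    return List::create(Named("loglik") = R_NegInf);
  for (int i = 0; i < k; ++i) D[i] /= s;
  logcomp += std::log(s);

  std::vector<double> Dc(D);
  if (cond_surv) {
    for (int i = 0; i < k; ++i) {
      const double denom = M.lam[i] * (1.0 - E[i]) * (1.0 - E[i]);
      if (denom <= 0.0)
        stop("survival conditioning undefined: lam*(1-E)^2 is zero");
      Dc[i] = D[i] / denom;
    }
  }
  double val = 0.0;
  if (root_mode == 0) {        // likelihood-weighted (FitzJohn)
    double sw = 0.0;
    for (int i = 0; i < k; ++i) sw += D[i];
    for (int i = 0; i < k; ++i) val += (D[i] / sw) * Dc[i];
  } else if (root_mode == 1) { // flat
    for (int i = 0; i < k; ++i) val += Dc[i] / k;
  } else {                     // given weights
    for (int i = 0; i < k; ++i) val += root_p[i] * Dc[i];
  }
  const double loglik = std::log(val) + logcomp;
  return List::create(Named("loglik") = loglik,
                      Named("root_D") = NumericVector(D.begin(), D.end()),
                      Named("root_E") = NumericVector(E.begin(), E.end()));
}
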