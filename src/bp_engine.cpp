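// Belief-propagation sweep engine for a single target row of the interaction
// matrix. Rows decouple at steady state, so the R layer calls this once per
// inferable node. Factors rho^mu(w_ij) are kept in log space; the cavity
// field over non-cavity sources is summarised by its Gaussian mean/variance
// and the local update integral is evaluated by Gauss-Hermite quadrature.
//
// Layout: logF is an S x M x K array (sources x conditions x grid values),
// index(t, mu, k) = t + S*(mu + M*k). Ssum is S x K with the per-source sum
// of log factors over all conditions; it is rebuilt from logF at the start
// of every sweep to stop incremental floating-point drift.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double sqr(double x) { return x * x; }

static inline int idx3(int t, int mu, int k, int S, int M) {
  return t + S * (mu + M * k);
}

static void rebuild_ssum(const std::vector<double>& logF,
                         std::vector<double>& Ssum,
                         int S, int M, int K) {
  std::fill(Ssum.begin(), Ssum.end(), 0.0);
  for (int k = 0; k < K; ++k)
    for (int mu = 0; mu < M; ++mu)
      for (int t = 0; t < S; ++t)
        Ssum[t + S * k] += logF[idx3(t, mu, k, S, M)];
}

// Moments of the cavity marginal of source t (prior x product of factors
// excluding condition mu); fixed sources are point masses.
static void cavity_moments(int t, int mu,
                           const std::vector<double>& logF,
                           const std::vector<double>& Ssum,
                           const std::vector<double>& prior,
                           int S, int M, int K,
                           const NumericVector& omega,
                           const std::vector<int>& fixed,
                           const std::vector<double>& fixed_val,
                           std::vector<double>& q,
                           double& m, double& v) {
  if (fixed[t]) { m = fixed_val[t]; v = 0.0; return; }
  double qmax = R_NegInf;
  for (int k = 0; k < K; ++k) {
    q[k] = Ssum[t + S * k] - logF[idx3(t, mu, k, S, M)] + prior[k];
    if (q[k] > qmax) qmax = q[k];
  }
  double Z = 0.0, m1 = 0.0, m2 = 0.0;
  for (int k = 0; k < K; ++k) {
    double p = std::exp(q[k] - qmax);
    Z += p;
    m1 += p * omega[k];
    m2 += p * omega[k] * omega[k];
  }
  m = m1 / Z;
  v = m2 / Z - m * m;
  if (v < 0.0) v = 0.0;
}

// One cavity update: new (normalized, optionally damped) log factor for
// cavity source s in condition mu. When apply, Ssum and logF are updated.
static void update_one(int s, int mu,
                       std::vector<double>& logF,
                       std::vector<double>& Ssum,
                       const std::vector<double>& prior,
                       const NumericMatrix& Xs,
                       const NumericVector& xi,
                       const NumericVector& ui,
                       const NumericVector& omega,
                       const std::vector<int>& fixed,
                       const std::vector<double>& fixed_val,
                       double beta, double damping,
                       const NumericVector& ghx,
                       const NumericVector& ghw,
                       std::vector<double>& q,
                       std::vector<double>& a,
                       std::vector<double>& Lnew,
                       bool apply) {
  const int S = Xs.nrow(), M = Xs.ncol(), K = omega.size();
  const int Q = ghx.size();
  double mh = 0.0, vh = 0.0, m, v;
  for (int t = 0; t < S; ++t) {
    if (t == s) continue;
    cavity_moments(t, mu, logF, Ssum, prior, S, M, K, omega,
                   fixed, fixed_val, q, m, v);
    mh += m * Xs(t, mu);
    vh += v * Xs(t, mu) * Xs(t, mu);
  }
  const double xs = Xs(s, mu), xt = xi[mu], u = ui[mu];
  if (vh < 1e-14) {
    for (int k = 0; k < K; ++k)
      Lnew[k] = -beta * sqr(xt - std::tanh(mh + omega[k] * xs + u));
  } else {
    const double sv = std::sqrt(2.0 * vh);
    for (int k = 0; k < K; ++k) {
      double amax = R_NegInf;
      for (int qq = 0; qq < Q; ++qq) {
        a[qq] = -beta * sqr(xt - std::tanh(mh + sv * ghx[qq] +
                                           omega[k] * xs + u));
        if (a[qq] > amax) amax = a[qq];
      }
      double sum = 0.0;
      for (int qq = 0; qq < Q; ++qq) sum += ghw[qq] * std::exp(a[qq] - amax);
      Lnew[k] = std::log(sum) + amax;   // 1/sqrt(pi) drops in normalization
    }
  }
  double lmax = R_NegInf;
  for (int k = 0; k < K; ++k) if (Lnew[k] > lmax) lmax = Lnew[k];
  double lse = 0.0;
  for (int k = 0; k < K; ++k) lse += std::exp(Lnew[k] - lmax);
  lse = std::log(lse) + lmax;
  for (int k = 0; k < K; ++k) Lnew[k] -= lse;
  if (damping > 0.0) {
    for (int k = 0; k < K; ++k) {
      double pnew = (1.0 - damping) * std::exp(Lnew[k]) +
                    damping * std::exp(logF[idx3(s, mu, k, S, M)]);
      Lnew[k] = std::log(pnew);
    }
  }
  if (apply) {
    for (int k = 0; k < K; ++k) {
      const int id = idx3(s, mu, k, S, M);
      Ssum[s + S * k] += Lnew[k] - logF[id];
      logF[id] = Lnew[k];
    }
  }
}

// Final marginals P(w) ~ exp(lambda delta) prod_mu rho^mu(w); fixed sources
// get a point mass at their fixed grid value.
static void marginals(const std::vector<double>& Ssum,
                      const std::vector<double>& prior,
                      int S, int K,
                      const NumericVector& omega,
                      const std::vector<int>& fixed,
                      const std::vector<double>& fixed_val,
                      std::vector<double>& P) {
  for (int t = 0; t < S; ++t) {
    if (fixed[t]) {
      int kbest = 0;
      double dbest = R_PosInf;
      for (int k = 0; k < K; ++k) {
        double d = std::fabs(omega[k] - fixed_val[t]);
        if (d < dbest) { dbest = d; kbest = k; }
      }
      for (int k = 0; k < K; ++k) P[t + S * k] = (k == kbest) ? 1.0 : 0.0;
    } else {
      double qmax = R_NegInf;
      for (int k = 0; k < K; ++k) {
        double z = Ssum[t + S * k] + prior[k];
        if (z > qmax) qmax = z;
      }
      double Z = 0.0;
      for (int k = 0; k < K; ++k) {
        double p = std::exp(Ssum[t + S * k] + prior[k] - qmax);
        P[t + S * k] = p;
        Z += p;
      }
      for (int k = 0; k < K; ++k) P[t + S * k] /= Z;
    }
  }
}

// [[Rcpp::export]]
List cpp_bp_row(NumericMatrix Xs, NumericVector xi, NumericVector ui,
                NumericVector omega, NumericVector logF_in,
                IntegerVector fixed_in, NumericVector fixed_val_in,
                double beta, double lambda, double tol, int max_sweeps,
                double damping, NumericVector ghx, NumericVector ghw,
                Function sampler) {
  const int S = Xs.nrow(), M = Xs.ncol(), K = omega.size();
  if ((int) logF_in.size() != S * M * K) stop("logF has wrong length");
  if ((int) xi.size() != M || (int) ui.size() != M) stop("xi/ui length mismatch");
  std::vector<double> logF(logF_in.begin(), logF_in.end());
  std::vector<int> fixed(fixed_in.begin(), fixed_in.end());
  std::vector<double> fixed_val(fixed_val_in.begin(), fixed_val_in.end());
  std::vector<double> prior(K);
  for (int k = 0; k < K; ++k) prior[k] = (omega[k] == 0.0) ? lambda : 0.0;
  std::vector<double> Ssum(S * K), q(K), a(ghx.size()), Lnew(K);
  std::vector<double> P(S * K), Pprev(S * K);

  std::vector<int> free_src;
  for (int t = 0; t < S; ++t) if (!fixed[t]) free_src.push_back(t);
  const int nfree = free_src.size();
  const int npairs = nfree * M;

  rebuild_ssum(logF, Ssum, S, M, K);
  marginals(Ssum, prior, S, K, omega, fixed, fixed_val, Pprev);

  bool converged = (npairs == 0);
  int sweeps = 0;
  double delta = 0.0;
  for (int sweep = 0; sweep < max_sweeps && !converged; ++sweep) {
    rebuild_ssum(logF, Ssum, S, M, K);
    IntegerVector perm = sampler(npairs);
    for (int p = 0; p < npairs; ++p) {
      const int pair = perm[p] - 1;
      const int s = free_src[pair % nfree];
      const int mu = pair / nfree;
      update_one(s, mu, logF, Ssum, prior, Xs, xi, ui, omega,
                 fixed, fixed_val, beta, damping, ghx, ghw,
                 q, a, Lnew, true);
    }
    marginals(Ssum, prior, S, K, omega, fixed, fixed_val, P);
    delta = 0.0;
    for (int i = 0; i < S * K; ++i) {
      double d = std::fabs(P[i] - Pprev[i]);
      if (d > delta) delta = d;
    }
    Pprev = P;
    sweeps = sweep + 1;
    if (delta < tol) converged = true;
  }
  if (npairs == 0)
    marginals(Ssum, prior, S, K, omega, fixed, fixed_val, Pprev);

  NumericMatrix Pout(S, K);
  for (int t = 0; t < S; ++t)
    for (int k = 0; k < K; ++k) Pout(t, k) = Pprev[t + S * k];
  NumericVector logF_out(logF.begin(), logF.end());
  logF_out.attr("dim") = IntegerVector::create(S, M, K);
  return List::create(_["logF"] = logF_out, _["marg"] = Pout,
                      _["sweeps"] = sweeps, _["converged"] = converged,
                      _["delta"] = delta);
}

// Single cavity update (does not mutate state); returns the new factor as a
// probability vector. s and mu are 1-based.
// [[Rcpp::export]]
NumericVector cpp_bp_update(NumericMatrix Xs, NumericVector xi, NumericVector ui,
                            NumericVector omega, NumericVector logF_in,
                            IntegerVector fixed_in, NumericVector fixed_val_in,
                            int s, int mu, double beta, double lambda,
                            double damping, NumericVector ghx, NumericVector ghw) {
  const int S = Xs.nrow(), M = Xs.ncol(), K = omega.size();
  if ((int) logF_in.size() != S * M * K) stop("logF has wrong length");
  if (s < 1 || s > S || mu < 1 || mu > M) stop("s or mu out of range");
  std::vector<double> logF(logF_in.begin(), logF_in.end());
  std::vector<int> fixed(fixed_in.begin(), fixed_in.end());
  std::vector<double> fixed_val(fixed_val_in.begin(), fixed_val_in.end());
  std::vector<double> prior(K);
  for (int k = 0; k < K; ++k) prior[k] = (omega[k] == 0.0) ? lambda : 0.0;
  std::vector<double> Ssum(S * K), q(K), a(ghx.size()), Lnew(K);
  rebuild_ssum(logF, Ssum, S, M, K);
  update_one(s - 1, mu - 1, logF, Ssum, prior, Xs, xi, ui, omega,
             fixed, fixed_val, beta, damping, ghx, ghw, q, a, Lnew, false);
  NumericVector out(K);
  for (int k = 0; k < K; ++k) out[k] = std::exp(Lnew[k]);
  return out;
}
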