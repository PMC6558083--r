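#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Multi-class HBD HMM core. States 1..K (columns of emis); the transition
// between adjacent markers at genetic distance d Morgans is
//   T[k,j] = exp(-R_k d) * 1[k==j] + (1 - exp(-R_k d)) * pi_j
// i.e. the current segment survives with probability exp(-R_k d), otherwise a
// new segment class is drawn from the mixing proportions pi. The stay/switch
// decomposition makes forward and backward sweeps O(K) per marker, and the
// survival probabilities exp(-R_k d_t) depend only on the map, so they are
// precomputed once and reused across every EM iteration.

struct Workspace {
  std::vector<double> alpha;  // T x K scaled forward variables (row-major)
  std::vector<double> cvec;   // per-site scaling constants
};

// Forward-backward over one chain. emis/gamma are column-major R matrices of
// nrow Ttot; the chain occupies rows [t0, t0+T). surv is row-major (T-1) x K
// with surv[t*K + k] = exp(-R_k * d between markers t and t+1 of the chain).
static double fb_chain(const double* emis, int Ttot, int t0, int T, int K,
                       const double* surv, const double* pi, double* gamma,
                       double* entries, Workspace& ws) {
  ws.alpha.resize((size_t)T * K);
  ws.cvec.resize(T);
  double* alpha = ws.alpha.data();
  double* cvec = ws.cvec.data();

  double c0 = 0.0;
  for (int k = 0; k < K; ++k) {
    double a = pi[k] * emis[(size_t)k * Ttot + t0];
    alpha[k] = a;
    c0 += a;
  }
  if (c0 <= 0.0)
    stop("zero likelihood at chain marker 1: observation impossible under model");
  for (int k = 0; k < K; ++k) alpha[k] /= c0;
  cvec[0] = c0;
  double loglik = std::log(c0);

  for (int t = 1; t < T; ++t) {
    const double* s = surv + (size_t)(t - 1) * K;
    const double* ap = alpha + (size_t)(t - 1) * K;
    double* an = alpha + (size_t)t * K;
    double A = 0.0;  // forward mass whose segment ends at this step
    for (int k = 0; k < K; ++k) A += ap[k] * (1.0 - s[k]);
    double ct = 0.0;
    for (int j = 0; j < K; ++j) {
      double a = (s[j] * ap[j] + A * pi[j]) * emis[(size_t)j * Ttot + t0 + t];
      an[j] = a;
      ct += a;
    }
    if (ct <= 0.0)
      stop("zero likelihood at chain marker %d: observation impossible under model",
           t + 1);
    for (int j = 0; j < K; ++j) an[j] /= ct;
    cvec[t] = ct;
    loglik += std::log(ct);
  }

  // Backward sweep; with this scaling gamma_t = alpha_hat_t * beta_hat_t.
  std::vector<double> beta(K, 1.0), beta_new(K);
  {
    const double* ap = alpha + (size_t)(T - 1) * K;
    double rs = 0.0;
    for (int k = 0; k < K; ++k) rs += ap[k];
    for (int k = 0; k < K; ++k)
      gamma[(size_t)k * Ttot + t0 + T - 1] = ap[k] / rs;
  }
  for (int t = T - 2; t >= 0; --t) {
    const double* s = surv + (size_t)t * K;
    const double* ap = alpha + (size_t)t * K;
    double B = 0.0;  // sum_j pi_j e_{t+1}(j) beta_{t+1}(j)
    for (int j = 0; j < K; ++j)
      B += pi[j] * emis[(size_t)j * Ttot + t0 + t + 1] * beta[j];
    double A = 0.0, inv_c = 1.0 / cvec[t + 1];
    for (int k = 0; k < K; ++k) {
      beta_new[k] = (s[k] * emis[(size_t)k * Ttot + t0 + t + 1] * beta[k] +
                     (1.0 - s[k]) * B) * inv_c;
      A += ap[k] * (1.0 - s[k]);
    }
    // expected switch events landing in class j between markers t and t+1
    // (the switch component of xi_t(k,j) summed over k)
    for (int j = 0; j < K; ++j)
      entries[j] += A * pi[j] * emis[(size_t)j * Ttot + t0 + t + 1] * beta[j] *
                    inv_c;
    double rs = 0.0;
    for (int k = 0; k < K; ++k) {
      beta[k] = beta_new[k];
      double g = ap[k] * beta[k];
      gamma[(size_t)k * Ttot + t0 + t] = g;
      rs += g;
    }
    // renormalise the row against accumulated rounding
    for (int k = 0; k < K; ++k) gamma[(size_t)k * Ttot + t0 + t] /= rs;
  }
  // the initial segment of the chain counts as an entry into its class
  for (int k = 0; k < K; ++k) entries[k] += gamma[(size_t)k * Ttot + t0];
  return loglik;
}

// precompute survival probabilities exp(-R_k d_t), row-major (sum(T_c - 1)) x K
static std::vector<double> survival_table(const NumericVector& d,
                                          const NumericVector& rates) {
  const int K = rates.size();
  std::vector<double> surv((size_t)d.size() * K);
  for (int t = 0; t < d.size(); ++t)
    for (int k = 0; k < K; ++k)
      surv[(size_t)t * K + k] = std::exp(-rates[k] * d[t]);
  return surv;
}

// One E-step over all chains. `d` concatenates the chain-local gap vectors
// (length T_c - 1 each, in chain order); surv is its precomputed table.
static double estep_all(const double* emis, int Ttot, int K,
                        const IntegerVector& chain_lengths,
                        const std::vector<double>& surv, const double* pi,
                        double* gamma, double* entries, Workspace& ws) {
  double loglik = 0.0;
  int t0 = 0, d0 = 0;
  for (int c = 0; c < chain_lengths.size(); ++c) {
    int T = chain_lengths[c];
    loglik += fb_chain(emis, Ttot, t0, T, K, surv.data() + (size_t)d0 * K, pi,
                       gamma, entries, ws);
    t0 += T;
    d0 += T - 1;
  }
  return loglik;
}

// [[Rcpp::export]]
List cpp_forward_backward(NumericMatrix emis, NumericVector d,
                          IntegerVector chain_lengths, NumericVector rates,
                          NumericVector pi) {
  const int K = emis.ncol(), Ttot = emis.nrow();
  NumericMatrix gamma(Ttot, K);
  NumericVector entries(K);
  std::vector<double> surv = survival_table(d, rates);
  Workspace ws;
  double loglik = estep_all(emis.begin(), Ttot, K, chain_lengths, surv,
                            pi.begin(), gamma.begin(), entries.begin(), ws);
  return List::create(_["gamma"] = gamma, _["loglik"] = loglik,
                      _["entries"] = entries);
}

// EM with rates fixed: E-step forward-backward, M-step pi_k proportional to
// the expected number of segment entries into class k (initial state plus
// switch events, summed over chromosome chains). Stops when the
// log-likelihood gain drops below tol or at maxit; the returned posteriors
// come from the E-step under the accepted pi.
// [[Rcpp::export]]
List cpp_fit_em(NumericMatrix emis, NumericVector d, IntegerVector chain_lengths,
                NumericVector rates, NumericVector pi0, double tol, int maxit) {
  const int K = emis.ncol(), Ttot = emis.nrow();
  NumericVector pi = clone(pi0);
  NumericMatrix gamma(Ttot, K);
  NumericVector entries_out(K);
  std::vector<double> surv = survival_table(d, rates);
  Workspace ws;
  std::vector<double> llhist;
  double prev = R_NegInf;
  bool converged = false;
  int iters = 0;
  for (int iter = 1; iter <= maxit; ++iter) {
    iters = iter;
    NumericVector entries(K);
    double loglik = estep_all(emis.begin(), Ttot, K, chain_lengths, surv,
                              pi.begin(), gamma.begin(), entries.begin(), ws);
    entries_out = entries;
    llhist.push_back(loglik);
    if (iter > 1 && loglik - prev < tol) {
      converged = true;
      break;
    }
    prev = loglik;
    double tot = 0.0;
    for (int k = 0; k < K; ++k) tot += entries[k];
    for (int k = 0; k < K; ++k) pi[k] = entries[k] / tot;
  }
  return List::create(_["pi"] = pi, _["gamma"] = gamma,
                      _["loglik"] = llhist.back(),
                      _["loglik_history"] =
                          NumericVector(llhist.begin(), llhist.end()),
                      _["iterations"] = iters, _["converged"] = converged,
                      _["entries"] = entries_out);
}

// Viterbi decoding in log space; ties broken toward the lowest class index.
// [[Rcpp::export]]
IntegerVector cpp_viterbi(NumericMatrix emis, NumericVector d,
                          IntegerVector chain_lengths, NumericVector rates,
                          NumericVector pi) {
  const int K = emis.ncol(), Ttot = emis.nrow();
  IntegerVector path(Ttot);
  std::vector<double> surv = survival_table(d, rates);
  std::vector<double> logpi(K);
  for (int k = 0; k < K; ++k) logpi[k] = std::log(pi[k]);
  int t0 = 0, d0 = 0;
  for (int c = 0; c < chain_lengths.size(); ++c) {
    int T = chain_lengths[c];
    std::vector<double> delta((size_t)T * K);
    std::vector<int> psi((size_t)T * K);
    for (int k = 0; k < K; ++k)
      delta[k] = logpi[k] + std::log(emis[(size_t)k * Ttot + t0]);
    for (int t = 1; t < T; ++t) {
      const double* srow = &surv[(size_t)(d0 + t - 1) * K];
      const double* dp = &delta[(size_t)(t - 1) * K];
      for (int j = 0; j < K; ++j) {
        double best = R_NegInf;
        int arg = 0;
        for (int k = 0; k < K; ++k) {
          double trans = (1.0 - srow[k]) * pi[j] + (k == j ? srow[k] : 0.0);
          double v = dp[k] + std::log(trans);
          if (v > best) {  // strict: equal scores keep the lower class index
            best = v;
            arg = k;
          }
        }
        delta[(size_t)t * K + j] =
            best + std::log(emis[(size_t)j * Ttot + t0 + t]);
        psi[(size_t)t * K + j] = arg;
      }
    }
    double best = R_NegInf;
    int arg = 0;
    for (int k = 0; k < K; ++k)
      if (delta[(size_t)(T - 1) * K + k] > best) {
        best = delta[(size_t)(T - 1) * K + k];
        arg = k;
      }
    path[t0 + T - 1] = arg + 1;
    for (int t = T - 1; t > 0; --t) {
      arg = psi[(size_t)t * K + path[t0 + t] - 1];
      path[t0 + t - 1] = arg + 1;
    }
    t0 += T;
    d0 += T - 1;
  }
  return path;
}
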