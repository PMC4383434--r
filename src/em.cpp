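#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Full EM loop over mixed records: categorical attributes with Laplace-
// smoothed tables, numeric attributes with per-cluster Gaussians.
// cat: n x A_c integer codes (1-based), num: n x A_r doubles,
// resp: n x K initial responsibilities.  Iterates M-step / E-step until
// the mean per-record objective changes by less than tol.  The trace
// records the objective the M-step maximizes: the training
// log-likelihood plus the Laplace-smoothing log-prior (identical to the
// plain log-likelihood when alpha = 0).  That quantity carries the EM
// monotonicity guarantee; the raw likelihood alone does not once
// smoothing is active.
//
// Internal layout is record-major (each record's attributes and
// responsibilities contiguous) so the per-record loops stream through
// memory.
// [[Rcpp::export]]
List em_run_cpp(IntegerMatrix cat, NumericMatrix num, IntegerVector cards,
                NumericMatrix resp, double alpha, double var_floor,
                double tol, int max_iter) {
  int n = resp.nrow(), K = resp.ncol();
  int Ac = cat.ncol(), Ar = num.ncol();

  std::vector<int> ct((size_t)n * Ac);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < Ac; ++j) ct[(size_t)i * Ac + j] = cat(i, j) - 1;
  std::vector<double> xt((size_t)n * Ar);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < Ar; ++j) xt[(size_t)i * Ar + j] = num(i, j);
  std::vector<double> rs((size_t)n * K);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < K; ++k) rs[(size_t)i * K + k] = resp(i, k);

  // per-attribute log-probability tables, laid out [category][cluster]
  std::vector<std::vector<double>> tables(Ac);
  std::vector<int> off(Ac);
  for (int j = 0; j < Ac; ++j) tables[j].assign((size_t)cards[j] * K, 0.0);
  // Gaussian parameters laid out [attribute][cluster]
  std::vector<double> mu((size_t)Ar * K), varm((size_t)Ar * K);
  std::vector<double> pi(K), lp(K), Nk(K);
  std::vector<double> trace;
  double ll_old = R_NegInf;
  const double LOG2PI = std::log(2.0 * M_PI);

  for (int iter = 0; iter < max_iter; ++iter) {
    // ---- M-step ----
    std::fill(Nk.begin(), Nk.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      const double* r = &rs[(size_t)i * K];
      for (int k = 0; k < K; ++k) Nk[k] += r[k];
    }
    for (int k = 0; k < K; ++k) pi[k] = Nk[k] / n;

    double log_prior = 0.0;
    for (int j = 0; j < Ac; ++j) {
      std::vector<double>& tab = tables[j];
      std::fill(tab.begin(), tab.end(), alpha);
      for (int i = 0; i < n; ++i) {
        double* row = &tab[(size_t)ct[(size_t)i * Ac + j] * K];
        const double* r = &rs[(size_t)i * K];
        for (int k = 0; k < K; ++k) row[k] += r[k];
      }
      for (int k = 0; k < K; ++k) {
        double tot = 0.0;
        for (int c = 0; c < cards[j]; ++c) tot += tab[(size_t)c * K + k];
        for (int c = 0; c < cards[j]; ++c) {
          double& v = tab[(size_t)c * K + k];
          v = std::log(v / tot);
          log_prior += alpha * v;
        }
      }
    }
    if (Ar > 0) {
      std::vector<double> s((size_t)Ar * K, 0.0), s2((size_t)Ar * K, 0.0);
      for (int i = 0; i < n; ++i) {
        const double* r = &rs[(size_t)i * K];
        const double* x = &xt[(size_t)i * Ar];
        for (int j = 0; j < Ar; ++j) {
          double* sj = &s[(size_t)j * K];
          double* s2j = &s2[(size_t)j * K];
          double xv = x[j];
          for (int k = 0; k < K; ++k) {
            sj[k] += r[k] * xv;
            s2j[k] += r[k] * xv * xv;
          }
        }
      }
      for (int j = 0; j < Ar; ++j)
        for (int k = 0; k < K; ++k) {
          double m = s[(size_t)j * K + k] / Nk[k];
          double v = s2[(size_t)j * K + k] / Nk[k] - m * m;
          if (v < var_floor) v = var_floor;
          mu[(size_t)j * K + k] = m;
          varm[(size_t)j * K + k] = v;
        }
    }

    // ---- E-step + objective ----
    double ll = 0.0;
    std::vector<double> logpi(K), halflogv((size_t)Ar * K);
    for (int k = 0; k < K; ++k)
      logpi[k] = pi[k] > 0 ? std::log(pi[k]) : R_NegInf;
    for (size_t t = 0; t < halflogv.size(); ++t)
      halflogv[t] = 0.5 * (std::log(varm[t]) + LOG2PI);
    for (int i = 0; i < n; ++i) {
      for (int k = 0; k < K; ++k) lp[k] = logpi[k];
      const int* ci = &ct[(size_t)i * Ac];
      for (int j = 0; j < Ac; ++j) {
        const double* row = &tables[j][(size_t)ci[j] * K];
        for (int k = 0; k < K; ++k) lp[k] += row[k];
      }
      const double* x = &xt[(size_t)i * Ar];
      for (int j = 0; j < Ar; ++j) {
        const double* mj = &mu[(size_t)j * K];
        const double* vj = &varm[(size_t)j * K];
        const double* hj = &halflogv[(size_t)j * K];
        double xv = x[j];
        for (int k = 0; k < K; ++k) {
          double d = xv - mj[k];
          lp[k] += -0.5 * d * d / vj[k] - hj[k];
        }
      }
      double mx = R_NegInf;
      for (int k = 0; k < K; ++k) if (lp[k] > mx) mx = lp[k];
      double sum = 0.0;
      for (int k = 0; k < K; ++k) sum += std::exp(lp[k] - mx);
      double lse = mx + std::log(sum);
      ll += lse;
      double* r = &rs[(size_t)i * K];
      for (int k = 0; k < K; ++k) r[k] = std::exp(lp[k] - lse);
    }
    double obj = ll + log_prior;
    trace.push_back(obj);
    if (R_finite(ll_old) && std::fabs(obj - ll_old) / n < tol) break;
    ll_old = obj;
  }

  // hand results back on the probability scale, R-facing layouts
  List cat_params(Ac);
  for (int j = 0; j < Ac; ++j) {
    NumericMatrix out(cards[j], K);
    for (int c = 0; c < cards[j]; ++c)
      for (int k = 0; k < K; ++k)
        out(c, k) = std::exp(tables[j][(size_t)c * K + k]);
    cat_params[j] = out;
  }
  NumericMatrix muR(K, Ar), varR(K, Ar), respR(n, K);
  for (int j = 0; j < Ar; ++j)
    for (int k = 0; k < K; ++k) {
      muR(k, j) = mu[(size_t)j * K + k];
      varR(k, j) = varm[(size_t)j * K + k];
    }
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < K; ++k) respR(i, k) = rs[(size_t)i * K + k];
  NumericVector piR(pi.begin(), pi.end());
  return List::create(_["pi"] = piR, _["cat_params"] = cat_params,
                      _["num_mean"] = muR, _["num_var"] = varR,
                      _["trace"] = wrap(trace), _["resp"] = respR);
}
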