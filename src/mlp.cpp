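#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static inline double sigm(double z) { return 1.0 / (1.0 + std::exp(-z)); }

// Contiguous buffers: patterns are stored pattern-major (each pattern's
// inputs adjacent), weights unit-major (each unit's fan-in adjacent), so
// the per-pattern inner products stream through memory.
static std::vector<double> to_pattern_major(const NumericMatrix& X) {
  int n = X.nrow(), d = X.ncol();
  std::vector<double> out((size_t)n * d);
  for (int p = 0; p < n; ++p)
    for (int i = 0; i < d; ++i) out[(size_t)p * d + i] = X(p, i);
  return out;
}

static std::vector<double> to_unit_major(const NumericMatrix& W) {
  int u = W.nrow(), f = W.ncol();
  std::vector<double> out((size_t)u * f);
  for (int j = 0; j < u; ++j)
    for (int i = 0; i < f; ++i) out[(size_t)j * f + i] = W(j, i);
  return out;
}

static NumericMatrix from_unit_major(const std::vector<double>& v, int u,
                                     int f) {
  NumericMatrix W(u, f);
  for (int j = 0; j < u; ++j)
    for (int i = 0; i < f; ++i) W(j, i) = v[(size_t)j * f + i];
  return W;
}

static void forward_one(const double* x, int nin, int h, int nout,
                        const std::vector<double>& w1,
                        const std::vector<double>& th1,
                        const std::vector<double>& w2,
                        const std::vector<double>& th2,
                        double* hid, double* out) {
  for (int j = 0; j < h; ++j) {
    const double* wr = &w1[(size_t)j * nin];
    double s = th1[j];
    for (int i = 0; i < nin; ++i) s += wr[i] * x[i];
    hid[j] = sigm(s);
  }
  for (int k = 0; k < nout; ++k) {
    const double* wr = &w2[(size_t)k * h];
    double s = th2[k];
    for (int j = 0; j < h; ++j) s += wr[j] * hid[j];
    out[k] = sigm(s);
  }
}

// Forward pass for a 1-hidden-layer sigmoid network.
// W1: h x nin, b1: h, W2: nout x h, b2: nout, X: n x nin.
// [[Rcpp::export]]
NumericMatrix mlp_forward_cpp(NumericMatrix W1, NumericVector b1,
                              NumericMatrix W2, NumericVector b2,
                              NumericMatrix X) {
  int n = X.nrow(), nin = X.ncol(), h = W1.nrow(), nout = W2.nrow();
  if (W1.ncol() != nin) stop("input dimension mismatch");
  std::vector<double> Xp = to_pattern_major(X);
  std::vector<double> w1 = to_unit_major(W1), w2 = to_unit_major(W2);
  std::vector<double> th1(b1.begin(), b1.end()), th2(b2.begin(), b2.end());
  std::vector<double> hid(h), out(nout);
  NumericMatrix Y(n, nout);
  for (int p = 0; p < n; ++p) {
    forward_one(&Xp[(size_t)p * nin], nin, h, nout, w1, th1, w2, th2,
                hid.data(), out.data());
    for (int k = 0; k < nout; ++k) Y(p, k) = out[k];
  }
  return Y;
}

// Online backpropagation with momentum.
//   output layer:  dW2 = eta * (d-y) * (1-y) * y * y_hidden + mu * prev_dW2
//   hidden layer:  dW1 = eta * (1-yh) * yh * [sum_k (d-y)(1-y)y * W2_kj] * x
// Weight deltas for both layers are computed from the pre-update weights of
// the pattern, then applied; with mu = 0 one step is exactly gradient
// descent on half the squared error of that pattern.
// orders: epochs x n matrix of 1-based pattern orders (from R's RNG).
// Early stopping: if Xval has rows, training stops once the validation MSE
// has not improved for `patience` consecutive epochs; the best-so-far
// weights are restored.
// [[Rcpp::export]]
List mlp_train_cpp(NumericMatrix W1, NumericVector b1,
                   NumericMatrix W2, NumericVector b2,
                   NumericMatrix X, NumericMatrix D,
                   double eta, double mu, IntegerMatrix orders,
                   NumericMatrix Xval, NumericMatrix Dval,
                   int patience) {
  int n = X.nrow(), nin = X.ncol(), h = W1.nrow(), nout = W2.nrow();
  int epochs = orders.nrow();
  int nval = Xval.nrow();
  std::vector<double> Xp = to_pattern_major(X), Dp = to_pattern_major(D);
  std::vector<double> Xv = to_pattern_major(Xval),
                      Dv = to_pattern_major(Dval);
  std::vector<double> w1 = to_unit_major(W1), w2 = to_unit_major(W2);
  std::vector<double> th1(b1.begin(), b1.end()), th2(b2.begin(), b2.end());
  std::vector<double> pW1(w1.size(), 0.0), pW2(w2.size(), 0.0);
  std::vector<double> pb1(h, 0.0), pb2(nout, 0.0);
  std::vector<double> hid(h), out(nout), dk(nout), gj(h);
  std::vector<double> train_mse, val_mse;
  std::vector<double> bw1 = w1, bw2 = w2, bth1 = th1, bth2 = th2;
  double best_val = R_PosInf;
  int bad = 0, stopped = epochs;
  bool use_val = nval > 0;

  for (int e = 0; e < epochs; ++e) {
    double sse = 0.0;
    for (int q = 0; q < n; ++q) {
      int p = orders(e, q) - 1;
      const double* x = &Xp[(size_t)p * nin];
      const double* d = &Dp[(size_t)p * nout];
      forward_one(x, nin, h, nout, w1, th1, w2, th2, hid.data(), out.data());
      for (int k = 0; k < nout; ++k) {
        double err = d[k] - out[k];
        sse += err * err;
        dk[k] = err * (1.0 - out[k]) * out[k];
      }
      // hidden-layer signal from pre-update output weights
      for (int j = 0; j < h; ++j) {
        double back = 0.0;
        for (int k = 0; k < nout; ++k) back += dk[k] * w2[(size_t)k * h + j];
        gj[j] = (1.0 - hid[j]) * hid[j] * back;
      }
      for (int j = 0; j < h; ++j) {
        double* wr = &w1[(size_t)j * nin];
        double* pr = &pW1[(size_t)j * nin];
        double g = eta * gj[j];
        for (int i = 0; i < nin; ++i) {
          double dlt = g * x[i] + mu * pr[i];
          wr[i] += dlt;
          pr[i] = dlt;
        }
        double dlt = g + mu * pb1[j];
        th1[j] += dlt;
        pb1[j] = dlt;
      }
      for (int k = 0; k < nout; ++k) {
        double* wr = &w2[(size_t)k * h];
        double* pr = &pW2[(size_t)k * h];
        double g = eta * dk[k];
        for (int j = 0; j < h; ++j) {
          double dlt = g * hid[j] + mu * pr[j];
          wr[j] += dlt;
          pr[j] = dlt;
        }
        double dlt = g + mu * pb2[k];
        th2[k] += dlt;
        pb2[k] = dlt;
      }
    }
    double tm = sse / ((double)n * nout);
    train_mse.push_back(tm);
    if (!R_finite(tm)) stop("divergence at epoch %d: non-finite error", e + 1);

    if (use_val) {
      double vs = 0.0;
      for (int p = 0; p < nval; ++p) {
        forward_one(&Xv[(size_t)p * nin], nin, h, nout, w1, th1, w2, th2,
                    hid.data(), out.data());
        for (int k = 0; k < nout; ++k) {
          double err = Dv[(size_t)p * nout + k] - out[k];
          vs += err * err;
        }
      }
      double vm = vs / ((double)nval * nout);
      val_mse.push_back(vm);
      if (vm < best_val - 1e-12) {
        best_val = vm;
        bad = 0;
        bw1 = w1; bw2 = w2; bth1 = th1; bth2 = th2;
      } else if (++bad >= patience) {
        stopped = e + 1;
        break;
      }
    }
  }
  if (use_val) { w1 = bw1; w2 = bw2; th1 = bth1; th2 = bth2; }
  return List::create(
    _["W1"] = from_unit_major(w1, h, nin), _["b1"] = wrap(th1),
    _["W2"] = from_unit_major(w2, nout, h), _["b2"] = wrap(th2),
    _["train_mse"] = wrap(train_mse), _["val_mse"] = wrap(val_mse),
    _["epochs_run"] = stopped);
}
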