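#include <Rcpp.h>
using namespace Rcpp;

// im2col / col2im kernels for 1-D same-padded convolution over feature-map
// matrices laid out as (T*B) x C with t-within-b row order.  These are the
// hot inner loops of the autoencoder; everything else stays in R and BLAS.

// [[Rcpp::export(name = ".convIm2col")]]
NumericMatrix convIm2col(const NumericMatrix& X, int Tn, int B, int k) {
  const int C = X.ncol();
  const int pad = (k - 1) / 2;
  NumericMatrix M(Tn * B, k * C);
  for (int dk = 0; dk < k; ++dk) {
    const int off = dk - pad;
    for (int c = 0; c < C; ++c) {
      const double* src = &X(0, c);
      double* dst = &M(0, dk * C + c);
      for (int b = 0; b < B; ++b) {
        const int base = b * Tn;
        int tlo = std::max(0, -off);
        int thi = std::min(Tn, Tn - off);
        for (int t = tlo; t < thi; ++t) {
          dst[base + t] = src[base + t + off];
        }
      }
    }
  }
  return M;
}

// [[Rcpp::export(name = ".convCol2im")]]
NumericMatrix convCol2im(const NumericMatrix& dM, int Tn, int B, int C,
                         int k) {
  const int pad = (k - 1) / 2;
  NumericMatrix dX(Tn * B, C);
  for (int dk = 0; dk < k; ++dk) {
    const int off = dk - pad;
    for (int c = 0; c < C; ++c) {
      const double* src = &dM(0, dk * C + c);
      double* dst = &dX(0, c);
      for (int b = 0; b < B; ++b) {
        const int base = b * Tn;
        int tlo = std::max(0, -off);
        int thi = std::min(Tn, Tn - off);
        for (int t = tlo; t < thi; ++t) {
          dst[base + t + off] += src[base + t];
        }
      }
    }
  }
  return dX;
}

// y <- x + rep(b, each = nrow(x)) without the temporary
// [[Rcpp::export(name = ".addColwise")]]
NumericMatrix addColwise(const NumericMatrix& X, const NumericVector& b) {
  NumericMatrix Y = clone(X);
  for (int c = 0; c < Y.ncol(); ++c) {
    double* col = &Y(0, c);
    const double bc = b[c];
    for (int r = 0; r < Y.nrow(); ++r) col[r] += bc;
  }
  return Y;
}

// column means and (biased) variances in one pass
// [[Rcpp::export(name = ".bnColStats")]]
List bnColStats(const NumericMatrix& X) {
  const int n = X.nrow(), C = X.ncol();
  NumericVector mu(C), v(C);
  for (int c = 0; c < C; ++c) {
    const double* col = &X(0, c);
    double s = 0, s2 = 0;
    for (int r = 0; r < n; ++r) { s += col[r]; s2 += col[r] * col[r]; }
    mu[c] = s / n;
    v[c] = s2 / n - mu[c] * mu[c];
  }
  return List::create(_["mu"] = mu, _["v"] = v);
}

// xhat = (X - mu) * istd ; Y = xhat * gamma + beta
// [[Rcpp::export(name = ".bnApply")]]
List bnApply(const NumericMatrix& X, const NumericVector& gamma,
             const NumericVector& beta, const NumericVector& mu,
             const NumericVector& istd) {
  const int n = X.nrow(), C = X.ncol();
  NumericMatrix xhat(n, C), Y(n, C);
  for (int c = 0; c < C; ++c) {
    const double* col = &X(0, c);
    double* xh = &xhat(0, c);
    double* y = &Y(0, c);
    const double m = mu[c], is = istd[c], g = gamma[c], b = beta[c];
    for (int r = 0; r < n; ++r) {
      xh[r] = (col[r] - m) * is;
      y[r] = xh[r] * g + b;
    }
  }
  return List::create(_["Y"] = Y, _["xhat"] = xhat);
}

// training-mode batch-norm backward (returns dX, dgamma, dbeta)
// [[Rcpp::export(name = ".bnBackward")]]
List bnBackward(const NumericMatrix& dY, const NumericMatrix& xhat,
                const NumericVector& gamma, const NumericVector& istd) {
  const int n = dY.nrow(), C = dY.ncol();
  NumericMatrix dX(n, C);
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double* dy = &dY(0, c);
    const double* xh = &xhat(0, c);
    double sg = 0, sb = 0;
    for (int r = 0; r < n; ++r) { sg += dy[r] * xh[r]; sb += dy[r]; }
    dgamma[c] = sg; dbeta[c] = sb;
    const double mg = sg / n, mb = sb / n, sc = gamma[c] * istd[c];
    double* dx = &dX(0, c);
    for (int r = 0; r < n; ++r) dx[r] = (dy[r] - mb - xh[r] * mg) * sc;
  }
  return List::create(_["dX"] = dX, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// [[Rcpp::export(name = ".reluFwd")]]
NumericMatrix reluFwd(const NumericMatrix& X) {
  NumericMatrix Y = clone(X);
  double* y = Y.begin();
  for (R_xlen_t i = 0; i < Y.size(); ++i) if (y[i] < 0) y[i] = 0;
  return Y;
}

// dX = dY * (Yfwd > 0)
// [[Rcpp::export(name = ".reluBwd")]]
NumericMatrix reluBwd(const NumericMatrix& dY, const NumericMatrix& Yfwd) {
  NumericMatrix dX = clone(dY);
  double* dx = dX.begin();
  const double* y = Yfwd.begin();
  for (R_xlen_t i = 0; i < dX.size(); ++i) if (y[i] <= 0) dx[i] = 0;
  return dX;
}

// dropout: mask drawn from R's RNG (deterministic under set.seed)
// [[Rcpp::export(name = ".dropoutFwd")]]
List dropoutFwd(const NumericMatrix& X, double p) {
  NumericMatrix Y(X.nrow(), X.ncol()), mask(X.nrow(), X.ncol());
  const double keep = 1.0 - p;
  double* y = Y.begin(); double* m = mask.begin();
  const double* x = X.begin();
  for (R_xlen_t i = 0; i < X.size(); ++i) {
    const double u = R::runif(0.0, 1.0);
    m[i] = (u >= p) ? 1.0 / keep : 0.0;
    y[i] = x[i] * m[i];
  }
  return List::create(_["Y"] = Y, _["mask"] = mask);
}

// [[Rcpp::export(name = ".elemMul")]]
NumericMatrix elemMul(const NumericMatrix& A, const NumericMatrix& B) {
  NumericMatrix Y = clone(A);
  double* y = Y.begin();
  const double* b = B.begin();
  for (R_xlen_t i = 0; i < Y.size(); ++i) y[i] *= b[i];
  return Y;
}

// in-place Adam update on one parameter leaf (p, m, v mutated).  Callers
// must own these buffers exclusively (parameter trees are deep-copied at
// checkpoint boundaries).
// [[Rcpp::export(name = ".adamLeaf")]]
void adamLeaf(NumericVector p, NumericVector m, NumericVector v,
              const NumericVector& g, double lr, double b1, double b2,
              double eps, double bc1, double bc2) {
  const R_xlen_t n = p.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    m[i] = b1 * m[i] + (1 - b1) * g[i];
    v[i] = b2 * v[i] + (1 - b2) * g[i] * g[i];
    p[i] -= lr * (m[i] / bc1) / (std::sqrt(v[i] / bc2) + eps);
  }
}

// fused batch-norm + ReLU forward: Y = max(0, xhat*gamma + beta)
// [[Rcpp::export(name = ".bnApplyRelu")]]
List bnApplyRelu(const NumericMatrix& X, const NumericVector& gamma,
                 const NumericVector& beta, const NumericVector& mu,
                 const NumericVector& istd) {
  const int n = X.nrow(), C = X.ncol();
  NumericMatrix xhat(n, C), Y(n, C);
  for (int c = 0; c < C; ++c) {
    const double* col = &X(0, c);
    double* xh = &xhat(0, c);
    double* y = &Y(0, c);
    const double m = mu[c], is = istd[c], g = gamma[c], b = beta[c];
    for (int r = 0; r < n; ++r) {
      xh[r] = (col[r] - m) * is;
      const double t = xh[r] * g + b;
      y[r] = t > 0 ? t : 0;
    }
  }
  return List::create(_["Y"] = Y, _["xhat"] = xhat);
}

// fused ReLU-mask + batch-norm backward (training mode)
// [[Rcpp::export(name = ".bnReluBackward")]]
List bnReluBackward(const NumericMatrix& dY, const NumericMatrix& Yfwd,
                    const NumericMatrix& xhat, const NumericVector& gamma,
                    const NumericVector& istd) {
  const int n = dY.nrow(), C = dY.ncol();
  NumericMatrix dX(n, C);
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double* dy = &dY(0, c);
    const double* y = &Yfwd(0, c);
    const double* xh = &xhat(0, c);
    double* dx = &dX(0, c);
    double sg = 0, sb = 0;
    for (int r = 0; r < n; ++r) {
      const double d = y[r] > 0 ? dy[r] : 0;
      dx[r] = d;                       // temporarily hold masked dY
      sg += d * xh[r]; sb += d;
    }
    dgamma[c] = sg; dbeta[c] = sb;
    const double mg = sg / n, mb = sb / n, sc = gamma[c] * istd[c];
    for (int r = 0; r < n; ++r) dx[r] = (dx[r] - mb - xh[r] * mg) * sc;
  }
  return List::create(_["dX"] = dX, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// Y = max(0, A + B) (residual add + ReLU)
// [[Rcpp::export(name = ".addRelu")]]
NumericMatrix addRelu(const NumericMatrix& A, const NumericMatrix& B) {
  NumericMatrix Y(A.nrow(), A.ncol());
  double* y = Y.begin();
  const double* a = A.begin(); const double* b = B.begin();
  for (R_xlen_t i = 0; i < A.size(); ++i) {
    const double t = a[i] + b[i];
    y[i] = t > 0 ? t : 0;
  }
  return Y;
}
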