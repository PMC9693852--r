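// Convolution and pooling primitives for the sleep-staging CNN.
// Layout: feature maps are R arrays dim (H, W, C, N), column-major.
// Patch (im2col) order: kh fastest, then kw, then channel, matching the
// weight matrix rows of dim (K x kh*kw*C).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline void im2col(const double* x, int H, int W, int C,
                          int kh, int kw, int stride, int pad,
                          int Ho, int Wo, mat& P) {
  // P: (Ho*Wo) x (kh*kw*C)
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        int q = i + kh * (j + kw * c);
        double* Pq = P.colptr(q);
        for (int wo = 0; wo < Wo; ++wo) {
          int wsrc = wo * stride + j - pad;
          bool wok = (wsrc >= 0 && wsrc < W);
          const double* xcw = xc + (size_t)wsrc * H;
          for (int ho = 0; ho < Ho; ++ho) {
            int hsrc = ho * stride + i - pad;
            Pq[ho + Ho * wo] =
                (wok && hsrc >= 0 && hsrc < H) ? xcw[hsrc] : 0.0;
          }
        }
      }
    }
  }
}

static inline void col2im_add(const mat& P, double* dx, int H, int W, int C,
                              int kh, int kw, int stride, int pad,
                              int Ho, int Wo) {
  for (int c = 0; c < C; ++c) {
    double* xc = dx + (size_t)c * H * W;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        int q = i + kh * (j + kw * c);
        const double* Pq = P.colptr(q);
        for (int wo = 0; wo < Wo; ++wo) {
          int wsrc = wo * stride + j - pad;
          if (wsrc < 0 || wsrc >= W) continue;
          double* xcw = xc + (size_t)wsrc * H;
          for (int ho = 0; ho < Ho; ++ho) {
            int hsrc = ho * stride + i - pad;
            if (hsrc >= 0 && hsrc < H) xcw[hsrc] += Pq[ho + Ho * wo];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
Rcpp::List conv2d_forward(const Rcpp::NumericVector& x,
                          const Rcpp::IntegerVector& xdim,
                          const arma::mat& wmat,
                          const arma::vec& bias,
                          int kh, int kw, int stride, int pad) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  int K = wmat.n_rows;
  int Ho = (H + 2 * pad - kh) / stride + 1;
  int Wo = (W + 2 * pad - kw) / stride + 1;
  Rcpp::NumericVector y((size_t)Ho * Wo * K * N);
  mat P(Ho * Wo, kh * kw * C);
  size_t xstep = (size_t)H * W * C, ystep = (size_t)Ho * Wo * K;
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + n * xstep, H, W, C, kh, kw, stride, pad, Ho, Wo, P);
    mat Y = P * wmat.t();
    Y.each_row() += bias.t();
    std::copy(Y.begin(), Y.end(), y.begin() + n * ystep);
  }
  y.attr("dim") = Rcpp::IntegerVector::create(Ho, Wo, K, N);
  return Rcpp::List::create(Rcpp::Named("y") = y);
}

// [[Rcpp::export]]
Rcpp::List conv2d_backward(const Rcpp::NumericVector& x,
                           const Rcpp::IntegerVector& xdim,
                           const arma::mat& wmat,
                           const Rcpp::NumericVector& dy,
                           int kh, int kw, int stride, int pad) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  int K = wmat.n_rows;
  int Ho = (H + 2 * pad - kh) / stride + 1;
  int Wo = (W + 2 * pad - kw) / stride + 1;
  Rcpp::NumericVector dx((size_t)H * W * C * N);
  mat dW(K, kh * kw * C, fill::zeros);
  vec db(K, fill::zeros);
  mat P(Ho * Wo, kh * kw * C);
  size_t xstep = (size_t)H * W * C, ystep = (size_t)Ho * Wo * K;
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + n * xstep, H, W, C, kh, kw, stride, pad, Ho, Wo, P);
    mat dY(const_cast<double*>(dy.begin()) + n * ystep, Ho * Wo, K,
           false, true);
    dW += dY.t() * P;
    db += sum(dY, 0).t();
    mat dP = dY * wmat;
    col2im_add(dP, dx.begin() + n * xstep, H, W, C, kh, kw, stride, pad,
               Ho, Wo);
  }
  dx.attr("dim") = xdim;
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dw") = dW,
                            Rcpp::Named("db") = db);
}

// [[Rcpp::export]]
Rcpp::List maxpool_forward(const Rcpp::NumericVector& x,
                           const Rcpp::IntegerVector& xdim, int size) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  int Ho = H / size, Wo = W / size;
  size_t outlen = (size_t)Ho * Wo * C * N;
  Rcpp::NumericVector y(outlen);
  Rcpp::IntegerVector amax(outlen);   // 1-based index into x
  size_t o = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      size_t base = ((size_t)n * C + c) * H * W;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -datum::inf; size_t bidx = 0;
          for (int j = 0; j < size; ++j) {
            for (int i = 0; i < size; ++i) {
              size_t idx = base + (size_t)(wo * size + j) * H +
                           ho * size + i;
              if (x[idx] > best) { best = x[idx]; bidx = idx; }
            }
          }
          // output laid out (Ho, Wo, C, N): position computed directly
          size_t oidx = ((size_t)n * C + c) * Ho * Wo +
                        (size_t)wo * Ho + ho;
          y[oidx] = best;
          amax[oidx] = (int)(bidx + 1);
          ++o;
        }
      }
    }
  }
  y.attr("dim") = Rcpp::IntegerVector::create(Ho, Wo, C, N);
  return Rcpp::List::create(Rcpp::Named("y") = y,
                            Rcpp::Named("argmax") = amax);
}

// [[Rcpp::export]]
Rcpp::NumericVector maxpool_backward(const Rcpp::NumericVector& dy,
                                     const Rcpp::IntegerVector& amax,
                                     const Rcpp::IntegerVector& xdim) {
  size_t n = (size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  Rcpp::NumericVector dx(n);
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[amax[i] - 1] += dy[i];
  dx.attr("dim") = xdim;
  return dx;
}
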