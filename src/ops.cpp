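// Low-level numeric kernels for the segmentation network and pupil geometry.
// Tensor layout throughout: column-major R arrays [H, W, C, N]; convolution
// weights [k, k, Cin, Cout]; CARAFE kernels [m*m, rH, rW, N].

#include <RcppArmadillo.h>
#include <vector>

using namespace Rcpp;

static inline void get_dim4(const NumericVector& x, int d[4]) {
  IntegerVector dm = x.attr("dim");
  if (dm.size() != 4) stop("expected a 4-d array");
  for (int i = 0; i < 4; ++i) d[i] = dm[i];
}

static inline NumericVector make4(int a, int b, int c, int d) {
  NumericVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

// im2col for one sample: x points to H*W*C doubles, output K x (H*W)
// with K = k*k*C, row index ci*k*k + kj*k + ki, column index w*H + h.
static void im2col(const double* x, int H, int W, int C, int k, int pad,
                   arma::mat& col) {
  const int K = k * k * C;
  col.zeros(K, (size_t)H * W);
  for (int ci = 0; ci < C; ++ci) {
    const double* xc = x + (size_t)ci * H * W;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int row = ci * k * k + kj * k + ki;
        for (int w = 0; w < W; ++w) {
          const int sw = w + kj - pad;
          if (sw < 0 || sw >= W) continue;
          const double* src = xc + (size_t)sw * H;
          double* dst = col.colptr((size_t)w * H);
          const int h0 = std::max(0, pad - ki);
          const int h1 = std::min(H, H + pad - ki);
          for (int h = h0; h < h1; ++h) {
            dst[(size_t)h * K + row] = src[h + ki - pad];
          }
        }
      }
    }
  }
}

// scatter-add of a K x (H*W) column matrix back into an H*W*C image
static void col2im(const arma::mat& col, int H, int W, int C, int k, int pad,
                   double* dx) {
  const int K = k * k * C;
  for (int ci = 0; ci < C; ++ci) {
    double* xc = dx + (size_t)ci * H * W;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int row = ci * k * k + kj * k + ki;
        for (int w = 0; w < W; ++w) {
          const int sw = w + kj - pad;
          if (sw < 0 || sw >= W) continue;
          double* dst = xc + (size_t)sw * H;
          const double* src = col.colptr((size_t)w * H);
          const int h0 = std::max(0, pad - ki);
          const int h1 = std::min(H, H + pad - ki);
          for (int h = h0; h < h1; ++h) {
            dst[h + ki - pad] += src[(size_t)h * K + row];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w,
                             NumericVector b, int pad) {
  int dx[4]; get_dim4(x, dx);
  IntegerVector dw = w.attr("dim");
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int k = dw[0], Cout = dw[3];
  if (dw[1] != k || dw[2] != C) stop("weight/input channel mismatch");
  const int K = k * k * C;
  NumericVector out = make4(H, W, Cout, N);
  arma::mat Wm(w.begin(), K, Cout, false, true);
  arma::mat col;
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, k, pad, col);
    arma::mat o(out.begin() + (size_t)n * H * W * Cout, (size_t)H * W, Cout,
                false, true);
    o = col.t() * Wm;
    for (int co = 0; co < Cout; ++co) o.col(co) += b[co];
  }
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector dout,
                    int pad) {
  int dx4[4]; get_dim4(x, dx4);
  IntegerVector dw = w.attr("dim");
  const int H = dx4[0], W = dx4[1], C = dx4[2], N = dx4[3];
  const int k = dw[0], Cout = dw[3];
  const int K = k * k * C;
  NumericVector dX = make4(H, W, C, N);
  NumericVector dW = make4(k, k, C, Cout);
  NumericVector dB(Cout);
  arma::mat Wm(w.begin(), K, Cout, false, true);
  arma::mat dWm(dW.begin(), K, Cout, false, true);
  arma::vec dBv(dB.begin(), Cout, false, true);
  arma::mat col;
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, k, pad, col);
    arma::mat go(dout.begin() + (size_t)n * H * W * Cout, (size_t)H * W, Cout,
                 false, true);
    dWm += col * go;
    dBv += arma::sum(go, 0).t();
    arma::mat dcol = Wm * go.t();
    col2im(dcol, H, W, C, k, pad, dX.begin() + (size_t)n * H * W * C);
  }
  return List::create(_["dx"] = dX, _["dw"] = dW, _["db"] = dB);
}

// [[Rcpp::export]]
NumericVector cpp_avgpool2_fwd(NumericVector x) {
  int d[4]; get_dim4(x, d);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  if (H % 2 || W % 2) stop("avgpool2 needs even spatial dims");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector out = make4(Ho, Wo, C, N);
  const double* xs = x.begin();
  double* os = out.begin();
  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    const double* xi = xs + cn * H * W;
    double* oi = os + cn * Ho * Wo;
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h)
        oi[h + (size_t)w * Ho] =
            0.25 * (xi[2 * h + (size_t)(2 * w) * H] +
                    xi[2 * h + 1 + (size_t)(2 * w) * H] +
                    xi[2 * h + (size_t)(2 * w + 1) * H] +
                    xi[2 * h + 1 + (size_t)(2 * w + 1) * H]);
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_avgpool2_bwd(NumericVector dout, int H, int W) {
  int d[4]; get_dim4(dout, d);
  const int Ho = d[0], Wo = d[1], C = d[2], N = d[3];
  NumericVector dx = make4(H, W, C, N);
  const double* gs = dout.begin();
  double* ds = dx.begin();
  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    const double* gi = gs + cn * Ho * Wo;
    double* di = ds + cn * H * W;
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h) {
        const double g = 0.25 * gi[h + (size_t)w * Ho];
        di[2 * h + (size_t)(2 * w) * H] = g;
        di[2 * h + 1 + (size_t)(2 * w) * H] = g;
        di[2 * h + (size_t)(2 * w + 1) * H] = g;
        di[2 * h + 1 + (size_t)(2 * w + 1) * H] = g;
      }
  }
  return dx;
}

// Pixel-shuffle the raw kernel-predictor logits P [H, W, r*r*m*m, N] to
// one softmax-normalized m*m kernel per upsampled location [m*m, rH, rW, N].
// Channel block (dv*r + du) holds the kernel for output (r*s + du, r*t + dv).
// [[Rcpp::export]]
NumericVector cpp_carafe_kernels(NumericVector P, int m, int r) {
  int d[4]; get_dim4(P, d);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int m2 = m * m;
  if (C != r * r * m2) stop("logit channels must equal r^2*m^2");
  NumericVector K = make4(m2, H * r, W * r, N);
  const size_t planeP = (size_t)H * W;
  for (int n = 0; n < N; ++n) {
    const double* Pn = P.begin() + (size_t)n * planeP * C;
    double* Kn = K.begin() + (size_t)n * m2 * H * r * W * r;
    for (int t = 0; t < W; ++t)
      for (int s = 0; s < H; ++s)
        for (int dv = 0; dv < r; ++dv)
          for (int du = 0; du < r; ++du) {
            const int u = r * s + du, v = r * t + dv;
            const int off = (dv * r + du) * m2;
            double* kq = Kn + (size_t)m2 * (u + (size_t)v * H * r);
            double mx = -1e300;
            for (int i = 0; i < m2; ++i) {
              kq[i] = Pn[s + (size_t)t * H + (size_t)(off + i) * planeP];
              if (kq[i] > mx) mx = kq[i];
            }
            double sum = 0.0;
            for (int i = 0; i < m2; ++i) { kq[i] = std::exp(kq[i] - mx); sum += kq[i]; }
            for (int i = 0; i < m2; ++i) kq[i] /= sum;
          }
  }
  return K;
}

// Content-aware reassembly: out(u,v,c) = sum_{i,j} K(q)_{ij} x(s+i-c0, t+j-c0, c)
// with (s,t) = (floor(u/r), floor(v/r)) and zero padding at the border.
// [[Rcpp::export]]
NumericVector cpp_carafe_apply(NumericVector x, NumericVector K, int m, int r) {
  int d[4]; get_dim4(x, d);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int Ho = H * r, Wo = W * r, m2 = m * m, c0 = (m - 1) / 2;
  NumericVector out = make4(Ho, Wo, C, N);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)n * H * W * C;
    const double* Kn = K.begin() + (size_t)n * m2 * Ho * Wo;
    double* on = out.begin() + (size_t)n * Ho * Wo * C;
    for (int v = 0; v < Wo; ++v)
      for (int u = 0; u < Ho; ++u) {
        const int s = u / r, t = v / r;
        const double* kq = Kn + (size_t)m2 * (u + (size_t)v * Ho);
        for (int j = 0; j < m; ++j) {
          const int tj = t + j - c0;
          if (tj < 0 || tj >= W) continue;
          for (int i = 0; i < m; ++i) {
            const int si = s + i - c0;
            if (si < 0 || si >= H) continue;
            const double kij = kq[j * m + i];
            if (kij == 0.0) continue;
            const double* xp = xn + si + (size_t)tj * H;
            double* op = on + u + (size_t)v * Ho;
            for (int c = 0; c < C; ++c)
              op[(size_t)c * Ho * Wo] += kij * xp[(size_t)c * H * W];
          }
        }
      }
  }
  return out;
}

// Backward pass of kernels+apply. Returns dx and the gradient dP on the raw
// (pre-softmax, pre-shuffle) logits.
// [[Rcpp::export]]
List cpp_carafe_bwd(NumericVector x, NumericVector K, NumericVector dout,
                    int m, int r) {
  int d[4]; get_dim4(x, d);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int Ho = H * r, Wo = W * r, m2 = m * m, c0 = (m - 1) / 2;
  NumericVector dX = make4(H, W, C, N);
  NumericVector dP = make4(H, W, r * r * m2, N);
  std::vector<double> dk(m2);
  const size_t planeP = (size_t)H * W;
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)n * H * W * C;
    const double* Kn = K.begin() + (size_t)n * m2 * Ho * Wo;
    const double* gn = dout.begin() + (size_t)n * Ho * Wo * C;
    double* dxn = dX.begin() + (size_t)n * H * W * C;
    double* dPn = dP.begin() + (size_t)n * planeP * r * r * m2;
    for (int v = 0; v < Wo; ++v)
      for (int u = 0; u < Ho; ++u) {
        const int s = u / r, t = v / r;
        const double* kq = Kn + (size_t)m2 * (u + (size_t)v * Ho);
        std::fill(dk.begin(), dk.end(), 0.0);
        for (int j = 0; j < m; ++j) {
          const int tj = t + j - c0;
          if (tj < 0 || tj >= W) continue;
          for (int i = 0; i < m; ++i) {
            const int si = s + i - c0;
            if (si < 0 || si >= H) continue;
            const double kij = kq[j * m + i];
            double acc = 0.0;
            for (int c = 0; c < C; ++c) {
              const double g = gn[u + (size_t)v * Ho + (size_t)c * Ho * Wo];
              acc += g * xn[si + (size_t)tj * H + (size_t)c * H * W];
              dxn[si + (size_t)tj * H + (size_t)c * H * W] += kij * g;
            }
            dk[j * m + i] = acc;
          }
        }
        // softmax jacobian: dlogit = K * (dk - <K, dk>)
        double dot = 0.0;
        for (int i = 0; i < m2; ++i) dot += kq[i] * dk[i];
        const int off = ((v % r) * r + (u % r)) * m2;
        for (int i = 0; i < m2; ++i)
          dPn[s + (size_t)t * H + (size_t)(off + i) * planeP] =
              kq[i] * (dk[i] - dot);
      }
  }
  return List::create(_["dx"] = dX, _["dp"] = dP);
}

// 8-connected component labelling of a logical/integer matrix; 0 = background.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<std::pair<int,int> > stack;
  int next = 0;
  for (int w0 = 0; w0 < W; ++w0)
    for (int h0 = 0; h0 < H; ++h0) {
      if (!mask(h0, w0) || lab(h0, w0)) continue;
      ++next;
      stack.push_back(std::make_pair(h0, w0));
      lab(h0, w0) = next;
      while (!stack.empty()) {
        const int h = stack.back().first, w = stack.back().second;
        stack.pop_back();
        for (int dw = -1; dw <= 1; ++dw)
          for (int dh = -1; dh <= 1; ++dh) {
            const int hh = h + dh, ww = w + dw;
            if (hh < 0 || hh >= H || ww < 0 || ww >= W) continue;
            if (mask(hh, ww) && !lab(hh, ww)) {
              lab(hh, ww) = next;
              stack.push_back(std::make_pair(hh, ww));
            }
          }
      }
    }
  return lab;
}
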