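#include <Rcpp.h>
using namespace Rcpp;

// Direct valid convolution + bias of a batch of images.
// X: (h*w*cin) x B column-major image stack; W: (k*k*cin) x F with the
// kernel offset index ordered dr fastest, then dc, then channel (matching
// the R-side im2col plan); returns Z: ((ho*wo)*B) x F with output position
// (row-major within column, i.e. r fastest) fastest and image second.
// [[Rcpp::export]]
NumericMatrix cpp_conv_fwd(const NumericMatrix& X, const NumericMatrix& W,
                           const NumericVector& bias,
                           int h, int w, int cin, int k) {
  const int B = X.ncol();
  const int ho = h - (k - 1), wo = w - (k - 1);
  const int npos = ho * wo;
  const int F = W.ncol();
  const int K = k * k * cin;
  NumericMatrix Z(npos * B, F);
  std::vector<int> off(K);
  {
    int j = 0;
    for (int ch = 0; ch < cin; ++ch)
      for (int dc = 0; dc < k; ++dc)
        for (int dr = 0; dr < k; ++dr)
          off[j++] = dr + dc * h + ch * h * w;
  }
  for (int b = 0; b < B; ++b) {
    const double* x = &X(0, b);
    for (int f = 0; f < F; ++f) {
      double* z = &Z(b * npos, f);
      const double bf = bias[f];
      for (int p = 0; p < npos; ++p) z[p] = bf;
      for (int j = 0; j < K; ++j) {
        const double wv = W(j, f);
        if (wv == 0.0) continue;
        const double* xs = x + off[j];
        double* zp = z;
        for (int c = 0; c < wo; ++c) {
          const double* xc = xs + c * h;
          for (int r = 0; r < ho; ++r) zp[r] += wv * xc[r];
          zp += ho;
        }
      }
    }
  }
  return Z;
}

// ReLU + 2x2 max pooling over conv output Z ((ho*wo)*B) x F (position
// fastest, image second). Returns pooled M ((hp*wp)*B) x F and the 1-based
// row index of each winner (first of NW, SW, NE, SE on ties).
// [[Rcpp::export]]
List cpp_relu_pool(const NumericMatrix& Z, int ho, int wo) {
  const int npos = ho * wo;
  const int B = Z.nrow() / npos;
  const int F = Z.ncol();
  const int hp = ho / 2, wp = wo / 2;
  const int npool = hp * wp;
  NumericMatrix M(npool * B, F);
  IntegerMatrix arg(npool * B, F);
  for (int f = 0; f < F; ++f) {
    for (int b = 0; b < B; ++b) {
      const double* z = &Z(b * npos, f);
      double* m = &M(b * npool, f);
      int* a = &arg(b * npool, f);
      for (int c = 0; c < wp; ++c) {
        for (int r = 0; r < hp; ++r) {
          const int base = 2 * r + 2 * c * ho;
          const int cand[4] = {base, base + 1, base + ho, base + ho + 1};
          double best = 0.0; int bi = cand[0];
          for (int q = 0; q < 4; ++q) {
            double v = z[cand[q]];
            if (v < 0.0) v = 0.0;
            if (q == 0 || v > best) { best = v; bi = cand[q]; }
          }
          m[r + c * hp] = best;
          a[r + c * hp] = b * npos + bi + 1;  // 1-based row into Z
        }
      }
    }
  }
  return List::create(_["M"] = M, _["arg"] = arg);
}

// Scatter pooled gradients back to conv-output rows via the argmax map.
// [[Rcpp::export]]
NumericMatrix cpp_pool_bwd(const NumericMatrix& dM, const IntegerMatrix& arg,
                           int nrowZ) {
  const int n = dM.nrow(), F = dM.ncol();
  NumericMatrix dA(nrowZ, F);
  for (int f = 0; f < F; ++f)
    for (int i = 0; i < n; ++i)
      dA(arg(i, f) - 1, f) += dM(i, f);
  return dA;
}

// Backward pass of the same convolution. dZ: ((ho*wo)*B) x F (gradient at
// the pre-activation). Returns gW (K x F), gb (F), and optionally dX
// ((h*w*cin) x B) when need_dx is true.
// [[Rcpp::export]]
List cpp_conv_bwd(const NumericMatrix& X, const NumericMatrix& W,
                  const NumericMatrix& dZ,
                  int h, int w, int cin, int k, bool need_dx) {
  const int B = X.ncol();
  const int ho = h - (k - 1), wo = w - (k - 1);
  const int npos = ho * wo;
  const int F = W.ncol();
  const int K = k * k * cin;
  NumericMatrix gW(K, F);
  NumericVector gb(F);
  NumericMatrix dX(need_dx ? X.nrow() : 1, need_dx ? B : 1);
  std::vector<int> off(K);
  {
    int j = 0;
    for (int ch = 0; ch < cin; ++ch)
      for (int dc = 0; dc < k; ++dc)
        for (int dr = 0; dr < k; ++dr)
          off[j++] = dr + dc * h + ch * h * w;
  }
  for (int b = 0; b < B; ++b) {
    const double* x = &X(0, b);
    for (int f = 0; f < F; ++f) {
      const double* dz = &dZ(b * npos, f);
      double s = 0.0;
      for (int p = 0; p < npos; ++p) s += dz[p];
      gb[f] += s;
      for (int j = 0; j < K; ++j) {
        const double* xs = x + off[j];
        double acc = 0.0;
        const double* dzp = dz;
        for (int c = 0; c < wo; ++c) {
          const double* xc = xs + c * h;
          for (int r = 0; r < ho; ++r) acc += xc[r] * dzp[r];
          dzp += ho;
        }
        gW(j, f) += acc;
      }
      if (need_dx) {
        double* dx = &dX(0, b);
        for (int j = 0; j < K; ++j) {
          const double wv = W(j, f);
          if (wv == 0.0) continue;
          double* dxs = dx + off[j];
          const double* dzp = dz;
          for (int c = 0; c < wo; ++c) {
            double* dxc = dxs + c * h;
            for (int r = 0; r < ho; ++r) dxc[r] += wv * dzp[r];
            dzp += ho;
          }
        }
      }
    }
  }
  return List::create(_["gW"] = gW, _["gb"] = gb, _["dX"] = dX);
}
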