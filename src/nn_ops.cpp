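// Low-level numeric kernels for the Conv-Transformer classifier and the
// graph-based over-segmentation used by the region proposal.
//
// Feature-map layout convention (shared with the R side): 4D arrays with
// dim = c(H, W, N, C) where N indexes samples (batch * frames) and C channels.
// im2col rows are ordered k + 9*c with k = dy + 3*dx (dy fastest), matching
// the weight matrix layout W[Cout, 9*Cin].

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double at4(const double *x, int H, int W, int N,
                         int h, int w, int n, int c) {
  return x[h + (size_t)H * (w + (size_t)W * (n + (size_t)N * c))];
}

// 3x3 same-padding convolution forward.
// X: dim (H, W, N, Cin); Wmat: Cout x (9*Cin); bias: Cout.
// Returns list(out = dim (H, W, N, Cout), cols = (H*W*N) x (9*Cin)) — the
// transposed im2col layout keeps every bulk copy contiguous, and the GEMM
// output in (ncol x Cout) order IS the (H, W, N, Cout) array.
// [[Rcpp::export(name = ".nn_conv3_fwd")]]
List nn_conv3_fwd(NumericVector X, IntegerVector dims, NumericMatrix Wmat,
                  NumericVector bias, bool keep_cols) {
  const int H = dims[0], W = dims[1], N = dims[2], Cin = dims[3];
  const int Cout = Wmat.nrow();
  const size_t ncol = (size_t)H * W * N;
  NumericMatrix cols_r(ncol, 9 * Cin);
  arma::mat colsT(cols_r.begin(), ncol, 9 * Cin, false);
  const double *xp = X.begin();
  // build im2col with zero padding; each (k, c) is one contiguous column
  for (int c = 0; c < Cin; ++c) {
    for (int dx = -1; dx <= 1; ++dx) {
      for (int dy = -1; dy <= 1; ++dy) {
        const int k = (dy + 1) + 3 * (dx + 1);
        double *dst = cols_r.begin() + (size_t)ncol * (k + 9 * c);
        const double *src = xp + (size_t)H * W * N * c;
        size_t col = 0;
        for (int n = 0; n < N; ++n) {
          const double *plane = src + (size_t)H * W * n;
          for (int w = 0; w < W; ++w, col += H) {
            const int ws = w + dx;
            if (ws < 0 || ws >= W) {
              for (int h = 0; h < H; ++h) dst[col + h] = 0.0;
            } else {
              const double *colp = plane + (size_t)H * ws;
              if (dy < 0) dst[col] = 0.0;
              if (dy > 0) dst[col + H - 1] = 0.0;
              const int h0 = (dy < 0) ? 1 : 0;
              const int h1 = (dy > 0) ? H - 1 : H;
              for (int h = h0; h < h1; ++h) dst[col + h] = colp[h + dy];
            }
          }
        }
      }
    }
  }
  arma::mat Wa(Wmat.begin(), Cout, 9 * Cin, false);
  NumericVector res((size_t)ncol * Cout);
  arma::mat outT(res.begin(), ncol, Cout, false);
  outT = colsT * Wa.t();  // (H*W*N) x Cout == (H, W, N, Cout) memory
  outT.each_row() += arma::rowvec(bias.begin(), Cout);
  res.attr("dim") = IntegerVector::create(H, W, N, Cout);
  List ret = List::create(_["out"] = res);
  if (keep_cols) ret["cols"] = cols_r;
  return ret;
}

// Backward pass of the 3x3 convolution.
// dout: dim (H, W, N, Cout); cols: as returned by forward (ncol x 9Cin).
// [[Rcpp::export(name = ".nn_conv3_bwd")]]
List nn_conv3_bwd(NumericVector dout, IntegerVector dims, NumericMatrix cols_,
                  NumericMatrix Wmat) {
  const int H = dims[0], W = dims[1], N = dims[2], Cin = dims[3];
  const int Cout = Wmat.nrow();
  const size_t ncol = (size_t)H * W * N;
  arma::mat dOUTT(dout.begin(), ncol, Cout, false);  // no-copy view
  arma::mat colsT(cols_.begin(), ncol, 9 * Cin, false);
  arma::mat Wa(Wmat.begin(), Cout, 9 * Cin, false);
  arma::mat dW = dOUTT.t() * colsT;                  // Cout x 9Cin
  arma::rowvec db = arma::sum(dOUTT, 0);
  arma::mat dcolsT = dOUTT * Wa;                     // ncol x 9Cin
  NumericVector dX((size_t)ncol * Cin);
  double *dxp = dX.begin();
  for (int c = 0; c < Cin; ++c) {
    double *dst0 = dxp + (size_t)H * W * N * c;
    for (int dx = -1; dx <= 1; ++dx) {
      for (int dy = -1; dy <= 1; ++dy) {
        const int k = (dy + 1) + 3 * (dx + 1);
        const double *src = dcolsT.colptr(k + 9 * c);
        size_t col = 0;
        for (int n = 0; n < N; ++n) {
          double *plane = dst0 + (size_t)H * W * n;
          for (int w = 0; w < W; ++w, col += H) {
            const int ws = w + dx;
            if (ws < 0 || ws >= W) continue;
            double *colp = plane + (size_t)H * ws;
            const int h0 = (dy < 0) ? 1 : 0;
            const int h1 = (dy > 0) ? H - 1 : H;
            for (int h = h0; h < h1; ++h) colp[h + dy] += src[col + h];
          }
        }
      }
    }
  }
  dX.attr("dim") = IntegerVector::create(H, W, N, Cin);
  return List::create(_["dX"] = dX, _["dW"] = wrap(dW),
                      _["db"] = NumericVector(db.begin(), db.end()));
}


// Fused batch-norm forward: x viewed as (m x C); returns out and xhat with
// out = xhat * gamma[c] + beta[c], xhat = (x - mu[c]) * inv[c].
// [[Rcpp::export(name = ".nn_bn_apply")]]
List nn_bn_apply(NumericVector x, int m, int C, NumericVector mu,
                 NumericVector inv, NumericVector gamma, NumericVector beta) {
  NumericVector xhat((size_t)m * C), out((size_t)m * C);
  const double *xp = x.begin();
  double *hp = xhat.begin(), *op = out.begin();
  for (int c = 0; c < C; ++c) {
    const double mc = mu[c], ic = inv[c], gc = gamma[c], bc = beta[c];
    const size_t off = (size_t)m * c;
    for (int i = 0; i < m; ++i) {
      const double h = (xp[off + i] - mc) * ic;
      hp[off + i] = h;
      op[off + i] = h * gc + bc;
    }
  }
  return List::create(_["out"] = out, _["xhat"] = xhat);
}

// Fused batch-norm backward: dy, xhat viewed as (m x C).
// dx = (dy*g - mean(dy*g) - xhat * mean(dy*g*xhat)) * inv  (per channel)
// [[Rcpp::export(name = ".nn_bn_bwd")]]
List nn_bn_bwd(NumericVector dy, NumericVector xhat, int m, int C,
               NumericVector gamma, NumericVector inv) {
  NumericVector dx((size_t)m * C), dgamma(C), dbeta(C);
  const double *dp = dy.begin(), *hp = xhat.begin();
  double *op = dx.begin();
  for (int c = 0; c < C; ++c) {
    const size_t off = (size_t)m * c;
    double s1 = 0, s2 = 0;
    for (int i = 0; i < m; ++i) {
      s1 += dp[off + i];
      s2 += dp[off + i] * hp[off + i];
    }
    dgamma[c] = s2;
    dbeta[c] = s1;
    const double g = gamma[c], ic = inv[c];
    const double m1 = g * s1 / m, m2 = g * s2 / m;
    for (int i = 0; i < m; ++i)
      op[off + i] = (dp[off + i] * g - m1 - hp[off + i] * m2) * ic;
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// Per-channel mean and variance of x viewed as (m x C).
// [[Rcpp::export(name = ".nn_col_meanvar")]]
List nn_col_meanvar(NumericVector x, int m, int C) {
  NumericVector mu(C), var(C);
  const double *xp = x.begin();
  for (int c = 0; c < C; ++c) {
    const size_t off = (size_t)m * c;
    double s = 0;
    for (int i = 0; i < m; ++i) s += xp[off + i];
    const double mc = s / m;
    double v = 0;
    for (int i = 0; i < m; ++i) {
      const double d = xp[off + i] - mc;
      v += d * d;
    }
    mu[c] = mc;
    var[c] = v / m;
  }
  return List::create(_["mean"] = mu, _["var"] = var);
}

// 2x2 max pooling, stride 2, floor semantics (trailing odd row/col dropped).
// [[Rcpp::export(name = ".nn_maxpool2_fwd")]]
List nn_maxpool2_fwd(NumericVector X, IntegerVector dims) {
  const int H = dims[0], W = dims[1], N = dims[2], C = dims[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector out((size_t)Ho * Wo * N * C);
  IntegerVector idx((size_t)Ho * Wo * N * C);  // 0..3: (dh, dw) = (i%2, i/2)
  const double *xp = X.begin();
  double *op = out.begin();
  int *ip = idx.begin();
  size_t j = 0;
  for (int c = 0; c < C; ++c)
    for (int n = 0; n < N; ++n)
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h, ++j) {
          double best = -1e300;
          int bi = 0;
          for (int dw = 0; dw < 2; ++dw)
            for (int dh = 0; dh < 2; ++dh) {
              double v = at4(xp, H, W, N, 2 * h + dh, 2 * w + dw, n, c);
              if (v > best) { best = v; bi = dh + 2 * dw; }
            }
          op[j] = best;
          ip[j] = bi;
        }
  out.attr("dim") = IntegerVector::create(Ho, Wo, N, C);
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export(name = ".nn_maxpool2_bwd")]]
NumericVector nn_maxpool2_bwd(NumericVector dout, IntegerVector idx,
                              IntegerVector dims) {
  const int H = dims[0], W = dims[1], N = dims[2], C = dims[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector dX((size_t)H * W * N * C);
  double *dxp = dX.begin();
  const double *dp = dout.begin();
  const int *ip = idx.begin();
  size_t j = 0;
  for (int c = 0; c < C; ++c)
    for (int n = 0; n < N; ++n)
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h, ++j) {
          const int dh = ip[j] % 2, dw = ip[j] / 2;
          dxp[(2 * h + dh) +
              (size_t)H * ((2 * w + dw) + (size_t)W * (n + (size_t)N * c))] +=
              dp[j];
        }
  dX.attr("dim") = IntegerVector::create(H, W, N, C);
  return dX;
}

// ---------------------------------------------------------------------------
// Felzenszwalb-Huttenlocher graph segmentation (4-connectivity, intensity
// edge weights). Used as the over-segmentation stage of the selective-search
// style region proposal.

struct DisjointSet {
  std::vector<int> parent, rank_, size_;
  std::vector<double> thr;
  DisjointSet(int n, double k) : parent(n), rank_(n, 0), size_(n, 1), thr(n, k) {
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  }
  int join(int a, int b) {
    if (rank_[a] < rank_[b]) std::swap(a, b);
    parent[b] = a;
    size_[a] += size_[b];
    if (rank_[a] == rank_[b]) rank_[a]++;
    return a;
  }
};

// [[Rcpp::export(name = ".felz_segment")]]
IntegerMatrix felz_segment(NumericMatrix img, double k, int min_size) {
  const int H = img.nrow(), W = img.ncol();
  const int n = H * W;
  struct Edge { int a, b; double w; };
  std::vector<Edge> edges;
  edges.reserve(2 * (size_t)n);
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h) {
      const int id = h + H * w;
      if (h + 1 < H)
        edges.push_back({id, id + 1, std::fabs(img(h, w) - img(h + 1, w))});
      if (w + 1 < W)
        edges.push_back({id, id + H, std::fabs(img(h, w) - img(h, w + 1))});
    }
  std::sort(edges.begin(), edges.end(),
            [](const Edge &x, const Edge &y) { return x.w < y.w; });
  DisjointSet ds(n, k);
  for (const Edge &e : edges) {
    int a = ds.find(e.a), b = ds.find(e.b);
    if (a == b) continue;
    if (e.w <= ds.thr[a] && e.w <= ds.thr[b]) {
      int r = ds.join(a, b);
      ds.thr[r] = e.w + k / ds.size_[r];
    }
  }
  // absorb small components
  for (const Edge &e : edges) {
    int a = ds.find(e.a), b = ds.find(e.b);
    if (a != b && (ds.size_[a] < min_size || ds.size_[b] < min_size))
      ds.join(a, b);
  }
  IntegerMatrix lab(H, W);
  std::unordered_map<int, int> remap;
  int next = 0;
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h) {
      int r = ds.find(h + H * w);
      auto it = remap.find(r);
      if (it == remap.end()) { remap[r] = ++next; lab(h, w) = next; }
      else lab(h, w) = it->second;
    }
  return lab;
}
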