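#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Sliding-window gray-level co-occurrence features.
// `qpad` is the quantized image (values 0..levels-1) already reflect-padded by
// kappa/2 on every side; H, W are the original dimensions. `offsets` holds one
// (drow, dcol) pair per row. Per window one symmetric co-occurrence matrix is
// accumulated per offset, normalized, and the per-offset feature values are
// averaged with equal weight. Returns an H*W x 5 matrix with columns
// contrast, correlation, energy, entropy, homogeneity (pixel order column-major).
// [[Rcpp::export]]
NumericMatrix cpp_glcm_maps(IntegerMatrix qpad, int H, int W, int kappa,
                            int levels, IntegerMatrix offsets) {
  const int noff = offsets.nrow();
  NumericMatrix out(H * W, 5);
  std::vector<double> P(levels * levels);
  const double log2e = 1.0 / std::log(2.0);

  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      double feat[5] = {0, 0, 0, 0, 0};
      int used = 0;
      for (int o = 0; o < noff; ++o) {
        const int dr = offsets(o, 0), dc = offsets(o, 1);
        std::fill(P.begin(), P.end(), 0.0);
        double npairs = 0.0;
        // window spans rows r..r+kappa-1, cols c..c+kappa-1 of the padded image
        const int r0 = r, c0 = c;
        for (int wc = 0; wc < kappa; ++wc) {
          const int ac = c0 + wc, bc = ac + dc;
          if (bc < c0 || bc >= c0 + kappa) continue;
          for (int wr = 0; wr < kappa; ++wr) {
            const int ar = r0 + wr, br = ar + dr;
            if (br < r0 || br >= r0 + kappa) continue;
            const int ga = qpad(ar, ac), gb = qpad(br, bc);
            P[ga * levels + gb] += 1.0;
            P[gb * levels + ga] += 1.0;
            npairs += 2.0;
          }
        }
        if (npairs <= 0) continue;
        ++used;
        const double inv = 1.0 / npairs;
        double contrast = 0, energy = 0, entropy = 0, homog = 0;
        double mu_i = 0, mu_j = 0, sij = 0;
        for (int i = 0; i < levels; ++i) {
          for (int j = 0; j < levels; ++j) {
            const double p = P[i * levels + j] * inv;
            if (p <= 0) continue;
            const int d = i - j;
            contrast += p * d * d;
            energy += p * p;
            entropy -= p * std::log(p) * log2e;
            homog += p / (1.0 + std::abs(d));
            mu_i += i * p;
            mu_j += j * p;
            sij += static_cast<double>(i) * j * p;
          }
        }
        double var_i = 0, var_j = 0;
        for (int i = 0; i < levels; ++i) {
          for (int j = 0; j < levels; ++j) {
            const double p = P[i * levels + j] * inv;
            if (p <= 0) continue;
            var_i += (i - mu_i) * (i - mu_i) * p;
            var_j += (j - mu_j) * (j - mu_j) * p;
          }
        }
        double corr = 0.0;
        const double den = std::sqrt(var_i * var_j);
        if (den > 1e-12) corr = (sij - mu_i * mu_j) / den;
        feat[0] += contrast;
        feat[1] += corr;
        feat[2] += energy;
        feat[3] += entropy;
        feat[4] += homog;
      }
      const int idx = r + c * H;
      if (used > 0)
        for (int f = 0; f < 5; ++f) out(idx, f) = feat[f] / used;
      else
        out(idx, 2) = 1.0;  // no admissible pairs: treat as constant window
    }
  }
  return out;
}

// 'valid' 2-D correlation of a pre-padded image with a kernel: output has size
// (nrow(padded)-nrow(kern)+1) x (ncol(padded)-ncol(kern)+1).
// [[Rcpp::export]]
NumericMatrix cpp_conv2_valid(NumericMatrix padded, NumericMatrix kern) {
  const int kr = kern.nrow(), kc = kern.ncol();
  const int H = padded.nrow() - kr + 1, W = padded.ncol() - kc + 1;
  NumericMatrix out(H, W);
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      double s = 0.0;
      for (int j = 0; j < kc; ++j)
        for (int i = 0; i < kr; ++i)
          s += padded(r + i, c + j) * kern(i, j);
      out(r, c) = s;
    }
  }
  return out;
}

// Sorted distances to the k nearest neighbours of every row of X (self excluded),
// brute force. Returns an N x k matrix of Euclidean distances, ascending.
// [[Rcpp::export]]
NumericMatrix cpp_knn_dist(NumericMatrix X, int k) {
  const int N = X.nrow(), d = X.ncol();
  if (k >= N) stop("k must be smaller than the number of points");
  NumericMatrix out(N, k);
  std::vector<double> d2(N);
  const double *x = X.begin();
  for (int i = 0; i < N; ++i) {
    std::fill(d2.begin(), d2.end(), 0.0);
    for (int c = 0; c < d; ++c) {
      const double *col = x + static_cast<size_t>(c) * N;
      const double xi = col[i];
      for (int j = 0; j < N; ++j) {
        const double diff = xi - col[j];
        d2[j] += diff * diff;
      }
    }
    d2[i] = R_PosInf;
    std::nth_element(d2.begin(), d2.begin() + k - 1, d2.end());
    std::sort(d2.begin(), d2.begin() + k);
    for (int j = 0; j < k; ++j) out(i, j) = std::sqrt(d2[j]);
  }
  return out;
}

// Indices (0-based) of the k nearest neighbours of every row of X, self
// excluded, sorted by ascending distance; ties resolved by index order.
// [[Rcpp::export]]
IntegerMatrix cpp_knn_idx(NumericMatrix X, int k) {
  const int N = X.nrow(), d = X.ncol();
  if (k >= N) stop("k must be smaller than the number of points");
  IntegerMatrix out(N, k);
  std::vector<double> d2(N);
  std::vector<int> ord(N);
  const double *x = X.begin();
  for (int i = 0; i < N; ++i) {
    std::fill(d2.begin(), d2.end(), 0.0);
    for (int c = 0; c < d; ++c) {
      const double *col = x + static_cast<size_t>(c) * N;
      const double xi = col[i];
      for (int j = 0; j < N; ++j) {
        const double diff = xi - col[j];
        d2[j] += diff * diff;
      }
    }
    d2[i] = R_PosInf;
    for (int j = 0; j < N; ++j) ord[j] = j;
    std::partial_sort(ord.begin(), ord.begin() + k, ord.end(),
                      [&](int a, int b) {
                        return d2[a] < d2[b] || (d2[a] == d2[b] && a < b);
                      });
    for (int j = 0; j < k; ++j) out(i, j) = ord[j];
  }
  return out;
}

// Full joint-graph alpha-MI evaluation in one pass: builds the kNN graph of
// the joint matrix [F M], evaluates the three pairwise distances per edge and
// returns log(mean((dj/sqrt(df*dm))^gam2)) / (alpha-1). Distances are floored
// at 1e-12.
// [[Rcpp::export]]
double cpp_alpha_mi_joint(NumericMatrix F_, NumericMatrix M_, int k,
                          double alpha, double gam2) {
  const int N = F_.nrow(), df_ = F_.ncol(), dm_ = M_.ncol();
  if (k >= N) stop("k must be smaller than N");
  std::vector<double> d2(N);
  std::vector<int> ord(N);
  const double *fx = F_.begin();
  const double *mx = M_.begin();
  double acc = 0.0;
  const double eps = 1e-12;
  for (int i = 0; i < N; ++i) {
    std::fill(d2.begin(), d2.end(), 0.0);
    for (int c = 0; c < df_; ++c) {
      const double *col = fx + static_cast<size_t>(c) * N;
      const double xi = col[i];
      for (int j = 0; j < N; ++j) {
        const double diff = xi - col[j];
        d2[j] += diff * diff;
      }
    }
    std::vector<double> d2f(d2);   // marginal-F squared distances
    for (int c = 0; c < dm_; ++c) {
      const double *col = mx + static_cast<size_t>(c) * N;
      const double xi = col[i];
      for (int j = 0; j < N; ++j) {
        const double diff = xi - col[j];
        d2[j] += diff * diff;
      }
    }
    d2[i] = R_PosInf;
    for (int j = 0; j < N; ++j) ord[j] = j;
    std::partial_sort(ord.begin(), ord.begin() + k, ord.end(),
                      [&](int a, int b) {
                        return d2[a] < d2[b] || (d2[a] == d2[b] && a < b);
                      });
    double row = 0.0;
    for (int j = 0; j < k; ++j) {
      const int p = ord[j];
      double dj = std::sqrt(d2[p]);
      double dfv = std::sqrt(d2f[p]);
      double dmv = std::sqrt(d2[p] - d2f[p] > 0 ? d2[p] - d2f[p] : 0);
      if (dj < eps) dj = eps;
      if (dfv < eps) dfv = eps;
      if (dmv < eps) dmv = eps;
      row += std::pow(dj / std::sqrt(dfv * dmv), gam2);
    }
    acc += row / k;
  }
  return std::log(acc / N) / (alpha - 1.0);
}

// Euclidean distances between row i of X and the rows listed in idx(i, ).
// [[Rcpp::export]]
NumericMatrix cpp_pair_dist(NumericMatrix X, IntegerMatrix idx) {
  const int N = X.nrow(), d = X.ncol(), k = idx.ncol();
  NumericMatrix out(N, k);
  for (int i = 0; i < N; ++i) {
    for (int j = 0; j < k; ++j) {
      const int p = idx(i, j);
      double s = 0.0;
      for (int c = 0; c < d; ++c) {
        const double diff = X(i, c) - X(p, c);
        s += diff * diff;
      }
      out(i, j) = std::sqrt(s);
    }
  }
  return out;
}

static inline double bspline_basis(int m, double t) {
  const double t2 = t * t, t3 = t2 * t;
  switch (m) {
    case 0: return (1 - 3 * t + 3 * t2 - t3) / 6.0;
    case 1: return (3 * t3 - 6 * t2 + 4) / 6.0;
    case 2: return (-3 * t3 + 3 * t2 + 3 * t + 1) / 6.0;
    default: return t3 / 6.0;
  }
}

// Cubic B-spline free-form displacement at arbitrary (0-based) pixel positions.
// Control grids coefR/coefC are (Gr x Gc); grid row g (0-based) sits at spline
// index g-1, so a point with s = row/spacing, i0 = floor(s) reads rows i0..i0+3.
// Returns an N x 2 matrix of (drow, dcol).
// [[Rcpp::export]]
NumericMatrix cpp_bspline_disp(NumericMatrix coefR, NumericMatrix coefC,
                               NumericVector rows, NumericVector cols,
                               double spacing) {
  const int N = rows.size();
  const int Gr = coefR.nrow(), Gc = coefR.ncol();
  NumericMatrix out(N, 2);
  for (int n = 0; n < N; ++n) {
    const double sr = rows[n] / spacing, sc = cols[n] / spacing;
    const int i0 = static_cast<int>(std::floor(sr));
    const int j0 = static_cast<int>(std::floor(sc));
    const double tr = sr - i0, tc = sc - j0;
    double br[4], bc[4];
    for (int m = 0; m < 4; ++m) {
      br[m] = bspline_basis(m, tr);
      bc[m] = bspline_basis(m, tc);
    }
    double ur = 0.0, uc = 0.0;
    for (int mj = 0; mj < 4; ++mj) {
      const int gj = j0 + mj;
      if (gj < 0 || gj >= Gc) continue;
      for (int mi = 0; mi < 4; ++mi) {
        const int gi = i0 + mi;
        if (gi < 0 || gi >= Gr) continue;
        const double w = br[mi] * bc[mj];
        ur += w * coefR(gi, gj);
        uc += w * coefC(gi, gj);
      }
    }
    out(n, 0) = ur;
    out(n, 1) = uc;
  }
  return out;
}

// Bilinear sampling of `img` at 0-based (row, col) positions; samples outside
// [0, H-1] x [0, W-1] return `fill`.
// [[Rcpp::export]]
NumericVector cpp_bilinear(NumericMatrix img, NumericVector rows,
                           NumericVector cols, double fill = 0.0) {
  const int H = img.nrow(), W = img.ncol(), N = rows.size();
  NumericVector out(N);
  const double eps = 1e-9;
  for (int n = 0; n < N; ++n) {
    double r = rows[n], c = cols[n];
    // samples a rounding error outside the domain clamp to the border
    if (r > -eps && r < 0) r = 0;
    if (c > -eps && c < 0) c = 0;
    if (r > H - 1 && r < H - 1 + eps) r = H - 1;
    if (c > W - 1 && c < W - 1 + eps) c = W - 1;
    if (!(r >= 0 && r <= H - 1 && c >= 0 && c <= W - 1)) {
      out[n] = fill;
      continue;
    }
    int r0 = static_cast<int>(std::floor(r));
    int c0 = static_cast<int>(std::floor(c));
    if (r0 == H - 1) r0 = H - 2 >= 0 ? H - 2 : 0;
    if (c0 == W - 1) c0 = W - 2 >= 0 ? W - 2 : 0;
    const double dr = r - r0, dc = c - c0;
    if (H == 1 && W == 1) { out[n] = img(0, 0); continue; }
    const int r1 = std::min(r0 + 1, H - 1), c1 = std::min(c0 + 1, W - 1);
    out[n] = img(r0, c0) * (1 - dr) * (1 - dc) + img(r1, c0) * dr * (1 - dc) +
             img(r0, c1) * (1 - dr) * dc + img(r1, c1) * dr * dc;
  }
  return out;
}

// Squared Euclidean cross-distances between rows of A (n x d) and B (m x d).
// [[Rcpp::export]]
NumericMatrix cpp_cross_dist2(NumericMatrix A, NumericMatrix B) {
  const int n = A.nrow(), m = B.nrow(), d = A.ncol();
  NumericMatrix out(n, m);
  for (int j = 0; j < m; ++j) {
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int c = 0; c < d; ++c) {
        const double diff = A(i, c) - B(j, c);
        s += diff * diff;
      }
      out(i, j) = s;
    }
  }
  return out;
}
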