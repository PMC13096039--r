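#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Feature maps are stored as (H*W*B) x C matrices, rows ordered
// y-fastest, then x, then sample: row = y + x*H + b*H*W (0-based).

// im2col for stride-1, same-padded k x k convolution.
// Output: (H*W*B) x (C*k*k), column = dy + dx*k + c*k*k.
// Inner copies run over contiguous y-spans so they vectorise.
// [[Rcpp::export]]
NumericMatrix cpp_im2col(const NumericMatrix& x, int H, int W, int B, int k) {
  int C = x.ncol();
  int pad = (k - 1) / 2;
  int N = H * W * B;
  NumericMatrix out(N, C * k * k);
  const double* xp = REAL(x);
  double* op = REAL(out);
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + (size_t)c * N;
    for (int dx = 0; dx < k; ++dx) {
      for (int dy = 0; dy < k; ++dy) {
        int col = c * k * k + dx * k + dy;
        double* oc = op + (size_t)col * N;
        int y_lo = std::max(0, pad - dy);          // first valid output y
        int y_hi = std::min(H, H + pad - dy);      // one past last valid
        if (y_lo >= y_hi) continue;
        for (int b = 0; b < B; ++b) {
          for (int xx = 0; xx < W; ++xx) {
            int sx = xx + dx - pad;
            if (sx < 0 || sx >= W) continue;
            const double* src = xc + (size_t)b * H * W + (size_t)sx * H
                                + (y_lo + dy - pad);
            double* dst = oc + (size_t)b * H * W + (size_t)xx * H + y_lo;
            std::copy(src, src + (y_hi - y_lo), dst);
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of cpp_im2col: scatter-add patch columns back onto the grid.
// [[Rcpp::export]]
NumericMatrix cpp_col2im(const NumericMatrix& cols, int H, int W, int B,
                         int C, int k) {
  int pad = (k - 1) / 2;
  int N = H * W * B;
  NumericMatrix out(N, C);
  const double* cp = REAL(cols);
  double* op = REAL(out);
  for (int c = 0; c < C; ++c) {
    double* oc = op + (size_t)c * N;
    for (int dx = 0; dx < k; ++dx) {
      for (int dy = 0; dy < k; ++dy) {
        int col = c * k * k + dx * k + dy;
        const double* cc = cp + (size_t)col * N;
        int y_lo = std::max(0, pad - dy);
        int y_hi = std::min(H, H + pad - dy);
        if (y_lo >= y_hi) continue;
        for (int b = 0; b < B; ++b) {
          for (int xx = 0; xx < W; ++xx) {
            int sx = xx + dx - pad;
            if (sx < 0 || sx >= W) continue;
            double* dst = oc + (size_t)b * H * W + (size_t)sx * H
                          + (y_lo + dy - pad);
            const double* src = cc + (size_t)b * H * W + (size_t)xx * H + y_lo;
            int n = y_hi - y_lo;
            for (int i = 0; i < n; ++i) dst[i] += src[i];
          }
        }
      }
    }
  }
  return out;
}

static int uf_find(std::vector<int>& parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

// Connected-component labelling of a binary matrix with 4- or 8-connectivity.
// Labels are positive integers; 0 stays background. Label order follows the
// column-major first occurrence of each component.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const IntegerMatrix& m, int conn) {
  int H = m.nrow(), W = m.ncol();
  std::vector<int> parent(H * W);
  for (int i = 0; i < H * W; ++i) parent[i] = i;

  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (m(r, c) == 0) continue;
      int idx = r + c * H;
      // neighbours already visited in column-major order
      if (r > 0 && m(r - 1, c) != 0) {
        int a = uf_find(parent, idx), b = uf_find(parent, idx - 1);
        if (a != b) parent[std::max(a, b)] = std::min(a, b);
      }
      if (c > 0 && m(r, c - 1) != 0) {
        int a = uf_find(parent, idx), b = uf_find(parent, idx - H);
        if (a != b) parent[std::max(a, b)] = std::min(a, b);
      }
      if (conn == 8) {
        if (r > 0 && c > 0 && m(r - 1, c - 1) != 0) {
          int a = uf_find(parent, idx), b = uf_find(parent, idx - H - 1);
          if (a != b) parent[std::max(a, b)] = std::min(a, b);
        }
        if (r < H - 1 && c > 0 && m(r + 1, c - 1) != 0) {
          int a = uf_find(parent, idx), b = uf_find(parent, idx - H + 1);
          if (a != b) parent[std::max(a, b)] = std::min(a, b);
        }
      }
    }
  }

  IntegerMatrix lab(H, W);
  std::vector<int> relabel(H * W, 0);
  int next = 0;
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (m(r, c) == 0) continue;
      int root = uf_find(parent, r + c * H);
      if (relabel[root] == 0) relabel[root] = ++next;
      lab(r, c) = relabel[root];
    }
  }
  return lab;
}
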