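#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Sliding min/max down each column: out(i,j) = extreme of x(ii, j) for
// ii in [i+a, i+b] intersected with [0, nrow). Monotonic-deque, O(n) per
// column, and memory access is contiguous (column-major storage).
static void col_sliding_extreme(const NumericMatrix &x, NumericMatrix &out,
                                int a, int b, bool maximum) {
  const int n = x.nrow(), m = x.ncol();
  std::vector<int> dq(n);
  for (int j = 0; j < m; ++j) {
    const double *col = &x(0, j);
    double *ocol = &out(0, j);
    int head = 0, tail = 0, nxt = 0;
    for (int i = 0; i < n; ++i) {
      int lo = i + a, hi = i + b;
      if (hi > n - 1) hi = n - 1;
      if (lo < 0) lo = 0;
      while (nxt <= hi) {
        double v = col[nxt];
        while (tail > head) {
          double back = col[dq[tail - 1]];
          if (maximum ? (back <= v) : (back >= v)) --tail; else break;
        }
        dq[tail++] = nxt++;
      }
      while (head < tail && dq[head] < lo) ++head;
      ocol[i] = col[dq[head]];
    }
  }
}

static NumericMatrix transpose_mat(const NumericMatrix &x) {
  const int R = x.nrow(), C = x.ncol();
  NumericMatrix out(C, R);
  const int B = 64;  // blocked transpose for cache friendliness
  for (int r0 = 0; r0 < R; r0 += B) {
    for (int c0 = 0; c0 < C; c0 += B) {
      const int r1 = std::min(R, r0 + B), c1 = std::min(C, c0 + B);
      for (int c = c0; c < c1; ++c)
        for (int r = r0; r < r1; ++r)
          out(c, r) = x(r, c);
    }
  }
  return out;
}

// Flat grayscale erosion (maximum = false) or dilation (maximum = true)
// with an arbitrary structuring element whose rows are contiguous runs
// containing the centre column (true for disks, centred lines, boxes).
// Pixels outside the image are ignored (the window shrinks at borders),
// so the result equals the brute-force min/max over in-bounds neighbours.
// Internally the image is transposed so that both the sliding pass and the
// fold walk contiguous memory.
// [[Rcpp::export]]
NumericMatrix morph_extreme_cpp(NumericMatrix x, LogicalMatrix se, bool maximum) {
  const int R = x.nrow(), C = x.ncol();
  const int sr = se.nrow(), sc = se.ncol();
  const int cr = sr / 2, cc = sc / 2;
  if (sr % 2 == 0 || sc % 2 == 0)
    stop("structuring element must have odd dimensions");
  NumericMatrix xt = transpose_mat(x);          // C x R
  NumericMatrix out_t(C, R), tmp(C, R);
  std::fill(out_t.begin(), out_t.end(), maximum ? R_NegInf : R_PosInf);
  for (int k = 0; k < sr; ++k) {
    int lo = -1, hi = -1;
    for (int j = 0; j < sc; ++j) {
      if (se(k, j)) {
        if (lo < 0) lo = j;
        else if (hi != j - 1) stop("structuring element rows must be contiguous runs");
        hi = j;
      }
    }
    if (lo < 0) continue;
    // window over the image's column index = xt's row index
    col_sliding_extreme(xt, tmp, lo - cc, hi - cc, maximum);
    const int dr = k - cr;
    for (int j = 0; j < R; ++j) {               // output image row j
      const int jj = j + dr;
      if (jj < 0 || jj >= R) continue;
      const double *tcol = &tmp(0, jj);
      double *ocol = &out_t(0, j);
      if (maximum) {
        for (int i = 0; i < C; ++i) if (tcol[i] > ocol[i]) ocol[i] = tcol[i];
      } else {
        for (int i = 0; i < C; ++i) if (tcol[i] < ocol[i]) ocol[i] = tcol[i];
      }
    }
  }
  return transpose_mat(out_t);
}

// Convolve each column of x with the kernel (zero padding at the ends).
static NumericMatrix conv_cols(const NumericMatrix &x, const NumericVector &kern) {
  const int n = x.nrow(), m = x.ncol(), K = kern.size(), h = K / 2;
  NumericMatrix out(n, m);
  for (int c = 0; c < m; ++c) {
    const double *col = &x(0, c);
    double *ocol = &out(0, c);
    for (int r = 0; r < n; ++r) {
      double s = 0.0;
      const int j0 = std::max(0, r - h), j1 = std::min(n - 1, r + h);
      for (int j = j0; j <= j1; ++j) s += col[j] * kern[h + (r - j)];
      ocol[r] = s;
    }
  }
  return out;
}

// Separable 2D convolution with a symmetric 1D kernel (zero padding).
// Both passes run down contiguous columns (with a transpose in between).
// [[Rcpp::export]]
NumericMatrix conv_sep_cpp(NumericMatrix x, NumericVector kern) {
  if (kern.size() % 2 == 0) stop("kernel length must be odd");
  NumericMatrix v = conv_cols(x, kern);
  NumericMatrix ht = conv_cols(transpose_mat(v), kern);
  return transpose_mat(ht);
}

// 8-connected component labelling of a logical mask (NA treated as false).
// [[Rcpp::export]]
IntegerMatrix label8_cpp(LogicalMatrix m) {
  const int R = m.nrow(), C = m.ncol();
  IntegerMatrix lab(R, C);
  std::vector<int> stack;
  int cur = 0;
  for (int c = 0; c < C; ++c) {
    for (int r = 0; r < R; ++r) {
      if (m(r, c) != TRUE || lab(r, c) != 0) continue;
      ++cur;
      lab(r, c) = cur;
      stack.push_back(r + R * c);
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int pr = p % R, pc = p / R;
        for (int dc = -1; dc <= 1; ++dc) {
          for (int dr = -1; dr <= 1; ++dr) {
            if (dr == 0 && dc == 0) continue;
            int rr = pr + dr, cc2 = pc + dc;
            if (rr < 0 || rr >= R || cc2 < 0 || cc2 >= C) continue;
            if (m(rr, cc2) == TRUE && lab(rr, cc2) == 0) {
              lab(rr, cc2) = cur;
              stack.push_back(rr + R * cc2);
            }
          }
        }
      }
    }
  }
  return lab;
}
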