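// Global pairwise alignment (Needleman-Wunsch) with affine gap penalties.
// A gap of length g costs open + (g - 1) * extend. Traceback tie-break:
// prefer match/mismatch over gap-in-a over gap-in-b.
#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(std::string a, std::string b, NumericMatrix sub,
                  std::string alphabet, double gap_open, double gap_extend) {
  int n = a.size(), m = b.size();
  std::vector<int> ai(n), bi(m);
  for (int i = 0; i < n; ++i) {
    size_t p = alphabet.find(a[i]);
    if (p == std::string::npos) stop("residue not in substitution matrix: %s",
                                     std::string(1, a[i]));
    ai[i] = p;
  }
  for (int j = 0; j < m; ++j) {
    size_t p = alphabet.find(b[j]);
    if (p == std::string::npos) stop("residue not in substitution matrix: %s",
                                     std::string(1, b[j]));
    bi[j] = p;
  }

  auto idx = [m](int i, int j) { return i * (m + 1) + j; };
  std::vector<double> M((n + 1) * (m + 1), NEG_INF);
  std::vector<double> X((n + 1) * (m + 1), NEG_INF);  // gap in b (consumes a)
  std::vector<double> Y((n + 1) * (m + 1), NEG_INF);  // gap in a (consumes b)
  M[idx(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) X[idx(i, 0)] = -gap_open - (i - 1) * gap_extend;
  for (int j = 1; j <= m; ++j) Y[idx(0, j)] = -gap_open - (j - 1) * gap_extend;

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = sub(ai[i - 1], bi[j - 1]);
      double pm = M[idx(i - 1, j - 1)], px = X[idx(i - 1, j - 1)],
             py = Y[idx(i - 1, j - 1)];
      M[idx(i, j)] = std::max(pm, std::max(px, py)) + s;
      X[idx(i, j)] = std::max(M[idx(i - 1, j)] - gap_open,
                     std::max(X[idx(i - 1, j)] - gap_extend,
                              Y[idx(i - 1, j)] - gap_open));
      Y[idx(i, j)] = std::max(M[idx(i, j - 1)] - gap_open,
                     std::max(X[idx(i, j - 1)] - gap_open,
                              Y[idx(i, j - 1)] - gap_extend));
    }
  }

  double vm = M[idx(n, m)], vx = X[idx(n, m)], vy = Y[idx(n, m)];
  double score = std::max(vm, std::max(vx, vy));

  // traceback; state 0 = M, 1 = Y (gap in a), 2 = X (gap in b);
  // tie preference M > Y > X
  int state = (vm >= vy && vm >= vx) ? 0 : (vy >= vx ? 1 : 2);
  std::string ra, rb;
  int i = n, j = m;
  const double eps = 1e-9;
  while (i > 0 || j > 0) {
    if (state == 0) {
      if (i == 0 || j == 0) stop("traceback error");
      double s = sub(ai[i - 1], bi[j - 1]);
      ra += a[i - 1]; rb += b[j - 1];
      double target = M[idx(i, j)] - s;
      --i; --j;
      if (std::fabs(M[idx(i, j)] - target) < eps) state = 0;
      else if (std::fabs(Y[idx(i, j)] - target) < eps) state = 1;
      else state = 2;
    } else if (state == 1) {            // gap in a, consumes b[j-1]
      ra += '-'; rb += b[j - 1];
      double v = Y[idx(i, j)];
      --j;
      if (i == 0 && j == 0) { state = 0; continue; }
      if (std::fabs(M[idx(i, j)] - (v + gap_open)) < eps) state = 0;
      else if (std::fabs(Y[idx(i, j)] - (v + gap_extend)) < eps) state = 1;
      else state = 2;                    // X -> Y with open
    } else {                             // gap in b, consumes a[i-1]
      ra += a[i - 1]; rb += '-';
      double v = X[idx(i, j)];
      --i;
      if (i == 0 && j == 0) { state = 0; continue; }
      if (std::fabs(M[idx(i, j)] - (v + gap_open)) < eps) state = 0;
      else if (std::fabs(X[idx(i, j)] - (v + gap_extend)) < eps) state = 2;
      else state = 1;                    // Y -> X with open
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["a"] = ra, _["b"] = rb, _["score"] = score);
}
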