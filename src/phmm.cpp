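// Profile-HMM Forward and Viterbi scoring in log2 (bits) space.
//
// Model layout (shared with the R-side builder and the test oracle):
//   - M match states, emission odds precomputed as log2(e_k(a)/bg(a)); the
//     unknown residue X (index 20) scores 0 bits in every state.
//   - insert states emit the background (0 bits per residue).
//   - core transitions t[k][from][to], k = 0..M, from/to in {M, I, D};
//     row M at k = 0 is the begin state B; target M at k = M is the end
//     state E; invalid cells hold probability 0.
//   - local mode: uniform entry B->Mk = 1/M, constant exit Mk->E = tau with
//     the remaining match-row mass scaled by (1 - tau); glocal mode enters
//     only through position 0 and leaves only through position M.
//   - unannotated flanking residues are emitted by background N/C loop
//     states whose self-transition equals the null model's geometric
//     parameter r, so a flank residue costs exactly 0 bits; each
//     core-consumed residue is relieved of the null's per-residue r.
#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline double lg2(double p) { return p > 0 ? std::log2(p) : NEG_INF; }

static inline double lse2(double a, double b) {
  if (a == NEG_INF) return b;
  if (b == NEG_INF) return a;
  double m = a > b ? a : b;
  return m + std::log2(std::exp2(a - m) + std::exp2(b - m));
}

struct Model {
  int M;
  const NumericMatrix &emo;   // M x 21 log2 odds (col 21 = X, zeros)
  std::vector<double> t;      // (M+1) x 3 x 3 probabilities
  bool local;
  double tau, r;
  Model(const NumericMatrix &emo_, const NumericVector &trans, int M_,
        bool local_, double tau_, double r_)
    : M(M_), emo(emo_), t(trans.begin(), trans.end()),
      local(local_), tau(tau_), r(r_) {}
  double tr(int k, int from, int to) const { return t[(k * 3 + from) * 3 + to]; }
  // log2 transition used for a *continuing* core move out of position k
  double ltr(int k, int from, int to) const {
    double p = tr(k, from, to);
    if (local && from == 0 && k >= 1) p *= (1.0 - tau);
    return lg2(p);
  }
  // log2 exit contribution from state (k, from) to E
  double lexit(int k, int from) const {
    if (local) {
      if (from == 0) {
        if (k == M) return lg2(tau + (1.0 - tau) * tr(M, 0, 0));
        return lg2(tau);
      }
      return k == M ? lg2(tr(M, from, 0)) : NEG_INF;
    }
    return k == M ? lg2(tr(M, from, 0)) : NEG_INF;
  }
};

// [[Rcpp::export(name = ".phmm_forward_cpp")]]
double phmm_forward_cpp(NumericMatrix emo, NumericVector trans,
                        IntegerVector seq, bool local, double tau, double r) {
  int M = emo.nrow(), L = seq.size();
  Model mod(emo, trans, M, local, tau, r);
  double lr = std::log2(r);
  double entry = local ? lg2(1.0 / M) : NEG_INF;

  // sm/si/sd[k][i]; i = 0..L, k = 0..M. Row k = 0 models B (glocal only).
  std::vector<std::vector<double>> sm(M + 1, std::vector<double>(L + 1, NEG_INF));
  std::vector<std::vector<double>> si(M + 1, std::vector<double>(L + 1, NEG_INF));
  std::vector<std::vector<double>> sd(M + 1, std::vector<double>(L + 1, NEG_INF));

  if (!local)
    for (int i = 0; i <= L; ++i) sm[0][i] = 0.0;  // B with free prefix flank
  // glocal N-terminal inserts (I_0)
  if (!local) {
    for (int i = 1; i <= L; ++i)
      si[0][i] = -lr + lse2(sm[0][i - 1] + mod.ltr(0, 0, 1),
                            si[0][i - 1] + mod.ltr(0, 1, 1));
  }
  // glocal deletes reachable at i = 0 and generally: handled in main loop via
  // k ascending with same-i dependencies; seed i = 0 D column first.
  if (!local) {
    for (int k = 1; k <= M; ++k)
      sd[k][0] = lse2(sm[k - 1][0] + mod.ltr(k - 1, 0, 2),
                 lse2(si[k - 1][0] + mod.ltr(k - 1, 1, 2),
                      sd[k - 1][0] + mod.ltr(k - 1, 2, 2)));
  }

  for (int i = 1; i <= L; ++i) {
    int a = seq[i - 1];
    for (int k = 1; k <= M; ++k) {
      double e = (a >= 20) ? 0.0 : emo(k - 1, a);
      double from_prev = lse2(sm[k - 1][i - 1] + mod.ltr(k - 1, 0, 0),
                         lse2(si[k - 1][i - 1] + mod.ltr(k - 1, 1, 0),
                              sd[k - 1][i - 1] + mod.ltr(k - 1, 2, 0)));
      if (local) from_prev = lse2(from_prev, entry);
      sm[k][i] = e - lr + from_prev;
      sd[k][i] = lse2(sm[k - 1][i] + mod.ltr(k - 1, 0, 2),
                 lse2(si[k - 1][i] + mod.ltr(k - 1, 1, 2),
                      sd[k - 1][i] + mod.ltr(k - 1, 2, 2)));
      si[k][i] = -lr + lse2(sm[k][i - 1] + mod.ltr(k, 0, 1),
                       lse2(si[k][i - 1] + mod.ltr(k, 1, 1),
                            sd[k][i - 1] + mod.ltr(k, 2, 1)));
    }
  }

  double tot = NEG_INF;
  int i0 = local ? 1 : 0;  // glocal all-delete path may consume nothing
  for (int i = i0; i <= L; ++i)
    for (int k = 1; k <= M; ++k) {
      tot = lse2(tot, sm[k][i] + mod.lexit(k, 0));
      tot = lse2(tot, si[k][i] + mod.lexit(k, 1));
      tot = lse2(tot, sd[k][i] + mod.lexit(k, 2));
    }
  return tot;
}

// [[Rcpp::export(name = ".phmm_viterbi_cpp")]]
List phmm_viterbi_cpp(NumericMatrix emo, NumericVector trans,
                      IntegerVector seq, bool local, double tau, double r) {
  int M = emo.nrow(), L = seq.size();
  Model mod(emo, trans, M, local, tau, r);
  double lr = std::log2(r);
  double entry = local ? lg2(1.0 / M) : NEG_INF;

  std::vector<std::vector<double>> sm(M + 1, std::vector<double>(L + 1, NEG_INF)),
      si(M + 1, std::vector<double>(L + 1, NEG_INF)),
      sd(M + 1, std::vector<double>(L + 1, NEG_INF));
  // predecessor state: 0=M, 1=I, 2=D, 3=entry/B, -1=unreachable
  std::vector<std::vector<int>> pm(M + 1, std::vector<int>(L + 1, -1)),
      pi(M + 1, std::vector<int>(L + 1, -1)),
      pd(M + 1, std::vector<int>(L + 1, -1));

  if (!local) {
    for (int i = 0; i <= L; ++i) { sm[0][i] = 0.0; pm[0][i] = 3; }
    for (int i = 1; i <= L; ++i) {
      double a1 = sm[0][i - 1] + mod.ltr(0, 0, 1);
      double a2 = si[0][i - 1] + mod.ltr(0, 1, 1);
      if (a1 >= a2) { si[0][i] = -lr + a1; pi[0][i] = 3; }
      else          { si[0][i] = -lr + a2; pi[0][i] = 1; }
    }
    for (int k = 1; k <= M; ++k) {
      double c[3] = { sm[k - 1][0] + mod.ltr(k - 1, 0, 2),
                      si[k - 1][0] + mod.ltr(k - 1, 1, 2),
                      sd[k - 1][0] + mod.ltr(k - 1, 2, 2) };
      int b = (c[0] >= c[1] && c[0] >= c[2]) ? 0 : (c[1] >= c[2] ? 1 : 2);
      if (c[b] > NEG_INF) { sd[k][0] = c[b]; pd[k][0] = b; }
    }
  }

  for (int i = 1; i <= L; ++i) {
    int a = seq[i - 1];
    for (int k = 1; k <= M; ++k) {
      double e = (a >= 20) ? 0.0 : emo(k - 1, a);
      double c[4] = { sm[k - 1][i - 1] + mod.ltr(k - 1, 0, 0),
                      si[k - 1][i - 1] + mod.ltr(k - 1, 1, 0),
                      sd[k - 1][i - 1] + mod.ltr(k - 1, 2, 0),
                      local ? entry : NEG_INF };
      int b = 0; for (int j = 1; j < 4; ++j) if (c[j] > c[b]) b = j;
      if (c[b] > NEG_INF) { sm[k][i] = e - lr + c[b]; pm[k][i] = b; }

      double d[3] = { sm[k - 1][i] + mod.ltr(k - 1, 0, 2),
                      si[k - 1][i] + mod.ltr(k - 1, 1, 2),
                      sd[k - 1][i] + mod.ltr(k - 1, 2, 2) };
      int bd = (d[0] >= d[1] && d[0] >= d[2]) ? 0 : (d[1] >= d[2] ? 1 : 2);
      if (d[bd] > NEG_INF) { sd[k][i] = d[bd]; pd[k][i] = bd; }

      double g[3] = { sm[k][i - 1] + mod.ltr(k, 0, 1),
                      si[k][i - 1] + mod.ltr(k, 1, 1),
                      sd[k][i - 1] + mod.ltr(k, 2, 1) };
      int bi = (g[0] >= g[1] && g[0] >= g[2]) ? 0 : (g[1] >= g[2] ? 1 : 2);
      if (g[bi] > NEG_INF) { si[k][i] = -lr + g[bi]; pi[k][i] = bi; }
    }
  }

  double best = NEG_INF; int bk = -1, bi_ = -1, bs = -1;
  int i0 = local ? 1 : 0;
  for (int i = i0; i <= L; ++i)
    for (int k = 1; k <= M; ++k) {
      double v;
      v = sm[k][i] + mod.lexit(k, 0);
      if (v > best) { best = v; bk = k; bi_ = i; bs = 0; }
      v = si[k][i] + mod.lexit(k, 1);
      if (v > best) { best = v; bk = k; bi_ = i; bs = 1; }
      v = sd[k][i] + mod.lexit(k, 2);
      if (v > best) { best = v; bk = k; bi_ = i; bs = 2; }
    }
  if (bk < 0)
    return List::create(_["bits"] = NEG_INF, _["path"] = CharacterVector(0),
                        _["start"] = NA_INTEGER, _["end"] = NA_INTEGER);

  // traceback
  std::vector<std::string> path;
  int k = bk, i = bi_, s = bs;
  int min_res = L + 2, max_res = -1;
  while (true) {
    int prev;
    if (s == 0) {
      if (k == 0) break;  // glocal B
      path.push_back("M" + std::to_string(k));
      if (i >= 1) { if (i < min_res) min_res = i; if (i > max_res) max_res = i; }
      prev = pm[k][i];
      if (prev == 3) break;
      k -= 1; i -= 1;
    } else if (s == 1) {
      path.push_back("I" + std::to_string(k));
      if (i >= 1) { if (i < min_res) min_res = i; if (i > max_res) max_res = i; }
      prev = pi[k][i];
      if (prev == 3) break;
      i -= 1;
    } else {
      path.push_back("D" + std::to_string(k));
      prev = pd[k][i];
      if (prev == 3) break;
      k -= 1;
    }
    s = prev;
  }
  std::reverse(path.begin(), path.end());
  int start0, end0;
  if (max_res < 0) { start0 = bi_; end0 = bi_; }  // nothing consumed
  else { start0 = min_res - 1; end0 = max_res; }
  return List::create(_["bits"] = best,
                      _["path"] = wrap(path),
                      _["start"] = start0, _["end"] = end0);
}
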