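// Minimum-free-energy folding of short RNAs (<= 200 nt) by dynamic
// programming under a simplified nearest-neighbor model: stacked-pair
// energies by pair class, loop penalties linear in loop size, multiloop
// affine in unpaired bases and branches. Nested structures only (no
// pseudoknots), Watson-Crick and G-U pairs, hairpin loops >= 3 nt.
//
// Zuker-style recursions:
//   V(i,j)  : minimum energy given i pairs j
//   M(i,j)  : minimum energy of a multiloop segment with >= 1 branch
//   W(j)    : minimum energy of prefix [0..j], exterior bases free
// Interior loops are bounded (maxInterior unpaired total), as in mfold.

#include <Rcpp.h>
#include <vector>
#include <utility>
using namespace Rcpp;

static const double INF = 1e9;
static const double EPS = 1e-7;

// bases: A=0, C=1, G=2, U=3; pair classes AU,UA,GC,CG,GU,UG -> 0..5
static inline int pairType(int a, int b) {
  if (a == 0 && b == 3) return 0;
  if (a == 3 && b == 0) return 1;
  if (a == 2 && b == 1) return 2;
  if (a == 1 && b == 2) return 3;
  if (a == 2 && b == 3) return 4;
  if (a == 3 && b == 2) return 5;
  return -1;
}

struct Params {
  NumericMatrix stack;   // 6x6, stack[outer, inner]
  double hairpinA, hairpinB;
  double bulgeA, bulgeB;
  double interiorA, interiorB;
  double mlA, mlB, mlC;
  int minLoop, maxInterior;
};

class Folder {
public:
  Folder(const std::vector<int>& s, const Params& p) : seq(s), par(p) {
    n = (int)seq.size();
    V.assign((size_t)n * n, INF);
    M.assign((size_t)n * n, INF);
    pairs.assign(n, -1);
  }

  double& v(int i, int j) { return V[(size_t)i * n + j]; }
  double& m(int i, int j) { return M[(size_t)i * n + j]; }

  // Energy of the loop closed by (i,j) with inner pair (k,l).
  double twoLoopE(int i, int j, int k, int l) {
    int s1 = k - i - 1, s2 = j - l - 1;
    if (s1 + s2 > par.maxInterior) return INF;
    int pto = pairType(seq[i], seq[j]);
    int pti = pairType(seq[k], seq[l]);
    if (pto < 0 || pti < 0) return INF;
    if (s1 == 0 && s2 == 0) return par.stack(pto, pti);
    if (s1 == 0 || s2 == 0) return par.bulgeA + par.bulgeB * (s1 + s2);
    return par.interiorA + par.interiorB * (s1 + s2);
  }

  void fill() {
    for (int span = par.minLoop + 1; span < n; ++span) {
      for (int i = 0; i + span < n; ++i) {
        int j = i + span;
        // ---- V(i,j) ----
        if (pairType(seq[i], seq[j]) >= 0 && j - i - 1 >= par.minLoop) {
          double best = par.hairpinA + par.hairpinB * (j - i - 1);
          int kmax = std::min(i + par.maxInterior + 1, j - 1);
          for (int k = i + 1; k <= kmax; ++k) {
            int lmin = std::max(k + par.minLoop + 1,
                                j - 1 - (par.maxInterior - (k - i - 1)));
            for (int l = j - 1; l >= lmin; --l) {
              if (pairType(seq[k], seq[l]) < 0) continue;
              double e = v(k, l);
              if (e >= INF) continue;
              e += twoLoopE(i, j, k, l);
              if (e < best) best = e;
            }
          }
          // multiloop closure: two >=1-branch segments inside
          for (int k = i + 2; k <= j - 2; ++k) {
            double a = m(i + 1, k), b = m(k + 1, j - 1);
            if (a >= INF || b >= INF) continue;
            double e = par.mlA + par.mlC + a + b;
            if (e < best) best = e;
          }
          v(i, j) = best;
        }
        // ---- M(i,j) ----
        double best = INF;
        if (v(i, j) < INF) best = v(i, j) + par.mlC;
        if (m(i + 1, j) + par.mlB < best) best = m(i + 1, j) + par.mlB;
        if (m(i, j - 1) + par.mlB < best) best = m(i, j - 1) + par.mlB;
        for (int k = i; k < j; ++k) {
          double e = m(i, k) + m(k + 1, j);
          if (e < best) best = e;
        }
        m(i, j) = best;
      }
    }
    // ---- exterior ----
    W.assign(n + 1, 0.0);
    for (int j = 0; j < n; ++j) {
      double best = W[j]; // j unpaired (W is 1-shifted: W[j+1] for prefix ..j)
      for (int i = 0; i <= j; ++i) {
        double e = W[i] + v(i, j);
        if (e < best) best = e;
      }
      W[j + 1] = best;
    }
  }

  // Deterministic traceback: interior candidates are scanned with the inner
  // 5' index ascending and the inner 3' index descending (prefer stacking /
  // longer helices), then multiloops, then the hairpin.
  void traceV(int i, int j) {
    pairs[i] = j; pairs[j] = i;
    double target = v(i, j);
    double hp = par.hairpinA + par.hairpinB * (j - i - 1);
    int kmax = std::min(i + par.maxInterior + 1, j - 1);
    for (int k = i + 1; k <= kmax; ++k) {
      int lmin = std::max(k + par.minLoop + 1,
                          j - 1 - (par.maxInterior - (k - i - 1)));
      for (int l = j - 1; l >= lmin; --l) {
        if (pairType(seq[k], seq[l]) < 0) continue;
        if (v(k, l) >= INF) continue;
        if (std::abs(v(k, l) + twoLoopE(i, j, k, l) - target) < EPS) {
          traceV(k, l);
          return;
        }
      }
    }
    for (int k = i + 2; k <= j - 2; ++k) {
      if (m(i + 1, k) >= INF || m(k + 1, j - 1) >= INF) continue;
      if (std::abs(par.mlA + par.mlC + m(i + 1, k) + m(k + 1, j - 1) - target)
          < EPS) {
        traceM(i + 1, k);
        traceM(k + 1, j - 1);
        return;
      }
    }
    if (std::abs(hp - target) < EPS) return; // hairpin loop
    Rcpp::stop("traceback failure in V");
  }

  void traceM(int i, int j) {
    double target = m(i, j);
    if (v(i, j) < INF && std::abs(v(i, j) + par.mlC - target) < EPS) {
      traceV(i, j);
      return;
    }
    if (i + 1 <= j && std::abs(m(i + 1, j) + par.mlB - target) < EPS) {
      traceM(i + 1, j);
      return;
    }
    if (i <= j - 1 && std::abs(m(i, j - 1) + par.mlB - target) < EPS) {
      traceM(i, j - 1);
      return;
    }
    for (int k = i; k < j; ++k) {
      if (std::abs(m(i, k) + m(k + 1, j) - target) < EPS) {
        traceM(i, k);
        traceM(k + 1, j);
        return;
      }
    }
    Rcpp::stop("traceback failure in M");
  }

  void traceW() {
    int j = n - 1;
    while (j >= 0) {
      if (std::abs(W[j + 1] - W[j]) < EPS) { --j; continue; }
      bool found = false;
      for (int i = 0; i <= j; ++i) {
        if (v(i, j) >= INF) continue;
        if (std::abs(W[i] + v(i, j) - W[j + 1]) < EPS) {
          traceV(i, j);
          j = i - 1;
          found = true;
          break;
        }
      }
      if (!found) Rcpp::stop("traceback failure in W");
    }
  }

  std::vector<int> seq;
  Params par;
  int n;
  std::vector<double> V, M, W;
  std::vector<int> pairs;
};

// [[Rcpp::export(name = ".fold_mfe_cpp")]]
List fold_mfe_cpp(IntegerVector baseCodes, NumericMatrix stack,
                  double hairpinA, double hairpinB,
                  double bulgeA, double bulgeB,
                  double interiorA, double interiorB,
                  double mlA, double mlB, double mlC,
                  int minLoop, int maxInterior) {
  Params p{stack, hairpinA, hairpinB, bulgeA, bulgeB,
           interiorA, interiorB, mlA, mlB, mlC, minLoop, maxInterior};
  std::vector<int> s(baseCodes.begin(), baseCodes.end());
  Folder f(s, p);
  f.fill();
  f.traceW();
  IntegerVector pr(f.n);
  for (int i = 0; i < f.n; ++i) pr[i] = f.pairs[i] + 1; // 1-based, 0 = unpaired
  return List::create(_["energy"] = f.W[f.n], _["pairs"] = pr);
}
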